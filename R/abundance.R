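#' Abundance matrices (metabolite x sample quantifier-ion heights)
#'
#' The profiling currency is the quantifier-ion (EIC) height matrix:
#' rows are identified metabolites (plus the ribitol negative-control
#' row until QC strips it), columns are samples with their metadata,
#' and censoring flags mark values reported at the detection floor.
#'
#' @name abundance
NULL

.new_abundance_matrix <- function(values, censored, samples) {
  stopifnot(ncol(values) == nrow(samples),
            all(dim(values) == dim(censored)))
  structure(list(values = values, censored = censored, samples = samples),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d metabolites x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$samples$role)),
                            table(x$samples$role)), collapse = ", ")))
  invisible(x)
}

#' Build the abundance matrix of a rendered batch
#'
#' For every run: fit the run's alkane RI calibration, identify peaks,
#' then extract one quantifier-ion height per library metabolite (at the
#' dominant TMS variant's retention index).  Unknown recurring features
#' (peaks identified as nothing) are clustered across runs by retention
#' index within the centroid merge radius and kept as `unknown@<RI>`
#' rows so the QC drift/blank filters can see contaminants.
#'
#' @param batch A `gcms_batch`.
#' @param library A `metabolite_library`.
#' @param params An [identification_params()] list.
#' @param min_criterion Keep library metabolites identified at this
#'   criterion tier or better in at least one biological run (default 3;
#'   `Inf` keeps every library metabolite regardless).
#' @param floor Detection floor passed to [extract_eic_height()].
#' @return An `abundance_matrix` covering all runs (biological, blanks,
#'   QC pools, standards) with identification metadata in
#'   `attr(, "identification")`.
#' @export
build_abundance_matrix <- function(batch, library,
                                   params = identification_params(),
                                   min_criterion = 3, floor = 500) {
  std_names <- c(amino_acid_names(library), "Ornithine")
  runs <- batch$runs
  calibs <- lapply(runs, fit_ri_map)

  # identify peaks per run; collect identified names and unknown features
  id_tables <- vector("list", length(runs))
  for (i in seq_along(runs))
    id_tables[[i]] <- identify_run(runs[[i]], library, params,
                                   standards = std_names)
  bio <- which(batch$manifest$role %in% c("transporter", "uninjected"))
  seen <- unlist(lapply(id_tables[bio], function(t)
    t$name[t$criterion %in% c("1", "2", "3")]))
  lib_rows <- if (is.infinite(min_criterion))
    names(library) else intersect(names(library), unique(seen))
  # always carry the IS and ladder (QC needs them) and by-products
  lib_rows <- union(lib_rows, names(library)[vapply(library, function(r)
    r$class %in% c("internal_standard", "alkane"), logical(1))])

  # unknown features: cluster unidentified peaks by RI across runs
  unk <- do.call(rbind, lapply(seq_along(runs), function(i) {
    t <- id_tables[[i]]
    u <- t[t$criterion == "unidentified", c("assigned_ri", "peak")]
    if (nrow(u) == 0) return(NULL)
    cbind(u, run = i)
  }))
  unknown_defs <- NULL
  if (!is.null(unk) && nrow(unk) > 0) {
    o <- order(unk$assigned_ri)
    ri <- unk$assigned_ri[o]
    cl <- cumsum(c(1, diff(ri) > params$centroid_distance))
    cen <- tapply(ri, cl, stats::median)
    counts <- tapply(ri, cl, length)
    keep <- counts >= max(3, length(bio) %/% 2)   # recurring features only
    unknown_defs <- data.frame(name = sprintf("unknown@%.0f", cen[keep]),
                               ri = as.numeric(cen[keep]))
  }

  row_names <- c(lib_rows, if (is.null(unknown_defs)) character()
                 else unknown_defs$name)
  values <- matrix(NA_real_, length(row_names), length(runs),
                   dimnames = list(row_names, batch$manifest$sample_id))
  censored <- matrix(FALSE, length(row_names), length(runs),
                     dimnames = dimnames(values))
  for (i in seq_along(runs)) {
    for (met in lib_rows) {
      rec <- library[[met]]
      h <- extract_eic_height(runs[[i]], rec$quantifier_mz,
                              rec$retention_index, calibs[[i]],
                              ri_window = params$ri_window, floor = floor)
      values[met, i] <- as.numeric(h)
      censored[met, i] <- isTRUE(attr(h, "censored"))
    }
    if (!is.null(unknown_defs)) for (j in seq_len(nrow(unknown_defs))) {
      pk <- runs[[i]]$peaks
      ris <- assign_ri(pk$rt, calibs[[i]])
      cand <- which(abs(ris - unknown_defs$ri[j]) <= params$ri_window)
      h <- if (length(cand) > 0) max(pk$height[cand]) else floor
      values[unknown_defs$name[j], i] <- max(h, floor)
      censored[unknown_defs$name[j], i] <- h < floor
    }
  }
  samples <- batch$manifest[, c("injection_order", "sample_id", "role",
                                "transporter", "timepoint", "replicate")]
  samples$ribitol_height <- vapply(runs, `[[`, 0, "ribitol_height")
  mat <- .new_abundance_matrix(values, censored, samples)
  attr(mat, "identification") <- id_tables
  mat
}

#' Simulate an abundance matrix directly (no chromatogram rendering)
#'
#' The statistical backbone of the pipeline without peak rendering or
#' identification: pools are simulated and converted straight to
#' quantifier-ion heights (`amount x n_oocytes x response factor x
#' dominant TMS proportion x (1 - conversion loss)`, with lognormal
#' instrument noise and floor censoring).  Used for simulation studies
#' that need many batches (e.g. type-I error calibration), where
#' rendering every injection would add nothing.
#'
#' @param design An [experiment_design()].
#' @param library,models Optional packaged fixtures.
#' @param floor Detection floor (default 500).
#' @return An `abundance_matrix` with transporter and un-injected
#'   samples at every timepoint x replicate.
#' @export
simulate_abundance_matrix <- function(design, library = NULL, models = NULL,
                                      floor = 500) {
  if (is.null(library)) library <- load_reference_library()
  if (is.null(models)) models <- load_transporter_models()
  pools_tr <- simulate_pools(design, library = library, models = models)
  d_un <- design; d_un$transporter <- "Un-injected"
  pools_un <- simulate_pools(d_un, library = library, models = models)
  set.seed(design$seed + 1L)
  pool_mets <- rownames(pools_tr[[1]])
  byprods <- names(library)[vapply(library, function(r)
    r$class == "by_product", logical(1))]
  mets <- c(pool_mets, byprods)
  eff <- vapply(mets, function(nm) {
    rec <- library[[nm]]
    response_factor(rec$rf_class) * max(rec$tms_variants$proportion)
  }, 0)
  # derivatization conversion: fraction of each parent renders as its
  # by-product (ornithine, pyroglutamic acid)
  convert <- function(amt) {
    out <- c(amt, setNames(rep(0, length(byprods)), byprods))
    for (nm in pool_mets) {
      cp <- library[[nm]]$conversion_products
      if (nrow(cp) > 0) {
        moved <- amt[nm] * cp$fraction
        out[nm] <- out[nm] - sum(moved)
        for (j in seq_len(nrow(cp)))
          out[cp$product[j]] <- out[cp$product[j]] + moved[j]
      }
    }
    out
  }
  phases <- colnames(pools_tr[[1]])
  cols <- expand.grid(replicate = seq_len(design$n_replicates),
                      timepoint = phases,
                      role = c("transporter", "uninjected"),
                      stringsAsFactors = FALSE)
  values <- matrix(NA_real_, length(mets), nrow(cols),
                   dimnames = list(mets, sprintf("%s_%s_rep%d",
                                                 substr(cols$role, 1, 2),
                                                 cols$timepoint,
                                                 cols$replicate)))
  rib <- numeric(nrow(cols))
  for (j in seq_len(nrow(cols))) {
    pools <- if (cols$role[j] == "transporter") pools_tr else pools_un
    amt <- convert(pools[[cols$replicate[j]]][, cols$timepoint[j]])
    h <- amt * design$n_oocytes * eff *
      exp(stats::rnorm(length(amt), 0, design$instrument_cv))
    values[, j] <- pmax(h, floor)
    rib[j] <- instrument_params()$ribitol_height *
      exp(stats::rnorm(1, 0, design$ribitol_cv))
  }
  censored <- values <= floor
  samples <- data.frame(injection_order = seq_len(nrow(cols)),
                        sample_id = colnames(values), role = cols$role,
                        transporter = ifelse(cols$role == "transporter",
                                             design$transporter,
                                             "Un-injected"),
                        timepoint = cols$timepoint,
                        replicate = cols$replicate,
                        ribitol_height = rib)
  .new_abundance_matrix(values, censored, samples)
}
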