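#' Dual fold-change / absolute-difference substrate profiling
#'
#' Transporter-expressing samples are profiled against matched
#' un-injected controls incubated in the same medium for the same time:
#' the fold-change (ratio of means) takes natural endogenous
#' fluctuations out of the picture, while the absolute difference
#' reveals flux into pools that are already large (where a ratio stays
#' near 1 -- the anionic amino acids being the canonical case).  Both
#' are needed for a faithful substrate profile; either alone produces
#' false negatives.
#'
#' @name profiling
NULL

.bio_means <- function(mat, metabolite, timepoint, role) {
  s <- mat$samples
  idx <- s$role == role & s$timepoint == timepoint
  mean(mat$values[metabolite, idx])
}

#' Per-metabolite, per-timepoint fold-change versus matched controls
#'
#' `FC(m, t) = mean transporter(m, t) / mean un-injected(m, t)`.
#' Censored-floor denominators are flagged.  The ribitol internal
#' standard, when present in the matrix, is the negative control: its
#' fold-change should stay within 1 +/- 0.1.
#'
#' @param mat An `abundance_matrix` containing transporter and
#'   uninjected samples.
#' @return data.frame `metabolite`, `timepoint`, `fold_change`,
#'   `censored_denominator`.
#' @export
fold_change <- function(mat) {
  s <- mat$samples
  tps <- unique(s$timepoint[s$role %in% c("transporter", "uninjected")])
  tps <- tps[!is.na(tps)]
  out <- expand.grid(metabolite = rownames(mat$values), timepoint = tps,
                     stringsAsFactors = FALSE)
  out$fold_change <- NA_real_
  out$censored_denominator <- FALSE
  for (i in seq_len(nrow(out))) {
    m <- out$metabolite[i]; tp <- out$timepoint[i]
    den_idx <- s$role == "uninjected" & s$timepoint == tp
    den <- mean(mat$values[m, den_idx])
    stopifnot(den > 0)    # impossible by construction: floor is 500
    out$fold_change[i] <- .bio_means(mat, m, tp, "transporter") / den
    out$censored_denominator[i] <- any(mat$censored[m, den_idx])
  }
  out
}

#' Per-metabolite, per-timepoint absolute signal difference
#'
#' `delta(m, t) = mean transporter(m, t) - mean un-injected(m, t)`.
#'
#' @inheritParams fold_change
#' @return data.frame `metabolite`, `timepoint`, `delta`.
#' @export
absolute_delta <- function(mat) {
  s <- mat$samples
  tps <- unique(s$timepoint[s$role %in% c("transporter", "uninjected")])
  tps <- tps[!is.na(tps)]
  out <- expand.grid(metabolite = rownames(mat$values), timepoint = tps,
                     stringsAsFactors = FALSE)
  out$delta <- vapply(seq_len(nrow(out)), function(i)
    .bio_means(mat, out$metabolite[i], out$timepoint[i], "transporter") -
    .bio_means(mat, out$metabolite[i], out$timepoint[i], "uninjected"), 0)
  out
}

# paired t with graceful handling of zero-variance differences
.paired_p <- function(x, y) {
  d <- y - x
  if (length(d) < 2) return(structure(NA_real_, flag = "fewer than 2 pairs"))
  if (stats::sd(d) == 0) {
    # identical pairs: no evidence of change; constant nonzero shift:
    # infinitely strong evidence (degenerate, flagged)
    return(structure(if (mean(d) == 0) 1 else 0, flag = "zero-variance"))
  }
  p <- tryCatch(stats::t.test(x, y, paired = TRUE)$p.value,
                error = function(e) NULL)
  if (is.null(p))   # numerically constant differences
    return(structure(if (abs(mean(d)) < 1e-12) 1 else 0,
                     flag = "zero-variance"))
  structure(p, flag = NA_character_)
}

#' Paired t-test between two timepoints on raw transporter values
#'
#' Two-sided paired t-test on the raw (un-normalised) transporter-sample
#' values between the first and last timepoint, pairing by replicate
#' (each replicate is one oocyte batch measured at both timepoints).
#' No multiple-testing adjustment is applied by default, matching the
#' per-metabolite p < 0.05 convention of this assay; a
#' Benjamini-Hochberg column is available downstream.
#'
#' @param mat An `abundance_matrix`.
#' @param metabolite Row name to test.
#' @param from,to Timepoint labels (default: first and last).
#' @param role Sample role tested (default `"transporter"`).
#' @return p-value with attribute `"flag"` (`NA`, `"zero-variance"`, or
#'   `"fewer than 2 pairs"`).
#' @export
paired_test <- function(mat, metabolite, from = NULL, to = NULL,
                        role = "transporter") {
  s <- mat$samples
  tps <- unique(s$timepoint[s$role == role])
  tps <- tps[!is.na(tps)]
  if (is.null(from)) from <- tps[1]
  if (is.null(to)) to <- tps[length(tps)]
  reps <- sort(unique(s$replicate[s$role == role]))
  val <- function(tp) vapply(reps, function(r) {
    idx <- which(s$role == role & s$timepoint == tp & s$replicate == r)
    mean(mat$values[metabolite, idx])
  }, 0)
  .paired_p(val(from), val(to))
}

# per-replicate transporter-minus-control differences at one timepoint
.control_deltas <- function(mat, metabolite, timepoint) {
  s <- mat$samples
  reps <- sort(unique(s$replicate[s$role == "transporter"]))
  vapply(reps, function(r) {
    ti <- which(s$role == "transporter" & s$timepoint == timepoint &
                  s$replicate == r)
    ui <- which(s$role == "uninjected" & s$timepoint == timepoint &
                  s$replicate == r)
    mean(mat$values[metabolite, ti]) - mean(mat$values[metabolite, ui])
  }, 0)
}

#' Full substrate profile of an abundance matrix
#'
#' Combines fold-change, absolute difference and the paired tests into
#' the long profile table.  For each metabolite and each timepoint after
#' the first, the time contrast (`p_value`: paired t between the first
#' timepoint and this one on raw transporter values -- the asterisk of
#' the heat maps) and the control contrast (`delta_p`: paired t of
#' transporter minus matched control across replicates) are computed.
#'
#' @param mat An `abundance_matrix` (biological samples; typically the
#'   QC-filtered matrix).
#' @param ribitol Optional named ribitol height vector (the QC
#'   negative-control row); when supplied a `"Ribitol"` row is included
#'   in the profile but excluded from calls.
#' @param alpha Significance level (default 0.05).
#' @param fc_threshold Fold-change magnitude for an FC-route detection,
#'   as a ratio (default 2: the conventional two-fold yardstick).
#' @param delta_floor Minimum absolute difference for a delta-route
#'   detection (default 500, the detection floor).
#' @return A `substrate_profile` data.frame: `metabolite`, `timepoint`,
#'   `fold_change`, `delta`, `p_value`, `p_adj` (Benjamini-Hochberg,
#'   reported but not used for calls), `delta_p`, `significant`,
#'   `fc_detected`, `delta_detected`, `call`.
#' @export
profile_substrates <- function(mat, ribitol = NULL, alpha = 0.05,
                               fc_threshold = 2, delta_floor = 500) {
  fc <- fold_change(mat)
  dl <- absolute_delta(mat)
  prof <- merge(fc, dl, by = c("metabolite", "timepoint"), sort = FALSE)
  s <- mat$samples
  tps <- unique(s$timepoint[s$role == "transporter"])
  tps <- tps[!is.na(tps)]
  t0 <- tps[1]
  prof$p_value <- NA_real_
  prof$delta_p <- NA_real_
  prof$consistent_direction <- NA
  for (i in seq_len(nrow(prof))) {
    m <- prof$metabolite[i]; tp <- prof$timepoint[i]
    if (tp == t0) next
    prof$p_value[i] <- as.numeric(paired_test(mat, m, from = t0, to = tp))
    cd <- .control_deltas(mat, m, tp)
    prof$delta_p[i] <- as.numeric(.paired_p(rep(0, length(cd)), cd))
    prof$consistent_direction[i] <- all(cd > 0) || all(cd < 0)
  }
  prof$p_adj <- NA_real_
  late <- !is.na(prof$p_value)
  prof$p_adj[late] <- stats::p.adjust(prof$p_value[late], "BH")
  prof$significant <- !is.na(prof$p_value) & prof$p_value < alpha
  prof$fc_detected <- prof$significant &
    (prof$fold_change >= fc_threshold | prof$fold_change <= 1 / fc_threshold)
  prof$delta_detected <- prof$significant &
    !is.na(prof$delta_p) & prof$delta_p < alpha &
    prof$consistent_direction & abs(prof$delta) >= delta_floor
  prof <- call_substrates(prof)

  if (!is.null(ribitol)) {
    rib_rows <- do.call(rbind, lapply(tps, function(tp) {
      ti <- s$sample_id[s$role == "transporter" & s$timepoint == tp]
      ui <- s$sample_id[s$role == "uninjected" & s$timepoint == tp]
      data.frame(metabolite = "Ribitol", timepoint = tp,
                 fold_change = mean(ribitol[ti]) / mean(ribitol[ui]),
                 censored_denominator = FALSE,
                 delta = mean(ribitol[ti]) - mean(ribitol[ui]),
                 p_value = NA_real_, delta_p = NA_real_,
                 consistent_direction = NA, p_adj = NA_real_,
                 significant = FALSE, fc_detected = FALSE,
                 delta_detected = FALSE, call = "negative control")
    }))
    prof <- rbind(prof, rib_rows)
  }
  class(prof) <- c("substrate_profile", "data.frame")
  prof
}

#' Substrate calls from the dual analysis
#'
#' A metabolite is called **accumulated** at a timepoint when the time
#' contrast is significant and either route detects an increase
#' (fold-change at or above the two-fold threshold, or a
#' replicate-consistent positive control contrast at p < alpha);
#' **depleted** symmetrically; otherwise **unchanged**.  Rows that are
#' not significant are always unchanged.  The ribitol negative-control
#' row never receives a call.
#'
#' @param profile A profile data.frame with `fc_detected`,
#'   `delta_detected`, `fold_change`, `delta`, `significant` columns.
#' @return The profile with a `call` column
#'   (`accumulated`/`depleted`/`unchanged`).
#' @export
call_substrates <- function(profile) {
  up <- (profile$fc_detected & profile$fold_change > 1) |
    (profile$delta_detected & profile$delta > 0)
  dn <- (profile$fc_detected & profile$fold_change < 1) |
    (profile$delta_detected & profile$delta < 0)
  profile$call <- ifelse(!profile$significant, "unchanged",
                         ifelse(up, "accumulated",
                                ifelse(dn, "depleted", "unchanged")))
  profile$call[profile$metabolite == "Ribitol"] <- "negative control"
  profile
}

#' Two-phase exchanger (preload / efflux) profile
#'
#' Exchangers equilibrate substrate pools without changing their sum, so
#' plain incubation shows little.  The preload protocol creates the
#' needed imbalance: phase 1 compares the post-preload state (column
#' "0,+") with the pre-preload baseline ("0,-") -- the preloaded
#' substrate must rise while preferred cytosolic substrates efflux;
#' phase 2 compares the post-medium state ("4") with the post-preload
#' state -- influx substrates rise as the preloaded substrate exits.
#'
#' @param mat An `abundance_matrix` whose transporter samples carry the
#'   phase labels `"baseline"`, `"preloaded"` and one or more `"t<h>"`
#'   columns (as produced from a preloaded [experiment_design()]).
#' @param alpha Significance level (default 0.05).
#' @return A `substrate_profile`-style data.frame: `metabolite`,
#'   `phase` (`"preload"` or `"medium"`), `fold_change` (ratio of
#'   transporter means across the transition), `delta` (difference of
#'   transporter means), `p_value` (paired t across replicates),
#'   `significant`, `sign` (`"+"`, `"-"` or `""`).
#' @export
exchanger_profile <- function(mat, alpha = 0.05) {
  s <- mat$samples
  tps <- unique(s$timepoint[s$role == "transporter"])
  needed <- c("baseline", "preloaded")
  if (!all(needed %in% tps))
    stop(sprintf("exchanger profile requires phase columns %s; found: %s",
                 paste(needed, collapse = ", "), paste(tps, collapse = ", ")))
  final <- setdiff(tps, needed)
  if (length(final) == 0) stop("exchanger profile requires a post-medium column")
  final <- final[length(final)]
  transitions <- list(preload = c("baseline", "preloaded"),
                      medium = c("preloaded", final))
  reps <- sort(unique(s$replicate[s$role == "transporter"]))
  rows <- list()
  for (ph in names(transitions)) {
    from <- transitions[[ph]][1]; to <- transitions[[ph]][2]
    for (m in rownames(mat$values)) {
      val <- function(tp) vapply(reps, function(r) {
        idx <- which(s$role == "transporter" & s$timepoint == tp &
                       s$replicate == r)
        mean(mat$values[m, idx])
      }, 0)
      x <- val(from); y <- val(to)
      p <- as.numeric(.paired_p(x, y))
      delta <- mean(y) - mean(x)
      sig <- !is.na(p) && p < alpha
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = m, phase = ph, fold_change = mean(y) / mean(x),
        delta = delta, p_value = p, significant = sig,
        sign = if (!sig) "" else if (delta > 0) "+" else "-")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("substrate_profile", "data.frame")
  out
}

#' Write heat-map-ready fold-change and delta tables
#'
#' Two TSV matrices (metabolite x timepoint/phase), significance marked
#' with an asterisk on the fold-change entry, ribitol and
#' conversion-product rows included whenever present in the profile.
#'
#' @param profile A `substrate_profile` data.frame.
#' @param dir Output directory.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_heatmap_tables <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  col <- if ("timepoint" %in% names(profile)) "timepoint" else "phase"
  mets <- unique(profile$metabolite)
  cols <- unique(profile[[col]])
  fmt <- function(valcol, star) {
    m <- matrix("", length(mets), length(cols),
                dimnames = list(mets, as.character(cols)))
    for (i in seq_len(nrow(profile))) {
      v <- profile[[valcol]][i]
      txt <- if (is.na(v)) "" else sprintf("%.4g", v)
      if (star && isTRUE(profile$significant[i])) txt <- paste0(txt, "*")
      m[profile$metabolite[i], as.character(profile[[col]][i])] <- txt
    }
    m
  }
  paths <- c(fold_change = file.path(dir, "fold_change.tsv"),
             delta = file.path(dir, "absolute_delta.tsv"))
  utils::write.table(fmt("fold_change", TRUE), paths["fold_change"],
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(fmt("delta", TRUE), paths["delta"], sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(paths)
}
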