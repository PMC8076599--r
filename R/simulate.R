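#' Simulate intracellular metabolite pools under a transport model
#'
#' Integrates intracellular amounts (pmol/oocyte) on a fixed-step grid.
#' Initial amino acid pools are the endogenous stage 5/6 oocyte values in
#' the reference library, perturbed per replicate by lognormal
#' between-batch noise (shared across roles within a replicate).  Three
#' flux components act on the pools:
#'
#' * **Symport influx** for substrate i:
#'   `v_i = Vmax_i (S_i/Km_i) / (1 + sum_j S_j/Km_j)` with `S_j` the
#'   (fixed) medium concentrations -- co-substrates compete for the
#'   carrier.  Medium depletion is ignored (2 ml of medium against nL
#'   oocyte volumes).  Uniporters use the same competitive
#'   facilitated-entry form.
#' * **Antiport** (strict 1:1 exchange): the summed intracellular amount
#'   over the transporter's substrate set is conserved; exchange drives
#'   each substrate toward the proportion of its trans-side (medium)
#'   saturation, `pi_i = (S_i/Km_i)/sum_j (S_j/Km_j)`, at the
#'   transporter's exchange rate.  Preloading a single substrate makes it
#'   the sole trans-side species, so it accumulates while preferred
#'   cytosolic substrates efflux.
#' * **Endogenous drift**, applied to every sample (transporter-expressing
#'   or not) when `design$drift` is TRUE: see [endogenous_drift_rates()].
#'
#' Negative excursions are clipped at 0 with a warning.
#'
#' @param design An [experiment_design()].
#' @param transporter Optional `transporter_model` overriding the design's
#'   named fixture.
#' @param library Optional `metabolite_library` (default: packaged).
#' @param models Optional `transporter_models` (default: packaged).
#' @param dt Integration step in hours (default 0.01).
#' @return A `pool_state` object: a list with one element per replicate,
#'   each a matrix (metabolites x sampled phases, pmol/oocyte) with
#'   columns `"t<h>"` for plain designs or `"baseline"`, `"preloaded"`,
#'   `"t<h>"` for preload designs.
#' @export
simulate_pools <- function(design, transporter = NULL, library = NULL,
                           models = NULL, dt = 0.01) {
  if (is.null(library)) library <- load_reference_library()
  if (is.null(models) && is.null(transporter)) models <- load_transporter_models()
  if (is.null(transporter)) {
    if (!design$transporter %in% names(models))
      stop(sprintf("unknown transporter '%s'; available: %s",
                   design$transporter, paste(names(models), collapse = ", ")))
    transporter <- models[[design$transporter]]
  }
  set.seed(design$seed)
  mets <- names(library)[vapply(library, function(r)
    r$class %in% c("amino_acid", "metabolite"), logical(1))]
  base <- vapply(library[mets], `[[`, 0, "endogenous_pmol_per_oocyte")
  drift <- endogenous_drift_rates()
  drift_vec <- setNames(rep(0, length(mets)), mets)
  if (design$drift) drift_vec[names(drift)] <- drift

  reps <- vector("list", design$n_replicates)
  clipped <- 0L
  for (r in seq_len(design$n_replicates)) {
    init <- base * exp(stats::rnorm(length(base), 0, design$pool_cv))
    segs <- .pool_segments(design)
    amounts <- init
    out <- matrix(NA_real_, length(mets), length(segs$labels),
                  dimnames = list(mets, segs$labels))
    k <- 1
    if (segs$sample_start) { out[, k] <- amounts; k <- k + 1 }
    for (s in seq_along(segs$media)) {
      res <- .integrate_segment(amounts, segs$media[[s]], segs$durations[[s]],
                                segs$sample_at[[s]], transporter, drift_vec, dt)
      clipped <- clipped + res$clipped
      for (m in seq_along(res$samples)) { out[, k] <- res$samples[[m]]; k <- k + 1 }
      amounts <- res$final
    }
    reps[[r]] <- out
  }
  if (clipped > 0)
    warning(sprintf("%d negative pool excursions clipped at 0", clipped))
  structure(reps, class = "pool_state", metabolites = mets)
}

# Split the design into incubation segments with sampling times.
.pool_segments <- function(design) {
  if (is.null(design$preload)) {
    tp <- design$timepoints
    sample_start <- tp[1] == 0
    later <- tp[tp > 0]
    list(sample_start = sample_start,
         labels = paste0("t", tp),
         media = list(design$medium),
         durations = list(max(later)),
         sample_at = list(later))
  } else {
    pre_med <- medium_preset("ND96")
    pre_med[design$preload$substrate] <- design$preload$conc_um
    later <- design$timepoints[design$timepoints > 0]
    list(sample_start = TRUE,
         labels = c("baseline", "preloaded", paste0("t", later)),
         media = list(pre_med, design$medium),
         durations = list(design$preload$duration_h, max(later)),
         sample_at = list(design$preload$duration_h, later))
  }
}

# Fixed-step explicit integration of one incubation segment.
.integrate_segment <- function(amounts, medium, duration, sample_at,
                               transporter, drift_vec, dt) {
  mets <- names(amounts)
  sub <- transporter$substrates
  sub <- sub[sub$substrate %in% mets, , drop = FALSE]
  mech <- transporter$mechanism
  v_sym <- NULL; pi_tgt <- NULL; kx <- 0
  if (nrow(sub) > 0 && mech %in% c("symport", "uniport")) {
    sat <- medium[sub$substrate] / sub$Km
    v_sym <- setNames(sub$Vmax * sat / (1 + sum(sat)), sub$substrate)
  } else if (nrow(sub) > 0 && mech == "antiport") {
    sat <- medium[sub$substrate] / sub$Km
    kx <- transporter$exchange_rate_per_h
    if (sum(sat) > 0) pi_tgt <- setNames(sat / sum(sat), sub$substrate)
  }
  n_steps <- round(duration / dt)
  sample_steps <- round(sample_at / dt)
  samples <- vector("list", length(sample_at))
  clipped <- 0L
  for (step in seq_len(max(n_steps, 0L))) {
    dA <- drift_vec * amounts
    if (!is.null(v_sym)) dA[names(v_sym)] <- dA[names(v_sym)] + v_sym
    if (!is.null(pi_tgt)) {
      tot <- sum(amounts[names(pi_tgt)])
      dA[names(pi_tgt)] <- dA[names(pi_tgt)] +
        kx * (pi_tgt * tot - amounts[names(pi_tgt)])
    }
    amounts <- amounts + dA * dt
    neg <- amounts < 0
    if (any(neg)) { clipped <- clipped + sum(neg); amounts[neg] <- 0 }
    hit <- which(sample_steps == step)
    for (h in hit) samples[[h]] <- amounts
  }
  if (n_steps == 0) for (h in seq_along(sample_at)) samples[[h]] <- amounts
  list(final = amounts, samples = samples, clipped = clipped)
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("<pool_state> %d replicates, %d metabolites, phases: %s\n",
              length(x), nrow(x[[1]]), paste(colnames(x[[1]]), collapse = ", ")))
  invisible(x)
}
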