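#' Biomimetic incubation medium presets
#'
#' Free amino acid concentrations (uM) of the incubation media emulated by
#' the simulator.  `"L15"` is a modified Leibovitz L-15 style biomimetic
#' medium with all 20 proteinogenic amino acids present (tryptophan
#' deliberately low, as in the real formulation); `"ND96"` is a plain
#' frog-Ringer assay buffer containing no amino acids, used for
#' preloading exchanger substrates.
#'
#' @param name `"L15"` or `"ND96"`.
#' @return Named numeric vector of concentrations (uM) over the 20
#'   proteinogenic amino acids.
#' @export
medium_preset <- function(name = c("L15", "ND96")) {
  name <- match.arg(name)
  l15 <- c(Alanine = 2200, Arginine = 1100, Asparagine = 450,
           `Aspartic acid` = 150, Cysteine = 700, Glutamine = 2100,
           `Glutamic acid` = 150, Glycine = 1800, Histidine = 1000,
           Isoleucine = 950, Leucine = 950, Lysine = 850, Methionine = 500,
           Phenylalanine = 600, Proline = 300, Serine = 1100,
           Threonine = 1700, Tryptophan = 60, Tyrosine = 250, Valine = 700)
  if (name == "L15") l15 else setNames(rep(0, length(l15)), names(l15))
}

#' Endogenous drift rates of un-injected oocytes
#'
#' Oocytes are not metabolically silent: over a 4 h incubation in rich
#' medium, TCA-cycle intermediates and the anionic/amide amino acids
#' accumulate (aspartate, glutamine, 2-aminoadipate and citrate more than
#' 2-fold) while the branched-chain amino acids valine, leucine and
#' isoleucine are consumed (more than 2-fold decrease).  The drift is
#' modelled as first-order exponential growth/decay applied to every
#' sample regardless of transporter expression.  Rates (per hour) are
#' fixture choices reproducing those fold-change magnitudes.
#'
#' @return Named numeric vector of first-order rates (1/h).
#' @export
endogenous_drift_rates <- function() {
  up24 <- log(2.5) / 4     # > 2-fold increase over 4 h
  dn24 <- log(0.42) / 4    # > 2-fold decrease over 4 h
  c(`Aspartic acid` = up24, Glutamine = up24, `2-Aminoadipic acid` = up24,
    `Citric acid` = up24, `Glutamic acid` = log(1.8) / 4,
    Sucrose = log(1.3) / 4,
    Valine = dn24, Leucine = dn24, Isoleucine = dn24)
}

#' Define a simulated oocyte transport experiment
#'
#' Captures the full study design: which transporter is expressed, the
#' incubation medium, optional exchanger preloading, sampling timepoints,
#' pooling and replication, and all noise magnitudes.
#'
#' @param transporter Name of a transporter fixture (see
#'   [load_transporter_models()]), e.g. `"SNAT2-like"` or `"Un-injected"`.
#' @param medium Named numeric vector of medium amino acid concentrations
#'   (uM); defaults to the biomimetic L-15 preset.
#' @param preload Optional list `list(substrate=, conc_um=, duration_h=)`
#'   describing exchanger preloading (default 10 mM for 6 h when used).
#' @param timepoints Incubation sampling times in hours (sorted, >= 2).
#' @param n_oocytes Oocytes pooled per sample (default 12).
#' @param n_replicates Experimental repeats, each a separate oocyte batch
#'   (default 3).
#' @param oocyte_volume_nl Water-accessible volume of a stage 5/6 oocyte
#'   in nL (default 365).
#' @param drift Apply endogenous metabolic drift (default TRUE).
#' @param pool_cv Between-replicate lognormal CV on initial endogenous
#'   pools (default 0.10); shared across roles within a replicate (one
#'   donor-frog batch split across conditions).
#' @param instrument_cv Lognormal CV on rendered peak heights (default 0.05).
#' @param ribitol_cv Lognormal CV on the spiked ribitol internal standard
#'   (default 0.02; pipetting precision).
#' @param ri_jitter_sd Gaussian retention-index jitter on rendered peaks,
#'   in RI units (default 1).
#' @param seed Integer seed controlling all randomness downstream.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(transporter = "SNAT2-like",
                              medium = medium_preset("L15"),
                              preload = NULL,
                              timepoints = c(0, 4),
                              n_oocytes = 12,
                              n_replicates = 3,
                              oocyte_volume_nl = 365,
                              drift = TRUE,
                              pool_cv = 0.10,
                              instrument_cv = 0.05,
                              ribitol_cv = 0.02,
                              ri_jitter_sd = 1,
                              seed = 1L) {
  timepoints <- sort(unique(timepoints))
  stopifnot(length(timepoints) >= 2, all(medium >= 0), n_oocytes >= 1,
            n_replicates >= 1)
  if (!is.null(preload)) {
    stopifnot(is.list(preload), !is.null(preload$substrate))
    if (is.null(preload$conc_um)) preload$conc_um <- 10000
    if (is.null(preload$duration_h)) preload$duration_h <- 6
  }
  d <- list(transporter = transporter, medium = medium, preload = preload,
            timepoints = timepoints, n_oocytes = n_oocytes,
            n_replicates = n_replicates, oocyte_volume_nl = oocyte_volume_nl,
            drift = drift, pool_cv = pool_cv, instrument_cv = instrument_cv,
            ribitol_cv = ribitol_cv, ri_jitter_sd = ri_jitter_sd,
            seed = as.integer(seed))
  class(d) <- "experiment_design"
  d
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s; %d reps x %d oocytes; t = {%s} h%s\n",
              x$transporter, x$n_replicates, x$n_oocytes,
              paste(x$timepoints, collapse = ", "),
              if (is.null(x$preload)) "" else
                sprintf("; preload %s %g uM / %g h", x$preload$substrate,
                        x$preload$conc_um, x$preload$duration_h)))
  invisible(x)
}
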