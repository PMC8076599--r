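#' Pipeline configuration
#'
#' A fully serialisable description of one end-to-end run: the
#' experiment design plus all analysis thresholds.  A config and its
#' seed reproduce every output byte-identically.
#'
#' @param design An [experiment_design()].
#' @param detection A [peak_detection_params()] list.
#' @param identification An [identification_params()] list.
#' @param ribitol_tolerance,drift_threshold,blank_threshold QC
#'   thresholds (see [qc_filter()]).
#' @param alpha,fc_threshold,delta_floor Profiling thresholds (see
#'   [profile_substrates()]).
#' @param output_dir Directory for all reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design = experiment_design(),
                            detection = peak_detection_params(),
                            identification = identification_params(),
                            ribitol_tolerance = 0.10,
                            drift_threshold = 0.8, blank_threshold = 0.10,
                            alpha = 0.05, fc_threshold = 2,
                            delta_floor = 500,
                            output_dir = tempfile("oometab_")) {
  structure(list(design = design, detection = detection,
                 identification = identification,
                 ribitol_tolerance = ribitol_tolerance,
                 drift_threshold = drift_threshold,
                 blank_threshold = blank_threshold, alpha = alpha,
                 fc_threshold = fc_threshold, delta_floor = delta_floor,
                 output_dir = output_dir),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  # cheap structural hash: stable across sessions, no external deps
  s <- paste(utils::capture.output(utils::str(
    unclass(config), digits.d = 12, list.len = 1000)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Simulate a batch and write it to disk
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (default: `<output_dir>/batch`).
#' @return The directory, invisibly; the batch manifest gains the config
#'   hash.
#' @export
run_simulate <- function(config, dir = file.path(config$output_dir, "batch")) {
  batch <- generate_batch(config$design)
  batch$manifest$config_hash <- .config_hash(config)
  write_batch(batch, dir)
  invisible(dir)
}

#' Run the full analysis on a batch directory
#'
#' Executes retention-index calibration, peak identification,
#' abundance-matrix extraction, quality control, calibration-curve
#' fitting and substrate profiling, writing one report per stage into
#' `config$output_dir`.  Fails (hard) if the batch contains no
#' biological samples or if QC discards more than half of them.
#'
#' @param batch_dir Directory written by [run_simulate()] /
#'   [write_batch()], or a `gcms_batch` object.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `matrix` (QC-filtered), `qc`,
#'   `curves`, `quantified`, `profile`, `calls`, `files`.
#' @export
run_profile <- function(batch_dir, config = pipeline_config()) {
  batch <- if (inherits(batch_dir, "gcms_batch")) batch_dir else
    read_batch(batch_dir)
  library <- load_reference_library()
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) message(sprintf(...))

  n_bio <- sum(batch$manifest$role %in% c("transporter", "uninjected"))
  if (n_bio == 0) stop("no biological samples in batch")

  log("stage ri_calibration + identification + extraction: %d runs",
      length(batch$runs))
  mat <- build_abundance_matrix(batch, library, config$identification)
  log("  matrix: %d rows x %d samples", nrow(mat$values), ncol(mat$values))

  log("stage qc_filters")
  qc <- qc_filter(mat, library, config$ribitol_tolerance,
                  config$drift_threshold, config$blank_threshold)
  for (l in qc$log) log("  %s", l)
  kept_bio <- sum(qc$matrix$samples$role %in% c("transporter", "uninjected"))
  if (kept_bio < n_bio / 2)
    stop(sprintf("QC discarded %d of %d biological samples",
                 n_bio - kept_bio, n_bio))

  log("stage quantification")
  curves <- batch_calibration_curves(batch, library)
  quantified <- .quantified_table(qc$matrix, curves, config$design, library)

  log("stage profiling")
  is_exchanger <- "preloaded" %in% qc$matrix$samples$timepoint
  profile <- if (is_exchanger) exchanger_profile(qc$matrix, config$alpha)
    else profile_substrates(qc$matrix, ribitol = qc$ribitol,
                            alpha = config$alpha,
                            fc_threshold = config$fc_threshold,
                            delta_floor = config$delta_floor)
  calls <- if (!is_exchanger) {
    tps <- unique(profile$timepoint[!is.na(profile$p_value)])
    final <- tps[length(tps)]
    profile[profile$timepoint == final &
              profile$metabolite != "Ribitol",
            c("metabolite", "call")]
  } else profile[, c("metabolite", "phase", "sign")]

  files <- c(
    qc = file.path(out, "qc_report.tsv"),
    calibration = file.path(out, "calibration_report.tsv"),
    quantified = file.path(out, "quantified.tsv"),
    profile = file.path(out, "profile.tsv"),
    calls = file.path(out, "substrate_calls.json"))
  utils::write.table(qc$gate, files["qc"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cal_df <- do.call(rbind, lapply(curves, function(cv) data.frame(
    metabolite = cv$metabolite, slope = cv$slope, intercept = cv$intercept,
    adjusted_r2 = cv$adjusted_r2, pass = cv$pass)))
  utils::write.table(cal_df, files["calibration"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(quantified, files["quantified"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(profile, files["profile"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(calls, files["calls"], auto_unbox = TRUE, digits = NA)
  write_heatmap_tables(profile, out)

  structure(list(matrix = qc$matrix, qc = qc, curves = curves,
                 quantified = quantified, profile = profile, calls = calls,
                 files = files),
            class = "pipeline_result")
}

# mean quantified endogenous content of un-injected t0 samples
.quantified_table <- function(mat, curves, design, library) {
  s <- mat$samples
  t0 <- sort(unique(s$timepoint))[1]
  idx <- s$role == "uninjected" & s$timepoint == t0
  rows <- list()
  for (met in intersect(rownames(mat$values), names(curves))) {
    h <- mean(mat$values[met, idx])
    cv <- curves[[met]]
    if (cv$slope <= 0) next
    # the rendered EIC height reflects the dominant TMS variant of the
    # post-conversion amount; the standards share both factors, so the
    # back-calculated amount is directly comparable
    qs <- quantify_sample(h, cv, design$n_oocytes, design$oocyte_volume_nl)
    rows[[met]] <- data.frame(metabolite = met,
                              pmol_per_oocyte = qs$pmol_per_oocyte,
                              concentration_um = qs$concentration_um)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d metabolites profiled; %d calibration curves\n",
              length(unique(x$profile$metabolite)), length(x$curves)))
  invisible(x)
}
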