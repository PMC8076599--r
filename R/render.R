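#' Instrument parameters for rendered GC-MS runs
#'
#' Emulates a single-quadrupole GC-MS with a 21-minute single-ramp oven
#' program (70 degC held 1 min, then 15 degC/min to 325 degC), full-scan
#' acquisition 40-600 m/z at 3.6 Hz.  With a single linear ramp the
#' retention-time/retention-index relation is (to good approximation)
#' linear, so the simulator's ground-truth map places the C12 alkane
#' (RI 1200) at 390 s and advances 0.325 s per RI unit, keeping C36
#' (RI 3600) inside the run.
#'
#' @param rt_per_ri Seconds per retention-index unit (default 0.325).
#' @param rt_at_1200 Retention time of RI 1200 in seconds (default 390).
#' @param scan_hz Scan rate (default 3.6).
#' @param peak_sigma_s Chromatographic peak width (Gaussian sigma,
#'   seconds; default 1.7).
#' @param run_shift_sd Per-run retention shift (seconds, default 2) --
#'   this is the drift the in-run alkane ladder corrects for.
#' @param ion_cv Lognormal CV on individual spectrum ion intensities
#'   (default 0.03).
#' @param ribitol_height Nominal ribitol internal-standard height
#'   (default 20000).
#' @param floor Detection floor in abundance units (default 500).
#' @return An `instrument_params` list.
#' @export
instrument_params <- function(rt_per_ri = 0.325, rt_at_1200 = 390,
                              scan_hz = 3.6, peak_sigma_s = 1.7,
                              run_shift_sd = 2, ion_cv = 0.03,
                              ribitol_height = 20000, floor = 500) {
  structure(list(rt_per_ri = rt_per_ri, rt_at_1200 = rt_at_1200,
                 scan_hz = scan_hz, peak_sigma_s = peak_sigma_s,
                 run_shift_sd = run_shift_sd, ion_cv = ion_cv,
                 ribitol_height = ribitol_height, floor = floor),
            class = "instrument_params")
}

# ground-truth RT for a retention index (before the per-run shift)
.rt_from_ri <- function(ri, inst) inst$rt_at_1200 + inst$rt_per_ri * (ri - 1200)

.alkane_carbons <- c(12, 15, 19, 22, 28, 33, 36)

#' Render one GC-MS injection from metabolite amounts
#'
#' Turns a named vector of metabolite amounts (pmol per pooled sample)
#' into a peak-level chromatogram run.  Derivatization conversion is
#' applied first (a fixed fraction of arginine renders as ornithine, of
#' glutamate/glutamine as pyroglutamic acid); each TMS variant of a
#' metabolite is rendered as its own peak at the variant's retention
#' index (plus Gaussian jitter); peak height is
#' `amount x response factor x lognormal noise`; the alkane ladder, the
#' ribitol internal standard (biological and QC roles) and any
#' contaminants are added on top.
#'
#' @param amounts Named numeric vector, pmol per pooled sample (may be
#'   empty for blanks).  Every name must exist in the library.
#' @param library A `metabolite_library`.
#' @param role One of `"uninjected"`, `"transporter"`, `"blank"`,
#'   `"qc_pool"`, `"standard_mix"`.
#' @param inst An [instrument_params()] list.
#' @param instrument_cv Lognormal CV on peak heights.
#' @param ribitol_cv Lognormal CV on the ribitol height (`NA` omits the
#'   internal standard entirely, emulating a failed spike).
#' @param ri_jitter_sd Gaussian RI jitter (RI units).
#' @param contaminants Optional data.frame `name`, `ri`, `height` of
#'   non-library peaks to add (drifting column contaminants).
#' @param sample_id,injection_order,transporter,timepoint,phase,replicate
#'   Sample metadata carried on the run.
#' @return A `chromatogram_run` object.
#' @export
render_run <- function(amounts, library, role, inst = instrument_params(),
                       instrument_cv = 0.05, ribitol_cv = 0.02,
                       ri_jitter_sd = 1, contaminants = NULL,
                       sample_id = "run", injection_order = NA_integer_,
                       transporter = NA_character_, timepoint = NA_character_,
                       phase = NA_character_, replicate = NA_integer_) {
  stopifnot(role %in% c("uninjected", "transporter", "blank", "qc_pool",
                        "standard_mix"))
  missing <- setdiff(names(amounts), names(library))
  if (length(missing) > 0)
    stop(sprintf("metabolite(s) absent from library: %s",
                 paste(missing, collapse = ", ")))
  run_shift <- stats::rnorm(1, 0, inst$run_shift_sd)

  # derivatization conversion products (e.g. Arg -> ornithine)
  amounts <- amounts[amounts > 0]
  adj <- amounts
  for (nm in names(amounts)) {
    cp <- library[[nm]]$conversion_products
    if (nrow(cp) > 0) {
      moved <- amounts[nm] * cp$fraction
      adj[nm] <- adj[nm] - sum(moved)
      for (j in seq_len(nrow(cp))) {
        tgt <- cp$product[j]
        adj[tgt] <- (if (tgt %in% names(adj)) adj[tgt] else 0) + moved[j]
      }
    }
  }
  adj <- adj[adj > 0]

  peaks <- list()
  add_peak <- function(name, variant, ri_true, height, spectrum) {
    ri_obs <- ri_true + stats::rnorm(1, 0, ri_jitter_sd)
    rt <- .rt_from_ri(ri_obs, inst) + run_shift
    area <- height * inst$peak_sigma_s * sqrt(2 * pi)
    peaks[[length(peaks) + 1]] <<- list(
      name = name, variant = variant, rt = rt, ri_true = ri_true,
      height = height, area = area, spectrum = spectrum)
  }
  noisy_spec <- function(spec) {
    spec$rel_intensity <- spec$rel_intensity *
      exp(stats::rnorm(nrow(spec), 0, inst$ion_cv))
    spec
  }
  for (nm in names(adj)) {
    rec <- library[[nm]]
    rf <- response_factor(rec$rf_class)
    tv <- rec$tms_variants
    for (j in seq_len(nrow(tv))) {
      h <- adj[[nm]] * tv$proportion[j] * rf *
        exp(stats::rnorm(1, 0, instrument_cv))
      add_peak(nm, tv$label[j], tv$retention_index[j], h,
               noisy_spec(rec$spectrum))
    }
  }

  ribitol_height <- NA_real_
  if (role %in% c("uninjected", "transporter", "qc_pool") && !is.na(ribitol_cv)) {
    rec <- library[["Ribitol"]]
    ribitol_height <- inst$ribitol_height * exp(stats::rnorm(1, 0, ribitol_cv))
    add_peak("Ribitol", "1", rec$retention_index, ribitol_height,
             noisy_spec(rec$spectrum))
  }

  alkane_rts <- numeric(length(.alkane_carbons))
  names(alkane_rts) <- sprintf("C%d", .alkane_carbons)
  for (i in seq_along(.alkane_carbons)) {
    n <- .alkane_carbons[i]
    rec <- library[[sprintf("C%d alkane", n)]]
    alk_jit <- if (ri_jitter_sd > 0) stats::rnorm(1, 0, 0.3) else 0
    rt <- .rt_from_ri(100 * n, inst) + run_shift + alk_jit
    alkane_rts[i] <- rt
    h <- 50000 * exp(stats::rnorm(1, 0, instrument_cv))
    peaks[[length(peaks) + 1]] <- list(
      name = rec$name, variant = "1", rt = rt, ri_true = 100 * n,
      height = h, area = h * inst$peak_sigma_s * sqrt(2 * pi),
      spectrum = noisy_spec(rec$spectrum))
  }
  stopifnot(all(diff(alkane_rts) > 0))

  if (!is.null(contaminants) && nrow(contaminants) > 0) {
    for (j in seq_len(nrow(contaminants))) {
      spec <- data.frame(mz = c(contaminants$mz1[j], 73, 147,
                                contaminants$mz2[j]),
                         rel_intensity = c(1, 0.8, 0.5, 0.4))
      add_peak(contaminants$name[j], "1", contaminants$ri[j],
               contaminants$height[j], spec)
    }
  }

  pk <- data.frame(
    name = vapply(peaks, `[[`, "", "name"),
    variant = vapply(peaks, `[[`, "", "variant"),
    rt = vapply(peaks, `[[`, 0, "rt"),
    ri_true = vapply(peaks, `[[`, 0, "ri_true"),
    height = vapply(peaks, `[[`, 0, "height"),
    area = vapply(peaks, `[[`, 0, "area"))
  pk$spectrum <- lapply(peaks, `[[`, "spectrum")
  pk <- pk[order(pk$rt), ]
  rownames(pk) <- NULL

  structure(list(sample_id = sample_id, role = role,
                 transporter = transporter, timepoint = timepoint,
                 phase = phase, replicate = replicate,
                 injection_order = injection_order, peaks = pk,
                 alkane_rts = alkane_rts, ribitol_height = ribitol_height,
                 instrument = inst),
            class = "chromatogram_run")
}

#' @export
print.chromatogram_run <- function(x, ...) {
  cat(sprintf("<chromatogram_run> %s [%s] #%s: %d peaks\n", x$sample_id,
              x$role, x$injection_order, nrow(x$peaks)))
  invisible(x)
}

#' Render a run (or a window of it) as centroided scan-level data
#'
#' Produces the wide scan x m/z intensity matrix consumed by the
#' peak-detection path: Gaussian chromatographic peaks on a uniform scan
#' grid, each m/z trace scaled by the peak's spectrum.
#'
#' @param run A `chromatogram_run`.
#' @param from,to Retention-time window in seconds (defaults to the span
#'   of the run's peaks plus a margin).
#' @param baseline Constant baseline offset added to the TIC-forming
#'   traces (default 0).
#' @param noise_sd Gaussian noise per scan cell (default 0).
#' @return A numeric matrix (scans x m/z) with scan times (s) in
#'   `attr(, "scan_times")` and integer m/z values as column names.
#' @export
render_scan_matrix <- function(run, from = NULL, to = NULL, baseline = 0,
                               noise_sd = 0) {
  inst <- run$instrument
  pk <- run$peaks
  if (is.null(from)) from <- max(0, min(pk$rt) - 20)
  if (is.null(to)) to <- max(pk$rt) + 20
  times <- seq(from, to, by = 1 / inst$scan_hz)
  mzs <- sort(unique(unlist(lapply(pk$spectrum, `[[`, "mz"))))
  mat <- matrix(baseline, length(times), length(mzs),
                dimnames = list(NULL, as.character(mzs)))
  for (i in seq_len(nrow(pk))) {
    if (pk$rt[i] < from - 10 | pk$rt[i] > to + 10) next
    shape <- pk$height[i] * exp(-(times - pk$rt[i])^2 /
                                  (2 * inst$peak_sigma_s^2))
    sp <- pk$spectrum[[i]]
    rel <- sp$rel_intensity / max(sp$rel_intensity)
    for (j in seq_len(nrow(sp)))
      mat[, as.character(sp$mz[j])] <- mat[, as.character(sp$mz[j])] +
        shape * rel[j]
  }
  if (noise_sd > 0) mat <- mat + matrix(stats::rnorm(length(mat), 0, noise_sd),
                                        nrow(mat))
  attr(mat, "scan_times") <- times
  mat
}

#' Standard-mix and calibration-series loadings
#'
#' The 21-component standard mix (20 canonical amino acids plus
#' ornithine) loads good-response-factor amino acids at 1 ug each and the
#' five poor-Rf amino acids (Arg, Ala, His, Trp, Cys) at 10 ug.
#' Calibration series are run per response-factor group at six amounts
#' spanning each group's linear range.
#'
#' @param library A `metabolite_library`.
#' @return List with `mix` (named pmol vector for the standard mix) and
#'   `calibration` (list per rf group: `metabolites`, `amounts_nmol`).
#' @export
standard_loadings <- function(library) {
  aa <- amino_acid_names(library)
  targets <- c(aa, "Ornithine")
  low_rf <- c("Arginine", "Alanine", "Histidine", "Tryptophan", "Cysteine")
  ug <- setNames(ifelse(targets %in% low_rf, 10, 1), targets)
  mw <- vapply(library[targets], `[[`, 0, "molecular_weight")
  mix <- ug * 1e6 / mw                     # ug -> pmol
  groups <- split(targets, vapply(library[targets], `[[`, "", "rf_class"))
  amounts <- list(high = c(0.25, 0.5, 1, 2, 4, 8),
                  medium = c(0.5, 1, 2, 4, 8, 16),
                  low = c(1.25, 2.5, 5, 10, 20, 40))
  list(mix = mix,
       calibration = lapply(setNames(names(amounts), names(amounts)),
         function(g) list(metabolites = groups[[g]],
                          amounts_nmol = amounts[[g]])))
}

#' Generate a complete synthetic GC-MS batch
#'
#' Simulates the intracellular pools for the design's transporter and its
#' matched un-injected controls, then renders every injection of a full
#' batch: biological samples at every timepoint x replicate, blanks at
#' batch start and end, pooled-QC injections at the start and after every
#' 8 samples, the 21-component standard mix at the beginning, mid-run and
#' end, and a 6-point calibration series per response-factor group.  One
#' column contaminant (present in every run including blanks) and one
#' drifting contaminant (height proportional to injection order) are
#' added by default.
#'
#' @param design An [experiment_design()].
#' @param library,models Optional packaged fixtures (loaded if NULL).
#' @param contaminant_drift Slope (abundance units per injection) of the
#'   drifting contaminant; 0 disables it.
#' @param column_contaminant_height Height of the constant column
#'   contaminant; 0 disables it.
#' @return A `gcms_batch` list: `runs` (list of `chromatogram_run`),
#'   `manifest` (data.frame, one row per injection), `design`, `pools`
#'   (transporter pools) and `pools_uninjected`.
#' @export
generate_batch <- function(design, library = NULL, models = NULL,
                           contaminant_drift = 250,
                           column_contaminant_height = 8000) {
  if (is.null(library)) library <- load_reference_library()
  if (is.null(models)) models <- load_transporter_models()
  if (!design$transporter %in% names(models))
    stop(sprintf("unknown transporter '%s'; available: %s",
                 design$transporter, paste(names(models), collapse = ", ")))

  pools_tr <- simulate_pools(design, library = library, models = models)
  d_un <- design
  d_un$transporter <- "Un-injected"
  d_un$seed <- design$seed   # same replicate pool perturbations (same frogs)
  pools_un <- simulate_pools(d_un, library = library, models = models)

  set.seed(design$seed + 1L)
  phases <- colnames(pools_tr[[1]])
  std <- standard_loadings(library)
  inst <- instrument_params()

  # build the non-QC injection queue
  queue <- list()
  push <- function(x) queue[[length(queue) + 1]] <<- x
  push(list(role = "blank", id = "blank_start"))
  push(list(role = "standard_mix", id = "stdmix_1", std_kind = "mix"))
  for (g in names(std$calibration))
    for (lv in seq_along(std$calibration[[g]]$amounts_nmol))
      push(list(role = "standard_mix", id = sprintf("cal_%s_%d", g, lv),
                std_kind = "cal", cal_group = g, cal_level = lv))
  bio <- list()
  for (ph in phases) for (r in seq_len(design$n_replicates))
    for (role in c("transporter", "uninjected"))
      bio[[length(bio) + 1]] <- list(role = role, id = sprintf(
        "%s_%s_rep%d", substr(role, 1, 2), ph, r), phase = ph, replicate = r)
  half <- ceiling(length(bio) / 2)
  for (b in bio[seq_len(half)]) push(b)
  push(list(role = "standard_mix", id = "stdmix_2", std_kind = "mix"))
  for (b in bio[seq(half + 1, length(bio))]) push(b)
  push(list(role = "standard_mix", id = "stdmix_3", std_kind = "mix"))
  push(list(role = "blank", id = "blank_end"))

  # interleave QC pools: first injection, then after every 8 runs
  seq_final <- list(list(role = "qc_pool", id = "qc_1"))
  since_qc <- 0; qc_n <- 1
  for (q in queue) {
    seq_final[[length(seq_final) + 1]] <- q
    since_qc <- since_qc + 1
    if (since_qc == 8) {
      qc_n <- qc_n + 1
      seq_final[[length(seq_final) + 1]] <- list(role = "qc_pool",
                                                 id = sprintf("qc_%d", qc_n))
      since_qc <- 0
    }
  }

  # QC pool content: mean of all biological sample contents
  bio_contents <- list()
  for (b in bio) {
    pools <- if (b$role == "transporter") pools_tr else pools_un
    bio_contents[[b$id]] <- pools[[b$replicate]][, b$phase] * design$n_oocytes
  }
  qc_content <- Reduce(`+`, bio_contents) / length(bio_contents)

  runs <- vector("list", length(seq_final))
  manifest <- NULL
  for (i in seq_along(seq_final)) {
    q <- seq_final[[i]]
    cont <- data.frame(name = character(), ri = numeric(), height = numeric(),
                       mz1 = integer(), mz2 = integer())
    if (column_contaminant_height > 0)
      cont <- rbind(cont, data.frame(
        name = "column_contaminant", ri = 2450,
        height = column_contaminant_height * exp(stats::rnorm(1, 0, 0.05)),
        mz1 = 341L, mz2 = 429L))
    if (contaminant_drift > 0)
      cont <- rbind(cont, data.frame(
        name = "drift_contaminant", ri = 2050,
        height = contaminant_drift * i * exp(stats::rnorm(1, 0, 0.05)),
        mz1 = 355L, mz2 = 467L))
    amounts <- switch(q$role,
      blank = setNames(numeric(0), character(0)),
      qc_pool = qc_content,
      standard_mix = if (identical(q$std_kind, "mix")) std$mix else {
        cal <- std$calibration[[q$cal_group]]
        setNames(rep(cal$amounts_nmol[q$cal_level] * 1000,
                     length(cal$metabolites)), cal$metabolites)
      },
      bio_contents[[q$id]])
    runs[[i]] <- render_run(
      amounts, library, role = q$role, inst = inst,
      instrument_cv = design$instrument_cv, ribitol_cv = design$ribitol_cv,
      ri_jitter_sd = design$ri_jitter_sd, contaminants = cont,
      sample_id = q$id, injection_order = i,
      transporter = if (q$role == "transporter") design$transporter else
        if (q$role == "uninjected") "Un-injected" else NA_character_,
      timepoint = if (!is.null(q$phase)) q$phase else NA_character_,
      phase = if (!is.null(q$phase)) q$phase else NA_character_,
      replicate = if (!is.null(q$replicate)) q$replicate else NA_integer_)
    manifest <- rbind(manifest, data.frame(
      injection_order = i, sample_id = q$id, role = q$role,
      transporter = runs[[i]]$transporter,
      timepoint = runs[[i]]$timepoint, replicate = runs[[i]]$replicate,
      std_kind = if (is.null(q$std_kind)) NA_character_ else q$std_kind,
      cal_group = if (is.null(q$cal_group)) NA_character_ else q$cal_group,
      cal_level = if (is.null(q$cal_level)) NA_integer_ else q$cal_level,
      cal_amount_nmol = if (is.null(q$cal_level)) NA_real_ else
        std$calibration[[q$cal_group]]$amounts_nmol[q$cal_level],
      seed = design$seed))
  }
  structure(list(runs = runs, manifest = manifest, design = design,
                 pools = pools_tr, pools_uninjected = pools_un),
            class = "gcms_batch")
}

#' @export
print.gcms_batch <- function(x, ...) {
  cat(sprintf("<gcms_batch> %s: %d injections (%s)\n", x$design$transporter,
              length(x$runs),
              paste(sprintf("%s=%d", names(table(x$manifest$role)),
                            table(x$manifest$role)), collapse = ", ")))
  invisible(x)
}

#' Write a batch to disk as documented text files
#'
#' One CSV per injection (peak list with the spectrum serialised as
#' `mz:intensity` pairs separated by `|`), a `manifest.tsv`, and a
#' `design.json`.
#'
#' @param batch A `gcms_batch`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(batch$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dsg <- batch$design
  dsg$medium <- as.list(dsg$medium)
  jsonlite::write_json(unclass(dsg), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (run in batch$runs) {
    pk <- run$peaks
    pk$spectrum <- vapply(pk$spectrum, function(s)
      paste(sprintf("%d:%.6g", s$mz, s$rel_intensity), collapse = "|"), "")
    f <- file.path(dir, sprintf("run_%03d_%s.csv", run$injection_order,
                                run$sample_id))
    meta <- c(sprintf("# sample_id=%s role=%s injection_order=%d",
                      run$sample_id, run$role, run$injection_order),
              sprintf("# ribitol_height=%.6g", run$ribitol_height),
              sprintf("# alkane_rts=%s",
                      paste(sprintf("%s:%.4f", names(run$alkane_rts),
                                    run$alkane_rts), collapse = "|")))
    writeLines(meta, f)
    suppressWarnings(utils::write.table(
      pk, f, sep = ",", row.names = FALSE, quote = TRUE, append = TRUE))
  }
  invisible(dir)
}

#' Read a batch written by [write_batch()]
#'
#' @param dir Directory containing `manifest.tsv` and per-run CSVs.
#' @return A `gcms_batch` (without the simulation ground-truth pools).
#' @export
read_batch <- function(dir) {
  mf <- utils::read.delim(file.path(dir, "manifest.tsv"))
  dsg <- jsonlite::fromJSON(file.path(dir, "design.json"))
  dsg$medium <- unlist(dsg$medium)
  if (!is.null(dsg$preload) && length(dsg$preload) == 0) dsg$preload <- NULL
  class(dsg) <- "experiment_design"
  files <- list.files(dir, pattern = "^run_\\d+_.*\\.csv$", full.names = TRUE)
  ord <- as.integer(sub("^run_(\\d+)_.*", "\\1", basename(files)))
  files <- files[order(ord)]
  runs <- lapply(files, function(f) {
    hdr <- readLines(f, n = 3)
    rib_txt <- sub("^# ribitol_height=", "", hdr[2])
    rib <- if (rib_txt == "NA") NA_real_ else as.numeric(rib_txt)
    alk <- strsplit(sub("^# alkane_rts=", "", hdr[3]), "|", fixed = TRUE)[[1]]
    alk_v <- vapply(strsplit(alk, ":"), function(x) as.numeric(x[2]), 0)
    names(alk_v) <- vapply(strsplit(alk, ":"), `[[`, "", 1)
    pk <- utils::read.csv(f, skip = 3)
    pk$spectrum <- lapply(strsplit(pk$spectrum, "|", fixed = TRUE), function(s) {
      parts <- strsplit(s, ":")
      data.frame(mz = as.integer(vapply(parts, `[[`, "", 1)),
                 rel_intensity = as.numeric(vapply(parts, `[[`, "", 2)))
    })
    i <- as.integer(sub(".*injection_order=(\\d+).*", "\\1", hdr[1]))
    m <- mf[mf$injection_order == i, ]
    structure(list(sample_id = m$sample_id, role = m$role,
                   transporter = m$transporter, timepoint = m$timepoint,
                   phase = m$timepoint, replicate = m$replicate,
                   injection_order = i, peaks = pk, alkane_rts = alk_v,
                   ribitol_height = rib, instrument = instrument_params()),
              class = "chromatogram_run")
  })
  structure(list(runs = runs, manifest = mf, design = dsg,
                 pools = NULL, pools_uninjected = NULL),
            class = "gcms_batch")
}
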