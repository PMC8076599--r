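#' Peak detection parameters
#'
#' The canonical single-quadrupole untargeted settings: slope threshold
#' 200 abundance units/scan, minimum peak area 1000, minimum peak height
#' 500, minimum peak purity factor 2 and a minimum peak width of 5 scans.
#'
#' @param slope_threshold Rising TIC slope required to open a peak
#'   (abundance units per scan).
#' @param min_area Minimum trapezoidal area (abundance units x scans).
#' @param min_height Minimum baseline-subtracted apex height.
#' @param min_purity_factor Minimum deconvolution purity factor.
#' @param min_width_scans Minimum peak width in scans.
#' @param smooth_window Moving-average width for the slope test (scans).
#' @param baseline_window Rolling-minimum window for the baseline (scans).
#' @param symmetry_threshold Minimum half-area symmetry about the
#'   centroid for identification-grade peaks.
#' @return A `peak_detection_params` list.
#' @export
peak_detection_params <- function(slope_threshold = 200, min_area = 1000,
                                  min_height = 500, min_purity_factor = 2,
                                  min_width_scans = 5, smooth_window = 5,
                                  baseline_window = 51,
                                  symmetry_threshold = 0.5) {
  p <- list(slope_threshold = slope_threshold, min_area = min_area,
            min_height = min_height, min_purity_factor = min_purity_factor,
            min_width_scans = min_width_scans, smooth_window = smooth_window,
            baseline_window = baseline_window,
            symmetry_threshold = symmetry_threshold)
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "peak_detection_params")
}

.moving_average <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

.rolling_min <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) min(x[max(1, i - h):min(n, i + h)]), 0)
}

#' Detect peaks in a scan-level run
#'
#' A peak is a maximal region of the smoothed total ion chromatogram
#' whose rising slope exceeds `slope_threshold` up to a local apex and
#' then falls; region boundaries are the flanking local minima of the
#' baseline-subtracted signal.  Peaks failing the minimum height, area
#' (trapezoidal over the region) or width are dropped.  Retained peaks
#' carry their apex spectrum, baseline-subtracted per m/z trace.
#'
#' @param scans Numeric matrix (scans x m/z) with integer m/z column
#'   names and scan times in `attr(, "scan_times")` (as produced by
#'   [render_scan_matrix()]); the scan grid must be uniform.
#' @param params A [peak_detection_params()] list.
#' @return data.frame of detected peaks: `apex_scan`, `apex_time`,
#'   `height`, `area`, `width_scans`, `symmetry`, `purity_factor`
#'   (a large sentinel until [deconvolve()] is applied), `left`, `right`
#'   (region bounds, scans) and a `spectrum` list column.
#' @export
detect_peaks <- function(scans, params = peak_detection_params()) {
  times <- attr(scans, "scan_times")
  if (is.null(times)) times <- seq_len(nrow(scans))
  if (nrow(scans) == 0)
    return(.empty_peaks())
  stopifnot(nrow(scans) == length(times))
  tic <- rowSums(scans)
  sm <- .moving_average(tic, params$smooth_window)
  base <- .rolling_min(sm, params$baseline_window)
  sig_sm <- pmax(sm - base, 0)       # smoothed: apex location + slope test
  sig <- pmax(tic - base, 0)         # raw: height, area, spectrum
  n <- length(sig)
  slope <- c(0, diff(sm))

  # apex candidates: strict local maxima of the smoothed signal
  apex <- which(sig_sm > 0 &
                c(-Inf, sig_sm[-n]) < sig_sm &
                sig_sm >= c(sig_sm[-1], -Inf))
  out <- list()
  for (a in apex) {
    # region: descend from the apex until the signal levels off or
    # falls below 1% of the apex (tail cutoff)
    cut <- 0.01 * sig_sm[a]
    l <- a; while (l > 1 && sig_sm[l - 1] < sig_sm[l] && sig_sm[l] > cut)
      l <- l - 1
    r <- a; while (r < n && sig_sm[r + 1] < sig_sm[r] && sig_sm[r] > cut)
      r <- r + 1
    if (max(slope[l:a]) < params$slope_threshold) next
    height <- max(sig[max(1, a - 1):min(n, a + 1)])
    if (height < params$min_height) next
    width <- r - l + 1
    if (width < params$min_width_scans) next
    region <- l:r
    area <- sum((sig[region][-1] + sig[region][-length(region)]) / 2)
    if (area < params$min_area) next
    centroid <- sum(region * sig[region]) / sum(sig[region])
    # half-area split about the centroid, the straddling scan divided
    # proportionally so a symmetric peak scores 1
    frac_left <- pmin(pmax(centroid - (region - 0.5), 0), 1)
    lw <- sum(sig[region] * frac_left)
    rw <- sum(sig[region] * (1 - frac_left))
    symmetry <- min(lw, rw) / max(lw, rw)
    spec_base <- apply(scans[max(1, l - 5):min(n, r + 5), , drop = FALSE], 2, min)
    spec_int <- pmax(scans[a, ] - spec_base, 0)
    keep <- spec_int > 0
    spectrum <- data.frame(mz = as.integer(colnames(scans)[keep]),
                           rel_intensity = unname(spec_int[keep]))
    out[[length(out) + 1]] <- list(apex_scan = a, apex_time = times[a],
                                   height = height, area = area,
                                   width_scans = width, symmetry = symmetry,
                                   left = l, right = r, spectrum = spectrum)
  }
  if (length(out) == 0) return(.empty_peaks())
  pk <- data.frame(
    apex_scan = vapply(out, `[[`, 0, "apex_scan"),
    apex_time = vapply(out, `[[`, 0, "apex_time"),
    height = vapply(out, `[[`, 0, "height"),
    area = vapply(out, `[[`, 0, "area"),
    width_scans = vapply(out, `[[`, 0, "width_scans"),
    symmetry = vapply(out, `[[`, 0, "symmetry"),
    purity_factor = .purity_sentinel,
    left = vapply(out, `[[`, 0, "left"),
    right = vapply(out, `[[`, 0, "right"))
  pk$spectrum <- lapply(out, `[[`, "spectrum")
  pk
}

.purity_sentinel <- 1e6

.empty_peaks <- function() {
  pk <- data.frame(apex_scan = integer(), apex_time = numeric(),
                   height = numeric(), area = numeric(),
                   width_scans = integer(), symmetry = numeric(),
                   purity_factor = numeric(), left = integer(),
                   right = integer())
  pk$spectrum <- list()
  pk
}

# Lawson-Hanson active-set nonnegative least squares: min ||Ax - b||, x >= 0
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * nrow(A)
  # dual feasibility tolerance must scale with the data magnitude,
  # otherwise rounding residuals re-activate converged columns forever
  tol_w <- tol * max(max(abs(b)), 1)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol_w) {
    iter <- iter + 1
    if (iter > 30 * n) stop("NNLS iteration limit exceeded")
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Deconvolve co-eluting components within a peak region
#'
#' Each local maximum of the region's TIC defines a component, modelled
#' as a unit-height Gaussian at its apex; every m/z trace is attributed
#' to the components by nonnegative least squares against those model
#' peaks.  The purity factor of a component is its height divided by the
#' height of the largest co-eluting component in the region (a large
#' sentinel when it elutes alone).  A singular fit falls back to
#' apex-spectrum attribution with a warning.
#'
#' @param scans Scan matrix as for [detect_peaks()].
#' @param region Integer vector of scan indices (or `c(from, to)`)
#'   bounding the region; must contain at least one detected apex.
#' @param sigma_scans Model peak width (Gaussian sigma, scans); estimated
#'   from the TIC half-width when NULL.
#' @return List of components, each with `apex_scan`, `apex_time`,
#'   `height` (summed attributed intensity at apex), `purity_factor` and
#'   `spectrum` (data.frame `mz`, `rel_intensity`).
#' @export
deconvolve <- function(scans, region, sigma_scans = NULL) {
  times <- attr(scans, "scan_times")
  if (is.null(times)) times <- seq_len(nrow(scans))
  if (length(region) == 2) region <- region[1]:region[2]
  tic <- rowSums(scans[region, , drop = FALSE])
  nr <- length(region)
  apex_loc <- which(tic > 0 &
                    c(-Inf, tic[-nr]) < tic &
                    tic >= c(tic[-1], -Inf))
  if (length(apex_loc) == 0) stop("region contains no apex")
  if (is.null(sigma_scans)) {
    half <- which(tic >= max(tic) / 2)
    sigma_scans <- max((max(half) - min(half)) / 2.355, 1.5)
  }
  M <- sapply(apex_loc, function(a)
    exp(-((seq_len(nr) - a)^2) / (2 * sigma_scans^2)))
  M <- matrix(M, nrow = nr)
  mzs <- as.integer(colnames(scans))
  coef <- matrix(0, length(apex_loc), length(mzs))
  singular <- FALSE
  for (j in seq_along(mzs)) {
    y <- scans[region, j]
    if (all(y <= 0)) next
    fit <- tryCatch(.nnls(M, y), error = function(e) NULL)
    if (is.null(fit)) { singular <- TRUE; break }
    coef[, j] <- fit
  }
  if (singular) {
    warning("singular deconvolution fit; falling back to apex-spectrum attribution")
    for (k in seq_along(apex_loc)) {
      a <- region[apex_loc[k]]
      coef[k, ] <- pmax(scans[a, ], 0)
    }
  }
  heights <- rowSums(coef)
  comps <- vector("list", length(apex_loc))
  for (k in seq_along(apex_loc)) {
    others <- heights[-k]
    purity <- if (length(others) == 0 || max(others) == 0) .purity_sentinel
              else heights[k] / max(others)
    keep <- coef[k, ] > 0
    comps[[k]] <- list(apex_scan = region[apex_loc[k]],
                       apex_time = times[region[apex_loc[k]]],
                       height = heights[k],
                       purity_factor = purity,
                       spectrum = data.frame(mz = mzs[keep],
                                             rel_intensity = unname(coef[k, keep])))
  }
  comps
}

# invert a piecewise-linear RI calibration (RI -> RT)
.ri_to_rt <- function(ri, calib) {
  tt <- calib$rt_seconds
  nn <- 100 * calib$carbon_number
  seg <- findInterval(ri, nn, all.inside = TRUE)
  tt[seg] + (tt[seg + 1] - tt[seg]) * (ri - nn[seg]) / (nn[seg + 1] - nn[seg])
}

#' Extract the quantifier-ion (EIC) height of a metabolite from a run
#'
#' Quantification uses a common quantifier m/z for the same metabolite
#' across all samples.  The height is the maximum baseline-subtracted
#' intensity of the quantifier trace within `expected_ri +/- ri_window`;
#' values below the detection floor are reported *at* the floor with a
#' censoring flag (they are not true zeros).
#'
#' @param run A `chromatogram_run` (peak-level) or a scan matrix from
#'   [render_scan_matrix()].
#' @param quantifier_mz Integer quantifier ion; must lie in 40-600.
#' @param expected_ri Library retention index of the target.
#' @param calib An `ri_calibration` for the run.
#' @param ri_window Half-width of the RI search window (default 4).
#' @param floor Detection floor (default 500).
#' @return Numeric height with attribute `"censored"` (logical).
#' @export
extract_eic_height <- function(run, quantifier_mz, expected_ri, calib,
                               ri_window = 4, floor = 500) {
  if (quantifier_mz < 40 || quantifier_mz > 600)
    stop("quantifier m/z outside the 40-600 scan range")
  val <- -Inf
  if (inherits(run, "chromatogram_run")) {
    pk <- run$peaks
    ris <- assign_ri(pk$rt, calib)
    cand <- which(abs(ris - expected_ri) <= ri_window)
    for (i in cand) {
      sp <- pk$spectrum[[i]]
      j <- match(quantifier_mz, sp$mz)
      if (is.na(j)) next
      val <- max(val, pk$height[i] * sp$rel_intensity[j] /
                   max(sp$rel_intensity))
    }
  } else {
    times <- attr(run, "scan_times")
    col <- match(as.character(quantifier_mz), colnames(run))
    if (!is.na(col)) {
      rt_lo <- .ri_to_rt(expected_ri - ri_window, calib)
      rt_hi <- .ri_to_rt(expected_ri + ri_window, calib)
      win <- which(times >= rt_lo & times <= rt_hi)
      # baseline from an expanded context window so a peak filling the
      # search window is not subtracted against its own flanks
      ctx_lo <- .ri_to_rt(expected_ri - 10 * ri_window, calib)
      ctx_hi <- .ri_to_rt(expected_ri + 10 * ri_window, calib)
      ctx <- which(times >= ctx_lo & times <= ctx_hi)
      if (length(win) > 0)
        val <- max(run[win, col]) - min(run[ctx, col])
    }
  }
  if (!is.finite(val) || val < floor) {
    val <- floor
    attr(val, "censored") <- TRUE
  } else {
    attr(val, "censored") <- FALSE
  }
  val
}
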