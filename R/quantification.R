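#' Absolute quantification against grouped amino-acid standards
#'
#' Amino acids are calibrated as grouped standards by comparative
#' response factor (high, medium, low), six data points per amino acid,
#' as linear nmol-vs-peak-height fits.  Concentrations are converted to
#' pmol/oocyte using the water-accessible volume of a stage 5/6 oocyte
#' (365 nL).
#'
#' @name quantification
NULL

#' Fit a linear calibration curve (peak height vs amount)
#'
#' Ordinary least squares `height = slope x amount + intercept` with the
#' small-sample adjusted R-squared.  Curves with adjusted R-squared
#' below `min_adj_r2` are flagged with a warning (the acceptance floor
#' for single-amino-acid calibrations is 0.94).
#'
#' @param points data.frame with columns `amount_nmol` and `height`
#'   (>= 3 points; duplicated amounts are allowed but flagged).
#' @param metabolite Optional name carried on the curve.
#' @param min_adj_r2 Quality floor (default 0.94).
#' @return A `calibration_curve` list: `metabolite`, `points`, `slope`,
#'   `intercept`, `adjusted_r2`, `pass`, `duplicated_amounts`.
#' @export
fit_calibration <- function(points, metabolite = NA_character_,
                            min_adj_r2 = 0.94) {
  stopifnot(is.data.frame(points),
            all(c("amount_nmol", "height") %in% names(points)),
            nrow(points) >= 3)
  if (stats::sd(points$amount_nmol) == 0)
    stop("calibration amounts have zero variance")
  dup <- any(duplicated(points$amount_nmol))
  fit <- stats::lm(height ~ amount_nmol, data = points)
  adj <- summary(fit)$adj.r.squared
  if (adj < min_adj_r2)
    warning(sprintf("calibration for %s rejected: adjusted R^2 %.3f < %.2f",
                    metabolite, adj, min_adj_r2))
  structure(list(metabolite = metabolite, points = points,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 adjusted_r2 = adj, pass = adj >= min_adj_r2,
                 duplicated_amounts = dup),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: height = %.3g x nmol + %.3g (adj R^2 = %.4f%s)\n",
              x$metabolite, x$slope, x$intercept, x$adjusted_r2,
              if (x$pass) "" else ", REJECTED"))
  invisible(x)
}

#' Convert a sample's peak height to absolute oocyte content
#'
#' Back-calculates the amount from the calibration curve, divides by the
#' number of pooled oocytes, and expresses the result both as
#' pmol/oocyte and as an intracellular concentration over the
#' water-accessible volume.
#'
#' @param height Observed quantifier-ion peak height (>= 0).
#' @param curve A `calibration_curve` (slope must be positive).
#' @param n_oocytes Oocytes pooled in the sample (default 12).
#' @param oocyte_volume_nl Water-accessible volume (default 365 nL).
#' @return An `oocyte_content` list: `metabolite`, `amount_nmol`,
#'   `pmol_per_oocyte`, `concentration_um`, `clipped` (TRUE when a
#'   negative back-calculated amount was clipped to 0).
#' @export
quantify_sample <- function(height, curve, n_oocytes = 12,
                            oocyte_volume_nl = 365) {
  stopifnot(height >= 0)
  if (curve$slope <= 0) stop("calibration slope must be positive")
  amount <- (height - curve$intercept) / curve$slope
  clipped <- amount < 0
  if (clipped) amount <- 0
  pmol <- amount * 1000 / n_oocytes
  structure(list(metabolite = curve$metabolite, amount_nmol = amount,
                 pmol_per_oocyte = pmol,
                 concentration_um = pmol / (oocyte_volume_nl / 1000),
                 n_oocytes = n_oocytes, clipped = clipped),
            class = "oocyte_content")
}

#' Convert an intracellular concentration to pmol/oocyte
#'
#' `pmol/oocyte = concentration (uM) x 0.365 nL-derived factor`, i.e.
#' micromolar times the 365 nL water-accessible volume.  Reproduces the
#' published endogenous amino-acid table rows after integer rounding
#' (e.g. 499 uM valine -> 182 pmol/oocyte).
#'
#' @param concentration_um Concentration in uM (>= 0).
#' @param oocyte_volume_nl Water-accessible volume (default 365 nL).
#' @return pmol per oocyte.
#' @export
content_from_concentration <- function(concentration_um,
                                       oocyte_volume_nl = 365) {
  stopifnot(all(concentration_um >= 0))
  concentration_um * oocyte_volume_nl / 1000
}

#' Fit calibration curves for every amino acid in a batch
#'
#' Reads the 6-point calibration series (grouped by response-factor
#' class) out of a rendered batch, extracts quantifier-ion heights and
#' fits one curve per amino acid.
#'
#' @param batch A `gcms_batch`.
#' @param library A `metabolite_library`.
#' @return Named list of `calibration_curve` objects.
#' @export
batch_calibration_curves <- function(batch, library) {
  mf <- batch$manifest
  cal <- mf[!is.na(mf$std_kind) & mf$std_kind == "cal", ]
  curves <- list()
  for (g in unique(cal$cal_group)) {
    rows <- cal[cal$cal_group == g, ]
    mets <- standard_loadings(library)$calibration[[g]]$metabolites
    for (met in mets) {
      rec <- library[[met]]
      pts <- data.frame(amount_nmol = numeric(), height = numeric())
      for (i in seq_len(nrow(rows))) {
        run <- batch$runs[[rows$injection_order[i]]]
        calib <- fit_ri_map(run)
        h <- extract_eic_height(run, rec$quantifier_mz, rec$retention_index,
                                calib)
        pts <- rbind(pts, data.frame(amount_nmol = rows$cal_amount_nmol[i],
                                     height = as.numeric(h)))
      }
      curves[[met]] <- suppressWarnings(fit_calibration(pts, met))
    }
  }
  curves
}
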