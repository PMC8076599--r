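#' Kovats retention-index calibration from the in-run alkane ladder
#'
#' Each injection carries seven n-alkanes (C12, C15, C19, C22, C28, C33,
#' C36) whose retention times anchor the retention-time to
#' retention-index map for that run.  Because the oven program is a
#' single linear temperature ramp, the non-isothermal Kovats index is
#' piecewise linear in retention time between consecutive anchors
#' (RI of the Cn alkane is 100 n by definition).
#'
#' @name ri_calibration
NULL

#' Fit a retention-index calibration from detected alkane peaks
#'
#' @param alkane_peaks data.frame with columns `carbon_number` and
#'   `rt_seconds` (one row per detected alkane; order irrelevant), or a
#'   `chromatogram_run` whose `alkane_rts` field is used.
#' @return An `ri_calibration` object: data.frame `carbon_number`,
#'   `rt_seconds`, sorted by carbon number.  A missing intermediate
#'   alkane degrades to the remaining anchors with a warning; fewer than
#'   two anchors or non-monotone times are hard failures.
#' @export
fit_ri_map <- function(alkane_peaks) {
  if (inherits(alkane_peaks, "chromatogram_run"))
    alkane_peaks <- data.frame(
      carbon_number = as.integer(sub("^C", "", names(alkane_peaks$alkane_rts))),
      rt_seconds = unname(alkane_peaks$alkane_rts))
  stopifnot(is.data.frame(alkane_peaks),
            all(c("carbon_number", "rt_seconds") %in% names(alkane_peaks)))
  a <- alkane_peaks[order(alkane_peaks$carbon_number),
                    c("carbon_number", "rt_seconds")]
  a$carbon_number <- as.integer(a$carbon_number)
  a$rt_seconds <- as.numeric(a$rt_seconds)
  a <- a[!duplicated(a$carbon_number), ]
  if (nrow(a) < 2)
    stop("retention-index calibration requires at least 2 alkane anchors")
  if (any(diff(a$rt_seconds) <= 0))
    stop("alkane retention times must increase with carbon number")
  expected <- c(12, 15, 19, 22, 28, 33, 36)
  missing <- setdiff(expected, a$carbon_number)
  if (length(missing) > 0)
    warning(sprintf("alkane ladder missing C%s; proceeding with %d anchors",
                    paste(missing, collapse = ", C"), nrow(a)))
  rownames(a) <- NULL
  structure(a, class = c("ri_calibration", "data.frame"))
}

#' Convert retention times to Kovats retention indices
#'
#' Linear interpolation between the bracketing alkane anchors:
#' for `t` between anchors `(n_a, t_a)` and `(n_b, t_b)`,
#' `RI = 100 n_a + 100 (n_b - n_a) (t - t_a) / (t_b - t_a)`.
#' Times outside the ladder are linearly extrapolated from the nearest
#' segment and flagged; identification treats extrapolated indices as
#' lower confidence.
#'
#' @param retention_time Numeric vector of retention times (s); must be
#'   positive.
#' @param calib An `ri_calibration`.
#' @return Numeric vector of retention indices with a logical attribute
#'   `"extrapolated"` marking values outside the ladder.
#' @export
#' @examples
#' cal <- fit_ri_map(data.frame(carbon_number = c(12, 15),
#'                              rt_seconds = c(390, 487.5)))
#' assign_ri(438.75, cal)   # midpoint -> 1350
assign_ri <- function(retention_time, calib) {
  stopifnot(inherits(calib, "ri_calibration"))
  if (any(retention_time <= 0)) stop("retention times must be positive")
  tt <- calib$rt_seconds
  nn <- 100 * calib$carbon_number
  # segment index: clamp to nearest segment for extrapolation
  seg <- findInterval(retention_time, tt, all.inside = TRUE)
  ri <- nn[seg] + (nn[seg + 1] - nn[seg]) *
    (retention_time - tt[seg]) / (tt[seg + 1] - tt[seg])
  extrap <- retention_time < tt[1] | retention_time > tt[length(tt)]
  attr(ri, "extrapolated") <- extrap
  ri
}

#' Write / read a retention-index calibration as two-column TSV
#' @param calib An `ri_calibration`.
#' @param path File path.
#' @return `path` (write) or an `ri_calibration` (read).
#' @export
write_ri_calibration <- function(calib, path) {
  utils::write.table(as.data.frame(calib), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ri_calibration
#' @export
read_ri_calibration <- function(path) {
  fit_ri_map(utils::read.delim(path))
}
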