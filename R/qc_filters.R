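#' Batch quality control
#'
#' The QC rules applied before any biological analysis: the ribitol
#' internal-standard gate, removal of peaks drifting with injection
#' order, removal of column contaminants seen in blanks, and stripping
#' of the internal-standard and alkane rows from the analysis matrix.
#'
#' @name qc_filters
NULL

#' Ribitol internal-standard gate
#'
#' Ribitol is spiked into every biological extract; a sample whose
#' ribitol signal deviates from the batch reference by more than the
#' tolerance indicates a failed extraction and is discarded.  The batch
#' median is used as the reference -- it is robust to the very outliers
#' the gate removes.
#'
#' @param ribitol_heights Named numeric vector (sample id -> ribitol
#'   height; `NA` marks a missing internal standard).
#' @param tolerance Maximum fractional deviation from the batch median
#'   (default 0.10).
#' @return data.frame `sample_id`, `ribitol_height`, `deviation`,
#'   `keep`, `reason`.
#' @export
ribitol_gate <- function(ribitol_heights, tolerance = 0.10) {
  med <- stats::median(ribitol_heights, na.rm = TRUE)
  dev <- abs(ribitol_heights - med) / med
  keep <- !is.na(ribitol_heights) & dev <= tolerance
  reason <- rep(NA_character_, length(ribitol_heights))
  reason[is.na(ribitol_heights)] <- "IS missing"
  reason[!is.na(ribitol_heights) & dev > tolerance] <-
    sprintf("IS deviation %.1f%% > %.0f%%",
            100 * dev[!is.na(ribitol_heights) & dev > tolerance],
            100 * tolerance)
  data.frame(sample_id = names(ribitol_heights),
             ribitol_height = unname(ribitol_heights),
             deviation = unname(dev), keep = unname(keep),
             reason = unname(reason), row.names = NULL)
}

#' Remove peaks drifting with injection order
#'
#' A metabolite row is an instrument artefact (accumulating column or
#' septum bleed) if its abundance rises monotonically with injection
#' order *independently of any biological variable* -- i.e. the rank
#' correlation with injection order reaches the threshold in every role
#' with enough injections, including blanks and pooled QC samples.  A
#' genuine substrate that increases only in transporter samples is
#' retained because its association is role-dependent.
#'
#' @param matrix_values Numeric matrix (metabolites x samples).
#' @param manifest data.frame with `sample_id`, `role`,
#'   `injection_order` covering the matrix columns.
#' @param threshold Spearman correlation threshold (default 0.8).
#' @param min_per_role Minimum injections for a role to participate
#'   (default 3).
#' @return List `values` (filtered matrix), `removed` (character).
#' @export
remove_drift_peaks <- function(matrix_values, manifest, threshold = 0.8,
                               min_per_role = 3) {
  m <- manifest[match(colnames(matrix_values), manifest$sample_id), ]
  roles <- split(seq_len(ncol(matrix_values)), m$role)
  roles <- roles[vapply(roles, length, 0L) >= min_per_role]
  # role-independence is only demonstrable against samples with no
  # biology (QC pools, standards, blanks); without any, a time trend
  # cannot be told apart from a biological change
  if (!any(names(roles) %in% c("qc_pool", "standard_mix", "blank"))) {
    warning("no non-biological roles present; drift filter skipped")
    return(list(values = matrix_values, removed = character()))
  }
  drift_row <- function(v) {
    if (length(roles) == 0) return(FALSE)
    all(vapply(roles, function(idx) {
      if (stats::sd(v[idx]) == 0) return(FALSE)
      stats::cor(v[idx], m$injection_order[idx], method = "spearman") >=
        threshold
    }, logical(1)))
  }
  removed <- rownames(matrix_values)[apply(matrix_values, 1, drift_row)]
  list(values = matrix_values[!rownames(matrix_values) %in% removed, ,
                              drop = FALSE],
       removed = removed)
}

#' Remove column contaminants observed in blank injections
#'
#' Rows whose mean blank signal reaches `threshold` (default 10%) of the
#' mean biological-sample signal are instrument contaminants and are
#' removed.  Blank values censored at the detection floor are treated as
#' zero signal here (they are below detection, and counting the floor
#' itself would delete every low-abundance metabolite).
#'
#' @param matrix_values Numeric matrix (metabolites x biological
#'   samples).
#' @param blank_values Numeric matrix (metabolites x blanks), same rows.
#' @param censored_blanks Optional logical matrix marking censored blank
#'   cells (treated as 0).
#' @param threshold Blank/sample mean ratio for removal; the boundary
#'   case (ratio exactly at threshold) is removed (default 0.10).
#' @return List `values`, `removed`.
#' @export
blank_subtraction <- function(matrix_values, blank_values,
                              censored_blanks = NULL, threshold = 0.10) {
  if (is.null(blank_values) || ncol(blank_values) == 0) {
    warning("no blank injections in batch; blank subtraction skipped")
    return(list(values = matrix_values, removed = character()))
  }
  bv <- blank_values
  if (!is.null(censored_blanks)) bv[censored_blanks] <- 0
  ratio <- rowMeans(bv) / pmax(rowMeans(matrix_values), 1e-12)
  removed <- rownames(matrix_values)[ratio >= threshold]
  list(values = matrix_values[!rownames(matrix_values) %in% removed, ,
                              drop = FALSE],
       removed = removed)
}

#' Strip internal-standard and alkane rows from the analysis matrix
#'
#' The ribitol internal standard and the n-alkane RI calibrants are
#' removed from the biological analysis matrix; the ribitol row is kept
#' aside as the negative-control channel that profiling re-attaches to
#' every output (any deviation of its fold-change from 1 +/- 0.1 flags a
#' normalisation problem).
#'
#' @param matrix_values Numeric matrix (metabolites x samples).
#' @param library A `metabolite_library` (identifies alkane/IS rows).
#' @return List `values` (stripped matrix), `ribitol` (named numeric
#'   vector or NULL), `removed` (character).
#' @export
strip_internal_peaks <- function(matrix_values, library) {
  internal <- names(library)[vapply(library, function(r)
    r$class %in% c("alkane", "internal_standard"), logical(1))]
  present <- intersect(rownames(matrix_values), internal)
  ribitol <- if ("Ribitol" %in% rownames(matrix_values))
    matrix_values["Ribitol", ] else NULL
  list(values = matrix_values[!rownames(matrix_values) %in% internal, ,
                              drop = FALSE],
       ribitol = ribitol, removed = present)
}

#' Full batch QC pass
#'
#' Applies, in order: the ribitol gate (biological and QC samples), drift
#' -peak removal, blank subtraction and internal-peak stripping.  The
#' pass is idempotent.
#'
#' @param mat An `abundance_matrix` (see [build_abundance_matrix()]).
#' @param library A `metabolite_library`.
#' @param ribitol_tolerance,drift_threshold,blank_threshold Rule
#'   thresholds.
#' @return A `qc_report` list: the filtered `abundance_matrix` in
#'   `$matrix` (biological samples only), plus `$gate`, `$drift_removed`,
#'   `$blank_removed`, `$internal_removed`, `$ribitol` (retained
#'   negative-control row) and `$log` (character).
#' @export
qc_filter <- function(mat, library, ribitol_tolerance = 0.10,
                      drift_threshold = 0.8, blank_threshold = 0.10) {
  s <- mat$samples
  log <- character()
  bio_idx <- which(s$role %in% c("transporter", "uninjected"))
  gate_idx <- which(s$role %in% c("transporter", "uninjected", "qc_pool"))
  rib <- setNames(s$ribitol_height[gate_idx], s$sample_id[gate_idx])
  gate <- ribitol_gate(rib, ribitol_tolerance)
  drop_ids <- gate$sample_id[!gate$keep]
  log <- c(log, sprintf("ribitol gate: %d/%d samples discarded",
                        length(drop_ids), nrow(gate)))
  keep_cols <- !(s$sample_id %in% drop_ids)
  v <- mat$values[, keep_cols, drop = FALSE]
  cen <- mat$censored[, keep_cols, drop = FALSE]
  s <- s[keep_cols, , drop = FALSE]

  dr <- remove_drift_peaks(v, s, drift_threshold)
  log <- c(log, sprintf("drift filter: removed %d row(s): %s",
                        length(dr$removed),
                        paste(dr$removed, collapse = ", ")))
  v <- dr$values
  cen <- cen[rownames(v), , drop = FALSE]

  blank_cols <- s$role == "blank"
  bio_cols <- s$role %in% c("transporter", "uninjected")
  bl <- blank_subtraction(v[, bio_cols, drop = FALSE],
                          v[, blank_cols, drop = FALSE],
                          cen[, blank_cols, drop = FALSE])
  log <- c(log, sprintf("blank filter: removed %d row(s): %s",
                        length(bl$removed),
                        paste(bl$removed, collapse = ", ")))
  v <- v[!rownames(v) %in% bl$removed, , drop = FALSE]
  cen <- cen[rownames(v), , drop = FALSE]

  st <- strip_internal_peaks(v, library)
  out_cols <- s$role %in% c("transporter", "uninjected")
  res <- list(values = st$values[, out_cols, drop = FALSE],
              censored = cen[rownames(st$values), out_cols, drop = FALSE],
              samples = s[out_cols, , drop = FALSE])
  class(res) <- "abundance_matrix"
  structure(list(matrix = res, gate = gate, drift_removed = dr$removed,
                 blank_removed = bl$removed, internal_removed = st$removed,
                 ribitol = if (is.null(st$ribitol)) NULL else
                   st$ribitol[s$sample_id[out_cols]],
                 log = log),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
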