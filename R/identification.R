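#' Identification parameters
#'
#' Thresholds of the three-criterion identification procedure.  The
#' major trimethylsilyl reagent ions at m/z 73 and 147 are present in
#' virtually every derivatised spectrum and are excluded from all
#' decisive comparisons.
#'
#' @param ri_window Candidate admission RI window (default 4).
#' @param centroid_distance Merge radius (RI units) for grouping the same
#'   component across samples into one matrix row (default 1).
#' @param min_area Minimum peak area (default 1000).
#' @param qualifier_ratio_tolerance Maximum per-ion ratio error for a
#'   qualifier ion to count as correct (default 0.30).
#' @param min_correct_qualifiers Minimum number of correct-ratio
#'   qualifier ions (default 2).
#' @param max_avg_ratio_error Maximum mean qualifier ratio error
#'   (default 0.70).
#' @param min_similarity_product Candidate admission gate on the forward
#'   score, as a fraction (default 0.60, i.e. forward score >= 600).
#' @param criterion1_ri_tol RI tolerance for criterion 1 (default 3.0).
#' @param criterion1_min_mz_peaks Characteristic library ions required in
#'   the query for criterion 1 (default 4).
#' @param criterion1_min_score Forward-score threshold for criterion 1
#'   (default 850).
#' @param criterion3_min_reverse Reverse-score threshold for criterion 3
#'   (default 700).
#' @param min_abundance Minimum deconvolved abundance (default 500).
#' @param excluded_mz Ions excluded from all spectral comparisons
#'   (fixed: 73 and 147).
#' @return An `identification_params` list.
#' @export
identification_params <- function(ri_window = 4, centroid_distance = 1,
                                  min_area = 1000,
                                  qualifier_ratio_tolerance = 0.30,
                                  min_correct_qualifiers = 2,
                                  max_avg_ratio_error = 0.70,
                                  min_similarity_product = 0.60,
                                  criterion1_ri_tol = 3.0,
                                  criterion1_min_mz_peaks = 4,
                                  criterion1_min_score = 850,
                                  criterion3_min_reverse = 700,
                                  min_abundance = 500,
                                  excluded_mz = c(73L, 147L)) {
  structure(list(ri_window = ri_window, centroid_distance = centroid_distance,
                 min_area = min_area,
                 qualifier_ratio_tolerance = qualifier_ratio_tolerance,
                 min_correct_qualifiers = min_correct_qualifiers,
                 max_avg_ratio_error = max_avg_ratio_error,
                 min_similarity_product = min_similarity_product,
                 criterion1_ri_tol = criterion1_ri_tol,
                 criterion1_min_mz_peaks = criterion1_min_mz_peaks,
                 criterion1_min_score = criterion1_min_score,
                 criterion3_min_reverse = criterion3_min_reverse,
                 min_abundance = min_abundance,
                 excluded_mz = as.integer(excluded_mz)),
            class = "identification_params")
}

.strip_excluded <- function(spec, excluded_mz) {
  spec[!spec$mz %in% excluded_mz, , drop = FALSE]
}

# weighted intensity: w(mz, I) = sqrt(I) * mz -- emphasises heavier,
# more diagnostic fragments over abundant low-mass ions
.weighted <- function(spec) sqrt(pmax(spec$rel_intensity, 0)) * spec$mz

#' Forward spectral match score
#'
#' Weighted cosine similarity over the union of query and library ions
#' (weights `sqrt(intensity) x m/z`), scaled to 0-1000.  A self-match
#' scores exactly 1000; disjoint ion sets score 0.  Ions at m/z 73 and
#' 147 are removed first.
#'
#' @param query,library_spectrum data.frames with columns `mz`,
#'   `rel_intensity`.
#' @param params An [identification_params()] list.
#' @return Score in \[0, 1000\].
#' @export
forward_score <- function(query, library_spectrum,
                          params = identification_params()) {
  q <- .strip_excluded(query, params$excluded_mz)
  l <- .strip_excluded(library_spectrum, params$excluded_mz)
  if (nrow(q) == 0 || nrow(l) == 0) return(0)
  mz <- union(q$mz, l$mz)
  qv <- lv <- numeric(length(mz))
  qv[match(q$mz, mz)] <- .weighted(q)
  lv[match(l$mz, mz)] <- .weighted(l)
  denom <- sqrt(sum(qv^2)) * sqrt(sum(lv^2))
  if (denom == 0) return(0)
  1000 * sum(qv * lv) / denom
}

#' Reverse (head-to-tail) spectral match score
#'
#' The same weighted cosine restricted to the library's ions only:
#' query-only ions (contaminants, co-elution residue) are ignored, so a
#' query that is a superset of the library still scores the maximum.
#' Scaled to 0-999.
#'
#' @inheritParams forward_score
#' @return Score in \[0, 999\].
#' @export
reverse_score <- function(query, library_spectrum,
                          params = identification_params()) {
  l <- .strip_excluded(library_spectrum, params$excluded_mz)
  q <- .strip_excluded(query, params$excluded_mz)
  if (nrow(q) == 0 || nrow(l) == 0) return(0)
  q <- q[q$mz %in% l$mz, , drop = FALSE]
  if (nrow(q) == 0) return(0)
  mz <- l$mz
  qv <- lv <- numeric(length(mz))
  qv[match(q$mz, mz)] <- .weighted(q)
  lv <- .weighted(l)
  denom <- sqrt(sum(qv^2)) * sqrt(sum(lv^2))
  if (denom == 0) return(0)
  999 * sum(qv * lv) / denom
}

#' Qualifier-ion ratio validation
#'
#' The library's qualifier ions are its most intense non-excluded ions
#' other than the quantifier.  For each, the query/library intensity
#' ratios to the quantifier ion are compared:
#' `error = |query_ratio - library_ratio| / library_ratio`.  The check
#' passes iff at least `min_correct_qualifiers` ions have error within
#' the per-ion tolerance *and* the mean error does not exceed
#' `max_avg_ratio_error`.
#'
#' @param query Query spectrum (data.frame `mz`, `rel_intensity`).
#' @param record A `metabolite_record` (defines quantifier and spectrum).
#' @param params An [identification_params()] list.
#' @param n_qualifiers Number of qualifier ions examined (default 3).
#' @return List `pass` (logical), `errors` (named per-ion relative
#'   errors), `reason` (character, when failing outright).
#' @export
qualifier_check <- function(query, record, params = identification_params(),
                            n_qualifiers = 3) {
  lib <- .strip_excluded(record$spectrum, params$excluded_mz)
  quant <- record$quantifier_mz
  lq <- lib$rel_intensity[match(quant, lib$mz)]
  quals <- lib[lib$mz != quant, , drop = FALSE]
  quals <- quals[order(-quals$rel_intensity), , drop = FALSE]
  quals <- utils::head(quals, n_qualifiers)
  if (nrow(quals) < params$min_correct_qualifiers)
    return(list(pass = FALSE, errors = numeric(0),
                reason = "library defines too few qualifier ions"))
  qq <- query$rel_intensity[match(quant, query$mz)]
  if (is.na(qq) || qq <= 0)
    return(list(pass = FALSE, errors = numeric(0),
                reason = "quantifier ion absent in query"))
  errs <- vapply(seq_len(nrow(quals)), function(j) {
    lib_ratio <- quals$rel_intensity[j] / lq
    qi <- query$rel_intensity[match(quals$mz[j], query$mz)]
    if (is.na(qi)) qi <- 0
    abs(qi / qq - lib_ratio) / lib_ratio
  }, 0)
  names(errs) <- quals$mz
  n_ok <- sum(errs <= params$qualifier_ratio_tolerance)
  pass <- n_ok >= params$min_correct_qualifiers &&
    mean(errs) <= params$max_avg_ratio_error
  list(pass = pass, errors = errs, reason = NA_character_)
}

#' Identify a detected peak against the reference library
#'
#' Implements the tiered decision procedure:
#'
#' * **Criterion 1** -- correct retention index (within 3.0 RI units of
#'   a library entry), at least 4 characteristic library ions present,
#'   forward score >= 850, deconvolved abundance >= 500, and acceptable
#'   symmetry about the peak centroid.
#' * **Criterion 2** -- criterion 1 plus confirmation by an authentic
#'   standard run in the same batch (the 21-component standard mix).
#' * **Criterion 3** -- for peaks failing criteria 1-2: reverse
#'   (head-to-tail) score >= 700 and the two most abundant non-excluded
#'   library ions present in the query.
#'
#' Candidates enter consideration when their RI error is within
#' `ri_window` and the forward score passes the similarity-product gate
#' (>= 600).  Ties resolve to the highest criterion tier, then the
#' higher forward score, then the smaller RI error.  Peaks with an
#' extrapolated RI (outside the alkane ladder) are never awarded
#' criterion 1 or 2.
#'
#' @param peak One-row slice of a peak table: needs `height` (or a
#'   deconvolved abundance), `symmetry`, `assigned_ri` and a `spectrum`
#'   data.frame.  Accepts a list or one-row data.frame.
#' @param library A `metabolite_library`.
#' @param params An [identification_params()] list.
#' @param standards Character vector of metabolite names confirmed by a
#'   same-batch standard (enables criterion 2).
#' @param ri_extrapolated Logical: the peak's RI came from extrapolation
#'   beyond the ladder.
#' @return An `identified_metabolite` list: `name`, `variant`,
#'   `criterion` (1, 2, 3 or `"unidentified"`), `forward_score`,
#'   `reverse_score`, `ri_error`, `qualifier_pass`,
#'   `standard_confirmed`, `is_conversion_product`, `parents`.
#' @export
identify_peak <- function(peak, library, params = identification_params(),
                          standards = character(),
                          ri_extrapolated = FALSE) {
  if (is.data.frame(peak)) {
    spec <- peak$spectrum[[1]]
    peak <- as.list(peak[1, setdiff(names(peak), "spectrum")])
    peak$spectrum <- spec
  }
  stopifnot(!is.null(peak$assigned_ri))
  cand <- library_variants(library)
  cand$ri_error <- abs(cand$retention_index - peak$assigned_ri)
  cand <- cand[cand$ri_error <= params$ri_window, , drop = FALSE]
  unid <- list(name = NA_character_, variant = NA_character_,
               criterion = "unidentified", forward_score = NA_real_,
               reverse_score = NA_real_, ri_error = NA_real_,
               qualifier_pass = NA, standard_confirmed = FALSE,
               is_conversion_product = FALSE, parents = character())
  class(unid) <- "identified_metabolite"
  if (nrow(cand) == 0) return(unid)

  abundance <- if (!is.null(peak$height)) peak$height else peak$abundance
  symmetry <- if (!is.null(peak$symmetry)) peak$symmetry else 1
  sym_ok <- symmetry >= 0.5
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    rec <- library[[cand$name[i]]]
    fwd <- forward_score(peak$spectrum, rec$spectrum, params)
    if (fwd < 1000 * params$min_similarity_product) next
    rev <- reverse_score(peak$spectrum, rec$spectrum, params)
    qual <- qualifier_check(peak$spectrum, rec, params)
    lib_sp <- .strip_excluded(rec$spectrum, params$excluded_mz)
    n_present <- sum(lib_sp$mz %in% peak$spectrum$mz)
    c1 <- !ri_extrapolated &&
      cand$ri_error[i] <= params$criterion1_ri_tol &&
      n_present >= params$criterion1_min_mz_peaks &&
      fwd >= params$criterion1_min_score &&
      abundance >= params$min_abundance && sym_ok && qual$pass
    c2 <- c1 && rec$name %in% standards
    top2 <- utils::head(lib_sp$mz[order(-lib_sp$rel_intensity)], 2)
    c3 <- !c1 && rev >= params$criterion3_min_reverse &&
      all(top2 %in% peak$spectrum$mz)
    tier <- if (c2) 2L else if (c1) 1L else if (c3) 3L else NA_integer_
    if (is.na(tier)) next
    rank <- c(`2` = 3, `1` = 2, `3` = 1)[as.character(tier)]
    key <- c(rank, fwd, -cand$ri_error[i])
    if (is.null(best) || .lex_gt(key, best$key)) {
      best <- list(key = key, name = cand$name[i], variant = cand$variant[i],
                   criterion = tier, forward_score = fwd, reverse_score = rev,
                   ri_error = cand$ri_error[i], qualifier_pass = qual$pass,
                   standard_confirmed = rec$name %in% standards)
    }
  }
  if (is.null(best)) return(unid)
  out <- list(name = best$name, variant = best$variant,
              criterion = best$criterion, forward_score = best$forward_score,
              reverse_score = best$reverse_score, ri_error = best$ri_error,
              qualifier_pass = best$qualifier_pass,
              standard_confirmed = best$standard_confirmed,
              is_conversion_product = FALSE, parents = character())
  class(out) <- "identified_metabolite"
  out
}

.lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Annotate known GC-MS conversion products
#'
#' Ornithine and pyroglutamic acid arise during sample work-up from
#' arginine and from glutamate/glutamine respectively; they are retained
#' in all outputs (heat maps include them) but flagged with their parent
#' metabolites.
#'
#' @param identified List of `identified_metabolite` objects, or a
#'   character vector of metabolite names (returned annotated as a
#'   data.frame).
#' @param library A `metabolite_library`.
#' @return The input with `is_conversion_product` and `parents` filled
#'   in (for a character vector: a data.frame `name`,
#'   `is_conversion_product`, `parents`).
#' @export
map_conversion_products <- function(identified, library) {
  parent_map <- list()
  for (rec in library) {
    cp <- rec$conversion_products
    for (j in seq_len(nrow(cp)))
      parent_map[[cp$product[j]]] <- c(parent_map[[cp$product[j]]], rec$name)
  }
  annotate <- function(name) {
    p <- parent_map[[name]]
    list(is_conversion_product = !is.null(p),
         parents = if (is.null(p)) character() else p)
  }
  if (is.character(identified)) {
    ann <- lapply(identified, annotate)
    return(data.frame(
      name = identified,
      is_conversion_product = vapply(ann, `[[`, FALSE, "is_conversion_product"),
      parents = vapply(ann, function(a)
        paste(a$parents, collapse = ";"), "")))
  }
  lapply(identified, function(id) {
    if (!is.na(id$name)) {
      a <- annotate(id$name)
      id$is_conversion_product <- a$is_conversion_product
      id$parents <- a$parents
    }
    id
  })
}

#' Identify every peak of a rendered run
#'
#' Convenience wrapper: fits the run's alkane RI calibration, assigns
#' retention indices, and identifies each peak.
#'
#' @param run A `chromatogram_run`.
#' @param library A `metabolite_library`.
#' @param params An [identification_params()] list.
#' @param standards Metabolite names confirmed by same-batch standards.
#' @return data.frame: one row per peak with identity, criterion tier,
#'   scores, RI error and flags.
#' @export
identify_run <- function(run, library, params = identification_params(),
                         standards = character()) {
  calib <- fit_ri_map(run)
  ris <- assign_ri(run$peaks$rt, calib)
  extrap <- attr(ris, "extrapolated")
  rows <- lapply(seq_len(nrow(run$peaks)), function(i) {
    pk <- list(height = run$peaks$height[i], symmetry = 1,
               assigned_ri = ris[i], spectrum = run$peaks$spectrum[[i]])
    id <- identify_peak(pk, library, params, standards, extrap[i])
    data.frame(peak = i, rt = run$peaks$rt[i], assigned_ri = ris[i],
               name = id$name, variant = id$variant,
               criterion = as.character(id$criterion),
               forward_score = id$forward_score,
               reverse_score = id$reverse_score, ri_error = id$ri_error,
               standard_confirmed = id$standard_confirmed)
  })
  res <- do.call(rbind, rows)
  ann <- map_conversion_products(ifelse(is.na(res$name), "", res$name), library)
  res$is_conversion_product <- ann$is_conversion_product
  res$parents <- ann$parents
  res
}
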