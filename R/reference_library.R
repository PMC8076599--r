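#' @title Reference metabolite library and transporter fixtures
#' @description Accessors for the packaged reference data shared by the
#'   simulator and the analysis pipeline: a metabolite library (names,
#'   Kovats retention indices, fragment spectra, quantifier EIC ions,
#'   response-factor classes, TMS-variant splits and known GC-MS
#'   conversion products) and a set of transporter kinetic fixtures.
#' @details Quantifier ions for the 20 proteinogenic amino acids are the
#'   EIC ions used for quantification in single-quadrupole GC-MS work
#'   (e.g. valine 144, leucine/isoleucine 158).  Fragment spectra and
#'   retention indices not established in the literature are fixed
#'   synthetic stand-ins; they are flagged as such in the fixture header
#'   and downstream code must not rely on their shapes beyond the
#'   documented invariants (non-empty, m/z within the 40-600 scan range,
#'   base peak normalised to 1, quantifier present).
#' @name reference_library
NULL

#' Load the packaged metabolite reference library
#'
#' Reads the versioned JSON fixture shipped with the package and validates
#' every record.  The library covers the 20 proteinogenic amino acids,
#' their main GC-MS by-products (ornithine from arginine, pyroglutamic
#' acid from glutamate/glutamine), the ribitol internal standard, the
#' seven n-alkane ladder components (C12-C36) and several abundant oocyte
#' metabolites (citrate, pantothenic acid, sucrose, 2-aminoadipate).
#'
#' @param path Optional path to an alternative library JSON file.
#' @return An object of class `metabolite_library`: a named list of
#'   `metabolite_record` lists with fields `name`, `class`,
#'   `retention_index`, `quantifier_mz`, `rf_class`, `molecular_weight`,
#'   `endogenous_pmol_per_oocyte`, `endogenous_um`, `spectrum`
#'   (data.frame `mz`, `rel_intensity`), `tms_variants` (data.frame
#'   `label`, `proportion`, `retention_index`) and `conversion_products`
#'   (data.frame `product`, `fraction`).
#' @export
#' @examples
#' lib <- load_reference_library()
#' lib[["Valine"]]$quantifier_mz    # 144
load_reference_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "metabolite_library.json",
                        package = "oometab", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  recs <- raw$records
  out <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    r <- lapply(recs, function(col) if (is.data.frame(col)) col[i, ] else col[[i]])
    rec <- list(
      name = r$name, class = r$class,
      retention_index = as.numeric(r$retention_index),
      quantifier_mz = as.integer(r$quantifier_mz),
      rf_class = r$rf_class,
      molecular_weight = as.numeric(r$molecular_weight),
      endogenous_pmol_per_oocyte = as.numeric(r$endogenous_pmol_per_oocyte),
      endogenous_um = as.numeric(r$endogenous_um),
      spectrum = as.data.frame(recs$spectrum[[i]]),
      tms_variants = as.data.frame(recs$tms_variants[[i]]),
      conversion_products = as.data.frame(recs$conversion_products[[i]]))
    class(rec) <- "metabolite_record"
    validate_metabolite_record(rec)
    out[[i]] <- rec
  }
  names(out) <- vapply(out, `[[`, "", "name")
  class(out) <- "metabolite_library"
  out
}

#' Validate a metabolite record against the library invariants
#'
#' Hard-fails (naming the offending record) if the spectrum is empty or
#' outside the 40-600 m/z scan range, the base peak is not normalised to
#' 1, the quantifier ion is missing from the spectrum, TMS-variant
#' proportions do not sum to 1, or an amino acid other than aspartate or
#' serine lacks a dominant (>= 0.8) TMS variant.
#'
#' @param rec A `metabolite_record`.
#' @return `rec`, invisibly.
#' @export
validate_metabolite_record <- function(rec) {
  fail <- function(msg) stop(sprintf("library record '%s': %s", rec$name, msg),
                             call. = FALSE)
  sp <- rec$spectrum
  if (is.null(sp) || nrow(sp) == 0) fail("empty spectrum")
  if (any(sp$mz < 40 | sp$mz > 600)) fail("spectrum m/z outside scan range 40-600")
  if (any(sp$rel_intensity <= 0 | sp$rel_intensity > 1))
    fail("relative intensities must lie in (0, 1]")
  if (abs(max(sp$rel_intensity) - 1) > 1e-9)
    fail("spectrum base peak not normalised to 1")
  if (!rec$quantifier_mz %in% sp$mz) fail("quantifier ion absent from spectrum")
  tv <- rec$tms_variants
  if (abs(sum(tv$proportion) - 1) > 1e-9)
    fail("TMS variant proportions do not sum to 1")
  multi_ok <- c("Aspartic acid", "Serine")
  if (rec$class == "amino_acid" && !rec$name %in% multi_ok &&
      max(tv$proportion) < 0.8)
    fail("expected a dominant (>= 0.8) TMS variant")
  if (rec$class == "alkane") {
    n <- as.integer(sub("^C(\\d+) alkane$", "\\1", rec$name))
    if (rec$retention_index != 100 * n)
      fail("alkane retention index must be 100 x carbon number")
  }
  invisible(rec)
}

#' Load the packaged transporter model fixtures
#'
#' @param path Optional path to an alternative transporter JSON file.
#' @return An object of class `transporter_models`: a named list of
#'   `transporter_model` lists with fields `name`, `mechanism` (one of
#'   `"symport"`, `"antiport"`, `"uniport"`, `"none"`), `stoichiometry`
#'   (descriptive metadata only -- ion coupling is not simulated),
#'   `exchange_rate_per_h` (antiporters only) and `substrates`
#'   (data.frame `substrate`, `Km` in uM, `Vmax` in pmol/oocyte/h).
#' @export
#' @examples
#' tm <- load_transporter_models()
#' tm[["LAT1-like"]]$mechanism      # "antiport"
load_transporter_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transporter_models.json",
                        package = "oometab", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  mods <- raw$models
  out <- vector("list", nrow(mods))
  for (i in seq_len(nrow(mods))) {
    m <- list(name = mods$name[i], mechanism = mods$mechanism[i],
              stoichiometry = mods$stoichiometry[i],
              exchange_rate_per_h = as.numeric(mods$exchange_rate_per_h[i]),
              substrates = as.data.frame(mods$substrates[[i]]))
    if (nrow(m$substrates) == 0)
      m$substrates <- data.frame(substrate = character(), Km = numeric(),
                                 Vmax = numeric())
    stopifnot(m$mechanism %in% c("symport", "antiport", "uniport", "none"))
    if (m$mechanism == "none" && nrow(m$substrates) > 0)
      stop("mechanism 'none' must have an empty substrate map")
    if (nrow(m$substrates) > 0 &&
        (any(m$substrates$Km <= 0) || any(m$substrates$Vmax < 0)))
      stop(sprintf("transporter '%s': Km must be > 0 and Vmax >= 0", m$name))
    class(m) <- "transporter_model"
    out[[i]] <- m
  }
  names(out) <- vapply(out, `[[`, "", "name")
  class(out) <- "transporter_models"
  out
}

#' Library entries expanded per TMS variant
#'
#' Identification works at the level of chromatographic peaks, and a
#' metabolite with several TMS derivatives (aspartate 2TMS/3TMS, serine
#' 2TMS/3TMS) produces one peak per variant.  This helper flattens the
#' library into one candidate row per (metabolite, variant).
#'
#' @param library A `metabolite_library`.
#' @return data.frame with columns `name`, `variant`, `retention_index`,
#'   `proportion`, `quantifier_mz`, `rf_class`, `class`.
#' @export
library_variants <- function(library) {
  do.call(rbind, lapply(library, function(rec) {
    tv <- rec$tms_variants
    data.frame(name = rec$name, variant = tv$label,
               retention_index = tv$retention_index,
               proportion = tv$proportion,
               quantifier_mz = rec$quantifier_mz,
               rf_class = rec$rf_class, class = rec$class,
               row.names = NULL)
  }))
}

#' Numeric response factor for a response-factor class
#'
#' Instrument response (abundance units per pmol analyte) by response
#' factor group.  The low-Rf amino acids (Arg, Ala, His, Trp, Cys) give
#' several-fold less signal per mole, which is why they are loaded at 10x
#' mass in the standard mix.
#'
#' @param rf_class Character vector of `"high"`, `"medium"`, `"low"`.
#' @return Numeric vector of response factors (abundance units / pmol).
#' @export
response_factor <- function(rf_class) {
  unname(c(high = 30, medium = 15, low = 6)[rf_class])
}

#' Names of the 20 proteinogenic amino acids in the library
#' @param library A `metabolite_library`.
#' @return Character vector of amino acid names.
#' @export
amino_acid_names <- function(library) {
  names(library)[vapply(library, function(r) r$class == "amino_acid",
                        logical(1))]
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat(sprintf("<metabolite_library> %d records (%d amino acids, %d alkanes)\n",
              length(x), length(amino_acid_names(x)),
              sum(vapply(x, function(r) r$class == "alkane", logical(1)))))
  invisible(x)
}

#' @export
print.transporter_model <- function(x, ...) {
  cat(sprintf("<transporter_model> %s [%s], %d substrates\n",
              x$name, x$mechanism, nrow(x$substrates)))
  invisible(x)
}
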