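test_that("library covers the required records and passes its invariants", {
  lib <- fx_library()
  expect_gte(length(lib), 25)
  aa <- amino_acid_names(lib)
  expect_setequal(aa, c("Valine", "Leucine", "Isoleucine", "Proline",
                        "Glycine", "Serine", "Alanine", "Threonine",
                        "Aspartic acid", "Methionine", "Cysteine",
                        "Glutamic acid", "Phenylalanine", "Asparagine",
                        "Glutamine", "Arginine", "Lysine", "Histidine",
                        "Tyrosine", "Tryptophan"))
  expect_true(all(c("Ornithine", "Pyroglutamic acid", "Ribitol") %in%
                    names(lib)))
  expect_length(grep(" alkane$", names(lib)), 7)
  non_aa <- setdiff(names(lib)[vapply(lib, function(r)
    r$class == "metabolite", logical(1))], character())
  expect_gte(length(non_aa), 3)
  # validation runs on load; re-run explicitly for clarity
  for (rec in lib) expect_silent(validate_metabolite_record(rec))
})

test_that("quantifier ions match the published EIC table verbatim", {
  lib <- fx_library()
  expected <- c(Valine = 144, Leucine = 158, Isoleucine = 158, Proline = 142,
                Glycine = 174, Serine = 204, Alanine = 188, Threonine = 218,
                `Aspartic acid` = 232, Methionine = 176, Cysteine = 220,
                `Glutamic acid` = 246, Phenylalanine = 216, Asparagine = 231,
                Glutamine = 156, Arginine = 157, Lysine = 156,
                Histidine = 154, Tyrosine = 280, Tryptophan = 202)
  for (nm in names(expected))
    expect_identical(lib[[nm]]$quantifier_mz, as.integer(expected[nm]),
                     label = nm)
})

test_that("alkane anchors and by-product metadata are correct", {
  lib <- fx_library()
  for (n in c(12, 15, 19, 22, 28, 33, 36))
    expect_identical(lib[[sprintf("C%d alkane", n)]]$retention_index, 100 * n)
  glu <- lib[["Glutamic acid"]]$conversion_products
  expect_true("Pyroglutamic acid" %in% glu$product && all(glu$fraction > 0))
  arg <- lib[["Arginine"]]$conversion_products
  expect_true("Ornithine" %in% arg$product)
  rib <- lib[["Ribitol"]]
  expect_true(rib$rf_class %in% c("high", "medium", "low"))
  expect_equal(max(rib$spectrum$rel_intensity), 1)
  # only aspartate and serine lack a dominant single TMS derivative
  multi <- Filter(function(r) r$class == "amino_acid" &&
                    max(r$tms_variants$proportion) < 0.8, lib)
  expect_setequal(names(multi), c("Aspartic acid", "Serine"))
})

test_that("corrupted records fail validation naming the record", {
  rec <- fx_library()[["Valine"]]
  bad <- rec
  bad$spectrum$rel_intensity <- bad$spectrum$rel_intensity / 2
  expect_error(validate_metabolite_record(bad), "Valine.*base peak")
  bad2 <- rec
  bad2$spectrum$mz[1] <- 700L
  expect_error(validate_metabolite_record(bad2), "scan range")
  bad3 <- rec
  bad3$quantifier_mz <- 599L
  expect_error(validate_metabolite_record(bad3), "quantifier")
})

test_that("transporter fixtures encode the expected mechanisms and profiles", {
  tm <- fx_models()
  snat2 <- tm[["SNAT2-like"]]$substrates$substrate
  snat1 <- tm[["SNAT1-like"]]$substrates$substrate
  expect_true(all(c("Alanine", "Serine", "Glycine", "Proline", "Methionine",
                    "Asparagine", "Glutamine", "Leucine") %in% snat2))
  expect_false("Leucine" %in% snat1)
  expect_false("Proline" %in% snat1)
  expect_identical(tm[["LAT1-like"]]$mechanism, "antiport")
  expect_identical(tm[["ASCT2-like"]]$mechanism, "antiport")
  expect_identical(tm[["EAAT1-like"]]$mechanism, "symport")
  expect_identical(tm[["Un-injected"]]$mechanism, "none")
  expect_identical(nrow(tm[["Un-injected"]]$substrates), 0L)
  for (m in tm) {
    expect_true(all(m$substrates$Km > 0))
    expect_true(all(m$substrates$Vmax >= 0))
  }
})
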