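test_that("forward score has the self-match and orthogonality identities", {
  lib <- fx_library()
  for (nm in c("Valine", "Glutamine", "Sucrose")) {
    sp <- lib[[nm]]$spectrum
    expect_equal(forward_score(sp, sp), 1000, tolerance = 1e-9)
    expect_equal(reverse_score(sp, sp), 999, tolerance = 1e-9)
  }
  a <- data.frame(mz = c(100, 120), rel_intensity = c(1, 0.5))
  b <- data.frame(mz = c(200, 220), rel_intensity = c(1, 0.5))
  expect_identical(forward_score(a, b), 0)
  # a spectrum of only the excluded TMS reagent ions carries no information
  tms <- data.frame(mz = c(73, 147), rel_intensity = c(1, 0.6))
  expect_identical(forward_score(tms, lib[["Valine"]]$spectrum), 0)
})

test_that("scores match an independent brute-force oracle on random spectra", {
  set.seed(12)
  for (i in 1:25) {
    nq <- sample(3:10, 1); nl <- sample(3:10, 1)
    q <- data.frame(mz = sample(40:600, nq), rel_intensity = runif(nq, .05, 1))
    l <- data.frame(mz = sample(40:600, nl), rel_intensity = runif(nl, .05, 1))
    # overlap some ions so scores are non-trivial
    k <- min(nq, nl, 3)
    q$mz[seq_len(k)] <- l$mz[seq_len(k)]
    expect_equal(forward_score(q, l), oracle_cosine_score(q, l, 1000),
                 tolerance = 1e-9)
    expect_equal(reverse_score(q, l),
                 oracle_cosine_score(q, l, 999, restrict = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("a contaminated superset query keeps a perfect reverse score", {
  lib_sp <- fx_library()[["Proline"]]$spectrum
  query <- rbind(lib_sp, data.frame(mz = c(311, 497), rel_intensity = c(0.4, 0.3)))
  expect_equal(reverse_score(query, lib_sp), 999, tolerance = 1e-9)
  expect_lt(forward_score(query, lib_sp), 1000)
})

test_that("qualifier ratio validation applies both printed rules", {
  rec <- fx_library()[["Valine"]]
  exact <- qualifier_check(rec$spectrum, rec)
  expect_true(exact$pass)
  expect_equal(unname(exact$errors), rep(0, length(exact$errors)))
  distort <- function(errs) {
    lib <- rec$spectrum[!rec$spectrum$mz %in% c(73, 147), ]
    quals <- lib[lib$mz != rec$quantifier_mz, ]
    quals <- quals$mz[order(-quals$rel_intensity)][seq_along(errs)]
    sp <- rec$spectrum
    for (j in seq_along(errs)) {
      i <- sp$mz == quals[j]
      sp$rel_intensity[i] <- sp$rel_intensity[i] * (1 + errs[j])
    }
    sp
  }
  # 2 ions at 25% + 1 at 200%: mean 83% fails the average-error rule
  fail_avg <- qualifier_check(distort(c(0.25, 0.25, 2.0)), rec)
  expect_false(fail_avg$pass)
  expect_equal(mean(fail_avg$errors), 0.8333, tolerance = 1e-3)
  # 2 ions at 29% + 1 at 50%: two correct, mean 36% -- passes
  pass_two <- qualifier_check(distort(c(0.29, 0.29, 0.50)), rec)
  expect_true(pass_two$pass)
  expect_equal(mean(pass_two$errors), 0.36, tolerance = 1e-3)
  # missing quantifier fails with a reason
  no_quant <- rec$spectrum[rec$spectrum$mz != rec$quantifier_mz, ]
  expect_match(qualifier_check(no_quant, rec)$reason, "quantifier")
})

test_that("the criterion tiers assign as specified on planted peaks", {
  lib <- fx_library()
  rec <- lib[["Valine"]]
  mk_peak <- function(ri, spec = rec$spectrum, height = 5000)
    list(height = height, symmetry = 1, assigned_ri = ri, spectrum = spec)
  std <- c(amino_acid_names(lib), "Ornithine")
  # noiseless valine at its true RI, standards in batch -> criterion 2
  id <- identify_peak(mk_peak(rec$retention_index), lib, standards = std)
  expect_identical(id$name, "Valine")
  expect_identical(id$criterion, 2L)
  # without standard confirmation -> criterion 1
  id1 <- identify_peak(mk_peak(rec$retention_index), lib)
  expect_identical(id1$criterion, 1L)
  # RI off by 3.5: criterion 1 excluded, good spectrum may still reach 3
  id3 <- identify_peak(mk_peak(rec$retention_index + 3.5), lib,
                       standards = std)
  expect_identical(id3$name, "Valine")
  expect_identical(id3$criterion, 3L)
  # abundance below the deconvolved-abundance floor blocks criterion 1
  idlow <- identify_peak(mk_peak(rec$retention_index, height = 400), lib)
  expect_false(identical(idlow$criterion, 1L))
  # a spectrum of only the excluded reagent ions is unidentifiable
  tms <- data.frame(mz = c(73, 147), rel_intensity = c(1, 0.6))
  expect_identical(identify_peak(mk_peak(rec$retention_index, tms), lib)$criterion,
                   "unidentified")
})

test_that("conversion products map to their parents and others pass through", {
  lib <- fx_library()
  ann <- map_conversion_products(c("Ornithine", "Pyroglutamic acid",
                                   "Valine"), lib)
  expect_true(ann$is_conversion_product[1])
  expect_identical(ann$parents[1], "Arginine")
  expect_setequal(strsplit(ann$parents[2], ";")[[1]],
                  c("Glutamic acid", "Glutamine"))
  expect_false(ann$is_conversion_product[3])
  expect_identical(ann$parents[3], "")
})

test_that("a default batch identifies planted metabolites and nothing in blanks", {
  b <- fx_snat2_batch()
  lib <- fx_library()
  std <- c(amino_acid_names(lib), "Ornithine")
  bio <- which(b$manifest$role %in% c("transporter", "uninjected"))[1:4]
  floor <- instrument_params()$floor
  for (i in bio) {
    run <- b$runs[[i]]
    idt <- identify_run(run, lib, standards = std)
    # tiers are mutually exclusive and exhaustive per peak
    expect_true(all(idt$criterion %in% c("1", "2", "3", "unidentified")))
    planted <- run$peaks$name[run$peaks$height >= floor &
                                run$peaks$name %in% names(lib)]
    hit <- idt$name[idt$criterion %in% c("1", "2", "3")]
    expect_gte(length(intersect(planted, hit)) / length(unique(planted)),
               0.95)
  }
  blank <- b$runs[[which(b$manifest$role == "blank")[1]]]
  idb <- identify_run(blank, lib, standards = std)
  non_internal <- idb$name[idb$criterion %in% c("1", "2", "3") &
                             !grepl("alkane", idb$name)]
  expect_length(non_internal, 0)
})
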