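test_that("no transporter and no drift leaves pools constant", {
  d <- experiment_design("Un-injected", drift = FALSE, seed = 3)
  p <- simulate_pools(d, library = fx_library(), models = fx_models())
  for (r in seq_along(p))
    expect_equal(p[[r]][, "t4"], p[[r]][, "t0"], tolerance = 1e-12)
})

test_that("antiport strictly conserves the substrate-set total", {
  tm <- fx_models()
  for (tr in c("LAT1-like", "ASCT2-like")) {
    pre <- if (tr == "LAT1-like") "Isoleucine" else "Alanine"
    d <- experiment_design(tr, preload = list(substrate = pre),
                           drift = FALSE, seed = 9)
    p <- simulate_pools(d, library = fx_library(), models = tm)
    subs <- tm[[tr]]$substrates$substrate
    for (r in seq_along(p)) {
      # oracle: sums recomputed independently of the integrator state
      s0 <- sum(p[[r]][subs, "baseline"])
      for (ph in colnames(p[[r]]))
        expect_lt(abs(sum(p[[r]][subs, ph]) - s0) / s0, 1e-6)
    }
  }
})

test_that("symporter substrates are nondecreasing under constant medium", {
  # oracle: brute-force fine-step integration must agree with the default
  d <- experiment_design("SNAT2-like", timepoints = c(0, 1, 2, 3, 4),
                         drift = FALSE, seed = 4)
  p <- simulate_pools(d, library = fx_library(), models = fx_models())
  pf <- simulate_pools(d, library = fx_library(), models = fx_models(),
                       dt = 0.001)
  for (r in seq_along(p)) {
    leu <- p[[r]]["Leucine", ]
    expect_true(all(diff(leu) >= 0))
    expect_true(all(diff(pf[[r]]["Leucine", ]) >= 0))
    expect_equal(unname(p[[r]]["Leucine", "t4"]),
                 unname(pf[[r]]["Leucine", "t4"]), tolerance = 1e-3)
  }
})

test_that("un-injected drift reproduces the published 4 h fold-changes", {
  d <- experiment_design("Un-injected", seed = 21)
  p <- simulate_pools(d, library = fx_library(), models = fx_models())
  for (r in seq_along(p)) {
    fold <- p[[r]][, "t4"] / p[[r]][, "t0"]
    expect_true(all(fold[c("Valine", "Leucine", "Isoleucine")] <= 0.5))
    expect_true(all(fold[c("Aspartic acid", "Glutamine")] >= 2.0))
  }
})

test_that("noiseless rendering gives height = amount x response factor", {
  run <- fx_noiseless_run(c(Valine = 1000))
  pk <- run$peaks[run$peaks$name == "Valine", ]
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$height, 1000 * response_factor("high"))
  # and the rendered RI round-trips exactly through the alkane ladder
  calib <- fit_ri_map(run)
  expect_equal(assign_ri(pk$rt, calib),
               fx_library()[["Valine"]]$retention_index,
               tolerance = 1e-6, ignore_attr = TRUE)
  c19 <- run$alkane_rts[["C19"]]
  expect_equal(assign_ri(c19, calib), 1900, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("TMS variants and conversion products split as the library says", {
  run <- fx_noiseless_run(c(`Aspartic acid` = 1000, Arginine = 1000))
  asp <- run$peaks[run$peaks$name == "Aspartic acid", ]
  expect_identical(nrow(asp), 2L)
  expect_equal(sort(asp$height / sum(asp$height)), c(0.30, 0.70),
               tolerance = 1e-9)
  arg <- run$peaks[run$peaks$name == "Arginine", ]
  orn <- run$peaks[run$peaks$name == "Ornithine", ]
  f <- fx_library()[["Arginine"]]$conversion_products$fraction
  rf_arg <- response_factor("low"); rf_orn <- response_factor("medium")
  expect_equal(orn$height / rf_orn / (orn$height / rf_orn + arg$height / rf_arg),
               f, tolerance = 1e-9)
})

test_that("rendered RI recovery is exact without jitter, tight with it", {
  set.seed(8)
  lib <- fx_library()
  amounts <- setNames(rep(2000, 20), amino_acid_names(lib))
  # noiseless peaks: every assigned RI recovers the library RI
  run0 <- render_run(amounts, lib, role = "uninjected",
                     instrument_cv = 0, ribitol_cv = NA, ri_jitter_sd = 0)
  cal0 <- fit_ri_map(run0)
  pk0 <- run0$peaks[!grepl("alkane", run0$peaks$name), ]
  expect_true(all(abs(assign_ri(pk0$rt, cal0) - pk0$ri_true) <= 1e-6))
  # at the default 1-RI-unit jitter the vast majority stay within 3 units
  hits <- 0; total <- 0
  for (i in 1:25) {
    run <- render_run(amounts, lib, role = "uninjected",
                      instrument_cv = 0, ribitol_cv = NA, ri_jitter_sd = 1)
    calib <- fit_ri_map(run)
    pk <- run$peaks[!grepl("alkane", run$peaks$name), ]
    ris <- assign_ri(pk$rt, calib)
    hits <- hits + sum(abs(ris - pk$ri_true) <= 3)
    total <- total + nrow(pk)
  }
  expect_gte(hits / total, 0.95)
})

test_that("batch layout follows the published injection scheme", {
  b <- fx_snat2_batch()
  mf <- b$manifest
  expect_gte(sum(mf$role == "blank"), 2)
  expect_identical(sum(!is.na(mf$std_kind) & mf$std_kind == "mix"), 3L)
  qc_pos <- mf$injection_order[mf$role == "qc_pool"]
  expect_identical(qc_pos[1], 1L)
  expect_true(all(diff(qc_pos) == 9))   # after every 8 injections
  expect_identical(mf$role[1], "qc_pool")
  expect_identical(mf$role[nrow(mf)], "blank")
  # 6-point calibration series per rf class
  cal <- mf[!is.na(mf$std_kind) & mf$std_kind == "cal", ]
  expect_identical(as.integer(table(cal$cal_group)[c("high", "low", "medium")]),
                   c(6L, 6L, 6L))
  # blanks contain no library amino-acid peaks
  blanks <- Filter(function(r) r$role == "blank", b$runs)
  for (bl in blanks)
    expect_length(intersect(bl$peaks$name, amino_acid_names(fx_library())), 0)
})

test_that("batches regenerate byte-identically from the same seed", {
  d <- experiment_design("EAAT1-like", seed = 77)
  b1 <- generate_batch(d, library = fx_library(), models = fx_models())
  b2 <- generate_batch(d, library = fx_library(), models = fx_models())
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
  dir1 <- tempfile(); dir2 <- tempfile()
  write_batch(b1, dir1); write_batch(b2, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(dir2, basename(f1)))))
})

test_that("batch files round-trip through the documented text formats", {
  b <- fx_snat2_batch()
  dir <- tempfile()
  write_batch(b, dir)
  b2 <- read_batch(dir)
  expect_identical(length(b2$runs), length(b$runs))
  r1 <- b$runs[[5]]; r2 <- b2$runs[[5]]
  expect_identical(r2$sample_id, r1$sample_id)
  expect_equal(r2$peaks$height, r1$peaks$height, tolerance = 1e-12)
  expect_equal(r2$alkane_rts, r1$alkane_rts, tolerance = 1e-4)
  expect_equal(r2$peaks$spectrum[[3]]$mz, r1$peaks$spectrum[[3]]$mz)
})

test_that("rendering an unknown metabolite is a hard failure", {
  expect_error(render_run(c(Unobtainium = 10), fx_library(), "uninjected"),
               "absent from library")
})
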