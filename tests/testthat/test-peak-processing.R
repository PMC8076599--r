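# build a scan matrix from planted Gaussian components (ground truth known)
plant_scans <- function(n_scans, components, mzs = c(100, 150, 200),
                        hz = 3.6) {
  mat <- matrix(0, n_scans, length(mzs), dimnames = list(NULL, mzs))
  for (cm in components) {
    shape <- cm$height * exp(-((seq_len(n_scans) - cm$center)^2) /
                               (2 * cm$sigma^2))
    for (j in seq_along(cm$rel))
      mat[, j] <- mat[, j] + shape * cm$rel[j]
  }
  attr(mat, "scan_times") <- seq_len(n_scans) / hz
  mat
}

test_that("a single clean Gaussian is recovered at its true apex", {
  sc <- plant_scans(200, list(list(center = 100, height = 5000,
                                   sigma = 9 / 2.355, rel = c(1, 0.5, 0.2))))
  pk <- detect_peaks(sc)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$apex_scan, 100)
  expect_gte(pk$width_scans, 5)
  expect_gt(pk$symmetry, 0.9)
  expect_equal(pk$height, sum(5000 * c(1, 0.5, 0.2)), tolerance = 0.05)
})

test_that("peaks below the published thresholds are dropped", {
  low <- plant_scans(200, list(list(center = 100, height = 400 / 1.7,
                                    sigma = 4, rel = c(1, 0.5, 0.2))))
  expect_identical(nrow(detect_peaks(low)), 0L)   # fails min height 500
  # shallow rise fails the slope threshold even when tall enough
  wide <- plant_scans(2000, list(list(center = 1000, height = 5000,
                                      sigma = 300, rel = c(1, 0, 0))))
  expect_identical(nrow(detect_peaks(wide)), 0L)
  expect_identical(nrow(detect_peaks(plant_scans(50, list()))), 0L)
})

test_that("50 planted non-overlapping peaks are all recovered within 1 scan", {
  set.seed(10)
  centers <- sort(sample(seq(30, 4970, by = 25), 50))
  comps <- lapply(centers, function(cc)
    list(center = cc, height = runif(1, 2000, 20000), sigma = 4,
         rel = c(1, runif(1, 0.2, 0.8), runif(1, 0.1, 0.5))))
  sc <- plant_scans(5000, comps)
  pk <- detect_peaks(sc)
  expect_identical(nrow(pk), 50L)
  expect_true(all(abs(pk$apex_scan - centers) <= 1))
})

test_that("detection is translation-invariant along the time axis", {
  comps <- list(list(center = 60, height = 4000, sigma = 4,
                     rel = c(1, 0.4, 0.1)))
  comps_shift <- list(list(center = 160, height = 4000, sigma = 4,
                           rel = c(1, 0.4, 0.1)))
  p1 <- detect_peaks(plant_scans(300, comps))
  p2 <- detect_peaks(plant_scans(400, comps_shift))
  expect_identical(p2$apex_scan - 100, p1$apex_scan)
  expect_equal(p2$height, p1$height, tolerance = 1e-9)
  expect_equal(p2$area, p1$area, tolerance = 1e-9)
})

test_that("deconvolution separates co-eluting disjoint-spectrum components", {
  # 3 scans apart: close enough to overlap, far enough for two TIC maxima
  mzs <- c(100, 150, 200, 250)
  sc <- plant_scans(120, list(
    list(center = 60, height = 6000, sigma = 1.2, rel = c(1, 0.5, 0, 0)),
    list(center = 63, height = 6000, sigma = 1.2, rel = c(0, 0, 1, 0.5))),
    mzs = mzs)
  comps <- deconvolve(sc, c(40, 90), sigma_scans = 1.2)
  expect_identical(length(comps), 2L)
  for (cm in comps) {
    own <- if (cm$apex_scan <= 61) c(100, 150) else c(200, 250)
    other <- setdiff(mzs, own)
    own_sig <- sum(cm$spectrum$rel_intensity[cm$spectrum$mz %in% own])
    other_sig <- sum(cm$spectrum$rel_intensity[cm$spectrum$mz %in% other])
    expect_lt(other_sig / own_sig, 0.01)
  }
})

test_that("purity factors follow the co-elution definition", {
  sc1 <- plant_scans(120, list(list(center = 60, height = 5000, sigma = 4,
                                    rel = c(1, 0.5, 0.2))))
  solo <- deconvolve(sc1, c(40, 90), sigma_scans = 4)
  expect_identical(length(solo), 1L)
  expect_gt(solo[[1]]$purity_factor, 1e5)      # sentinel: elutes alone
  sc2 <- plant_scans(160, list(
    list(center = 70, height = 5000, sigma = 4, rel = c(1, 0, 0)),
    list(center = 90, height = 5000, sigma = 4, rel = c(0, 1, 0))))
  pair <- deconvolve(sc2, c(40, 120), sigma_scans = 4)
  expect_identical(length(pair), 2L)
  for (cm in pair) {
    expect_equal(cm$purity_factor, 1, tolerance = 0.05)
    # both fail the minimum purity factor of 2
    expect_lt(cm$purity_factor, peak_detection_params()$min_purity_factor)
  }
})

test_that("EIC extraction quantifies each isomer from its own RI window", {
  # leucine and isoleucine share quantifier m/z 158 but elute apart
  run <- fx_noiseless_run(c(Leucine = 1000, Isoleucine = 3000))
  calib <- fit_ri_map(run)
  lib <- fx_library()
  h_leu <- extract_eic_height(run, 158, lib[["Leucine"]]$retention_index,
                              calib)
  h_ile <- extract_eic_height(run, 158, lib[["Isoleucine"]]$retention_index,
                              calib)
  expect_equal(as.numeric(h_leu), 1000 * response_factor("high"),
               tolerance = 1e-6)
  expect_equal(as.numeric(h_ile), 3000 * response_factor("high"),
               tolerance = 1e-6)
  expect_false(attr(h_leu, "censored"))
})

test_that("empty EIC windows are censored at the detection floor", {
  run <- fx_noiseless_run(c(Valine = 1000))
  calib <- fit_ri_map(run)
  h <- extract_eic_height(run, 144, 2000, calib)    # nothing near RI 2000
  expect_identical(as.numeric(h), 500)
  expect_true(attr(h, "censored"))
  expect_error(extract_eic_height(run, 700, 1500, calib), "scan range")
})

test_that("scan-level EIC extraction agrees with the planted height", {
  run <- fx_noiseless_run(c(Valine = 1000))
  calib <- fit_ri_map(run)
  sc <- render_scan_matrix(run)
  h <- extract_eic_height(sc, 144, fx_library()[["Valine"]]$retention_index,
                          calib)
  expect_equal(as.numeric(h), 1000 * response_factor("high"),
               tolerance = 0.02)
})
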