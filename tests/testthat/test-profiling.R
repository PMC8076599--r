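# hand-built abundance matrix: 2 roles x 2 timepoints x 3 replicates
mk_matrix <- function(values_fn, mets = c("A", "B")) {
  cols <- expand.grid(replicate = 1:3, timepoint = c("t0", "t4"),
                      role = c("transporter", "uninjected"),
                      stringsAsFactors = FALSE)
  cols$sample_id <- sprintf("%s_%s_r%d", substr(cols$role, 1, 2),
                            cols$timepoint, cols$replicate)
  v <- matrix(NA_real_, length(mets), nrow(cols),
              dimnames = list(mets, cols$sample_id))
  for (i in seq_len(nrow(cols)))
    v[, i] <- values_fn(cols$role[i], cols$timepoint[i], cols$replicate[i])
  samples <- data.frame(injection_order = seq_len(nrow(cols)),
                        sample_id = cols$sample_id, role = cols$role,
                        transporter = NA, timepoint = cols$timepoint,
                        replicate = cols$replicate,
                        ribitol_height = 20000)
  structure(list(values = v, censored = v < 500, samples = samples),
            class = "abundance_matrix")
}

test_that("fold-change and delta have their null and planted identities", {
  null_mat <- mk_matrix(function(role, tp, r) c(A = 1000, B = 2000))
  fc <- fold_change(null_mat)
  expect_true(all(abs(fc$fold_change - 1) < 1e-12))
  dl <- absolute_delta(null_mat)
  expect_true(all(abs(dl$delta) < 1e-12))
  # planted 3x accumulation of A and +1000 shift of B at t4
  mat <- mk_matrix(function(role, tp, r) {
    a <- if (role == "transporter" && tp == "t4") 3000 else 1000
    b <- if (role == "transporter" && tp == "t4") 3000 else 2000
    c(A = a, B = b)
  })
  fc4 <- fold_change(mat); fc4 <- fc4[fc4$timepoint == "t4", ]
  expect_equal(fc4$fold_change[fc4$metabolite == "A"], 3)
  dl4 <- absolute_delta(mat); dl4 <- dl4[dl4$timepoint == "t4", ]
  expect_equal(dl4$delta[dl4$metabolite == "B"], 1000)
})

test_that("paired tests behave at the degenerate and powered extremes", {
  flat <- mk_matrix(function(role, tp, r) c(A = 1000, B = 2000))
  p <- paired_test(flat, "A")
  expect_identical(as.numeric(p), 1)
  expect_identical(attr(p, "flag"), "zero-variance")
  # a +5 sigma shift across 3 pairs is significant
  set.seed(14)
  noise <- matrix(rnorm(12, 0, 10), 2)
  shift <- mk_matrix(function(role, tp, r) {
    base <- c(A = 1000, B = 2000) + noise[, r]
    if (tp == "t4" && role == "transporter") base <- base + 120
    base
  })
  expect_lt(as.numeric(paired_test(shift, "A")), 0.05)
})

test_that("type-I error of the paired test is calibrated at the null", {
  # 300 fast null batches here; the acceptance suite runs the full 500
  lib <- fx_library(); mods <- fx_models()
  rej <- 0; tot <- 0
  for (i in 1:300) {
    d <- experiment_design("Un-injected", drift = FALSE, seed = 5000 + i)
    m <- simulate_abundance_matrix(d, library = lib, models = mods)
    for (met in rownames(m$values)) {
      p <- as.numeric(paired_test(m, met))
      if (!is.na(p)) { tot <- tot + 1; rej <- rej + (p < 0.05) }
    }
  }
  expect_gte(rej / tot, 0.03)
  expect_lte(rej / tot, 0.07)
})

test_that("substrate calls recover each symporter's fixture profile", {
  lib <- fx_library(); mods <- fx_models()
  byprod <- c("Ornithine", "Pyroglutamic acid")
  for (tr in c("SNAT2-like", "SNAT1-like", "B0AT1-like", "EAAT1-like")) {
    d <- experiment_design(tr, seed = 101)
    m <- simulate_abundance_matrix(d, library = lib, models = mods)
    pr <- profile_substrates(m)
    pr4 <- pr[pr$timepoint == "t4" & pr$metabolite != "Ribitol", ]
    called <- pr4$metabolite[pr4$call == "accumulated"]
    truth <- mods[[tr]]$substrates$substrate
    # conversion products of accumulated parents legitimately co-accumulate
    called_primary <- setdiff(called, byprod)
    sens <- length(intersect(called_primary, truth)) / length(truth)
    fdr <- length(setdiff(called_primary, truth)) / max(length(called_primary), 1)
    expect_gte(sens, 0.9)
    expect_lte(fdr, 0.1)
  }
})

test_that("the null pipeline calls (almost) nothing", {
  lib <- fx_library(); mods <- fx_models()
  false_calls <- 0; tested <- 0
  for (i in 1:20) {
    d <- experiment_design("Un-injected", seed = 300 + i)
    m <- simulate_abundance_matrix(d, library = lib, models = mods)
    pr <- profile_substrates(m)
    pr4 <- pr[pr$timepoint == "t4" & pr$metabolite != "Ribitol", ]
    false_calls <- false_calls + sum(pr4$call != "unchanged")
    tested <- tested + nrow(pr4)
  }
  expect_lte(false_calls / tested, 0.05 + 0.02)
})

test_that("fold-change and delta detections agree in sign when both fire", {
  lib <- fx_library(); mods <- fx_models()
  d <- experiment_design("SNAT2-like", seed = 55)
  m <- simulate_abundance_matrix(d, library = lib, models = mods)
  pr <- profile_substrates(m)
  both <- pr[!is.na(pr$p_value) & pr$fc_detected & pr$delta_detected, ]
  expect_gt(nrow(both), 0)
  expect_true(all(sign(both$fold_change - 1) == sign(both$delta)))
})

test_that("exchanger profiling captures both phases of the preload design", {
  # drift off isolates the exchange mechanism: endogenous BCAA consumption
  # would otherwise drain the preloaded pool below the detection floor for
  # the scarcest substrate (tryptophan)
  lib <- fx_library(); mods <- fx_models()
  d <- experiment_design("LAT1-like", drift = FALSE,
                         preload = list(substrate = "Isoleucine"), seed = 1)
  m <- simulate_abundance_matrix(d, library = lib, models = mods)
  ep <- exchanger_profile(m)
  sgn <- function(met, ph) ep$sign[ep$metabolite == met & ep$phase == ph]
  expect_identical(sgn("Isoleucine", "preload"), "+")
  for (met in c("Tryptophan", "Tyrosine", "Histidine", "Phenylalanine",
                "Methionine"))
    expect_identical(sgn(met, "preload"), "-")
  expect_identical(sgn("Isoleucine", "medium"), "-")
  for (met in c("Leucine", "Phenylalanine", "Tryptophan"))
    expect_identical(sgn(met, "medium"), "+")
  # a matrix without the preload phases is rejected
  d2 <- experiment_design("LAT1-like", seed = 1)
  m2 <- simulate_abundance_matrix(d2, library = lib, models = mods)
  expect_error(exchanger_profile(m2), "phase")
})

test_that("antiport deltas over both phases cancel on amounts at zero noise", {
  tm <- fx_models()
  d <- experiment_design("LAT1-like",
                         preload = list(substrate = "Isoleucine"),
                         drift = FALSE, pool_cv = 0, seed = 2)
  p <- simulate_pools(d, library = fx_library(), models = tm)
  subs <- tm[["LAT1-like"]]$substrates$substrate
  for (r in seq_along(p)) {
    d1 <- p[[r]][subs, "preloaded"] - p[[r]][subs, "baseline"]
    d2 <- p[[r]][subs, "t4"] - p[[r]][subs, "preloaded"]
    expect_equal(sum(d1 + d2), 0, tolerance = 1e-6)
  }
})

test_that("heat-map tables carry the control and by-product rows", {
  lib <- fx_library(); mods <- fx_models()
  d <- experiment_design("SNAT2-like", seed = 7)
  m <- simulate_abundance_matrix(d, library = lib, models = mods)
  rib <- setNames(m$samples$ribitol_height, m$samples$sample_id)
  pr <- profile_substrates(m, ribitol = rib)
  rib_fc <- pr$fold_change[pr$metabolite == "Ribitol"]
  expect_true(all(abs(rib_fc - 1) <= 0.1))
  expect_identical(unique(pr$call[pr$metabolite == "Ribitol"]),
                   "negative control")
  dir <- tempfile()
  paths <- write_heatmap_tables(pr, dir)
  fcm <- read.delim(paths["fold_change"], row.names = 1, check.names = FALSE)
  expect_true(all(c("Ribitol", "Ornithine", "Pyroglutamic acid") %in%
                    rownames(fcm)))
  # empty profile still writes headers
  empty <- pr[0, ]
  paths2 <- write_heatmap_tables(empty, tempfile())
  expect_true(file.exists(paths2["fold_change"]))
})
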