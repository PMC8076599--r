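# Shared fixtures, built once per test run.  Everything is generated in
# code from the packaged reference data; nothing binary is stored.

.fx <- new.env(parent = emptyenv())

fx_library <- function() {
  if (is.null(.fx$library)) .fx$library <- load_reference_library()
  .fx$library
}

fx_models <- function() {
  if (is.null(.fx$models)) .fx$models <- load_transporter_models()
  .fx$models
}

# default SNAT2 batch used by several suites (rendered once, ~0.5 s)
fx_snat2_batch <- function() {
  if (is.null(.fx$snat2_batch))
    .fx$snat2_batch <- generate_batch(
      experiment_design("SNAT2-like", seed = 42),
      library = fx_library(), models = fx_models())
  .fx$snat2_batch
}

# full pipeline result on the default batch (built once, ~15 s)
fx_snat2_result <- function() {
  if (is.null(.fx$snat2_result)) {
    cfg <- pipeline_config(design = experiment_design("SNAT2-like", seed = 42))
    .fx$snat2_result <- suppressMessages(run_profile(fx_snat2_batch(), cfg))
  }
  .fx$snat2_result
}

# a clean ri calibration over the full ladder at the instrument defaults
fx_calib <- function() {
  inst <- instrument_params()
  fit_ri_map(data.frame(
    carbon_number = c(12, 15, 19, 22, 28, 33, 36),
    rt_seconds = inst$rt_at_1200 +
      inst$rt_per_ri * (100 * c(12, 15, 19, 22, 28, 33, 36) - 1200)))
}

# a noiseless single-run render of given amounts (pmol per pooled sample)
fx_noiseless_run <- function(amounts, role = "uninjected") {
  set.seed(1)
  inst <- instrument_params(run_shift_sd = 0, ion_cv = 0)
  render_run(amounts, fx_library(), role = role, inst = inst,
             instrument_cv = 0, ribitol_cv = 0, ri_jitter_sd = 0)
}

# independent weighted-cosine oracle (kept deliberately naive; mirrors the
# documented formula, not the implementation)
oracle_cosine_score <- function(query, lib, scale, restrict = FALSE) {
  q <- query[!query$mz %in% c(73, 147), ]
  l <- lib[!lib$mz %in% c(73, 147), ]
  if (restrict) q <- q[q$mz %in% l$mz, ]
  if (nrow(q) == 0 || nrow(l) == 0) return(0)
  mzs <- if (restrict) l$mz else sort(union(q$mz, l$mz))
  num <- 0; qn <- 0; ln <- 0
  for (mz in mzs) {
    qi <- q$rel_intensity[q$mz == mz]
    li <- l$rel_intensity[l$mz == mz]
    qw <- if (length(qi) == 0) 0 else sqrt(qi) * mz
    lw <- if (length(li) == 0) 0 else sqrt(li) * mz
    num <- num + qw * lw; qn <- qn + qw^2; ln <- ln + lw^2
  }
  if (qn == 0 || ln == 0) return(0)
  scale * num / sqrt(qn * ln)
}
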