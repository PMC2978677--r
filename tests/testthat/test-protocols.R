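test_that("ensembles are reproducible and empty without a stimulus", {
  s <- sensor_params()
  s$delta <- 0
  spec <- experiment_spec(protocol = make_train(0, 100),
                          zone = zone_config(sensor = s, baseline_uM = 0),
                          template = hybrid_template(peak_uM = 0,
                                                     mid_amp_uM = 0,
                                                     res_amp_uM = 0,
                                                     baseline_uM = 0),
                          n_trials = 1, seed = 1)
  ens <- run_ensemble(spec)
  expect_equal(nrow(ens$events), 0)
  spec2 <- experiment_spec(n_trials = 200, seed = 5)
  a <- run_ensemble(spec2)
  b <- run_ensemble(spec2)
  expect_identical(a$events, b$events)
})

test_that("paired comparisons share random streams", {
  spec <- experiment_spec(n_trials = 150, seed = 9)
  cmp <- run_comparison(spec, refractory = c(TRUE, TRUE))
  expect_identical(cmp$a$events, cmp$b$events)
  cmp2 <- run_comparison(spec, refractory = c(TRUE, FALSE))
  expect_false(cmp2$b$spec$zone$refractory)
  expect_error(run_comparison(spec), "toggle")
})

test_that("release probability grows with channel count across presets", {
  prs <- vapply(c("pr02", "pr06", "pr095"), function(p) {
    compute_pr(run_ensemble(experiment_spec(preset = p, n_trials = 400,
                                            seed = 21)))
  }, numeric(1))
  expect_true(all(diff(prs) > 0))
})

test_that("depletion-free trials can exceed the pool and replace vesicles", {
  spec <- experiment_spec(preset = "pr095", n_trials = 300, seed = 2)
  free <- run_depletion_free(spec)
  expect_true(free$spec$zone$depletion_free)
  # identical seeds, pool-limited run never exceeds 7
  lim <- run_ensemble(spec)
  expect_lte(max(table(lim$events$trial)), 7)
})
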