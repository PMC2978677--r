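test_that("geometry invariants hold", {
  g <- bouton_geometry()
  expect_equal(c(g$Lx, g$Ly, g$Lz), c(4000, 500, 500))
  expect_equal(nrow(g$vesicles), 7)
  # hexagonal array: largest centre-to-centre distance 35 nm
  d <- as.matrix(dist(g$vesicles[, c("x", "z")]))
  expect_equal(max(d), 35, tolerance = 1e-9)
  expect_error(bouton_geometry(lc_nm = 5), "10, 400")
  expect_error(bouton_geometry(lc_nm = 500), "10, 400")
})

test_that("immobile species do not move and Brownian MSD follows 6 D t", {
  pos <- tibble::tibble(x = runif(500, 100, 3900), y = runif(500, 100, 400),
                        z = runif(500, 100, 400))
  still <- step_brownian(pos, D_um2s = 0, dt_ms = 1)
  expect_equal(still$x, pos$x)
  # free-space displacement variance per axis = 2 D dt
  moved <- step_brownian(pos, D_um2s = 220, dt_ms = 0.01, box = NULL, seed = 2)
  msd <- mean((moved$x - pos$x)^2 + (moved$y - pos$y)^2 + (moved$z - pos$z)^2)
  expect_equal(msd, 6 * 220e3 * 0.01, tolerance = 0.1)
})

test_that("binding probability recovers mass action and flags saturation", {
  expect_equal(binding_prob(0, 100, 0.001), 0)
  p <- binding_prob(0.55e7, 100, 0.001) # high-affinity site at 100 uM sites
  expect_equal(p, -expm1(-0.55e7 * 1e-9 * 100 * 0.001), tolerance = 1e-12)
  expect_error(binding_prob(1e9, 1000, 1), "time step")
  expect_error(binding_prob(-1, 10, 0.1), "nonnegative")
})

test_that("resting bouton stays near 100 nM with buffer equilibrated", {
  d <- diffusion_params(dt_ca_us = 2, dt_other_us = 20)
  run <- run_spatial_engine(diffusion = d, t_end_ms = 10, seed = 3)
  expect_equal(mean(run$bulk$conc_uM), 0.1, tolerance = 0.1)
  # calbindin occupancy at rest: per-site equilibrium from the printed rates
  occ_h <- 0.1 / (0.1 + 2.6 / 0.55e7 * 1e6)
  occ_m <- 0.1 / (0.1 + 35.8 / 4.35e7 * 1e6)
  expected_bound <- run$diag$n_calbindin * 2 * (occ_h + occ_m)
  expect_equal(run$diag$bound_ca, expected_bound, tolerance = 0.05)
  # ion bookkeeping balances exactly (integer conservation)
  dg <- run$diag
  expect_equal(
    dg$free_ca + dg$bound_ca + dg$pump_held -
      (dg$init_free + dg$init_bound + dg$init_pump_held),
    dg$injected + dg$leaked + dg$clamp_added -
      dg$extruded - dg$clamp_removed)
})

test_that("local probe reads the bulk concentration in a uniform box", {
  d <- diffusion_params(dt_ca_us = 2, dt_other_us = 20)
  run <- run_spatial_engine(diffusion = d, t_end_ms = 10, seed = 5)
  tr <- measure_local_ca(run)
  # mean over the run: Poisson noise on ~0.02 ions per sample
  expect_equal(mean(tr$conc_uM), 0.1, tolerance = 0.5)
  expect_error(measure_local_ca(run, "nope"), "unknown probe")
})

test_that("effective diffusion is near-free without buffer and slowed with it", {
  geom <- bouton_geometry()
  d <- diffusion_params(dt_ca_us = 2, dt_other_us = 20)
  nob <- run_spatial_engine(
    geometry = geom, buffer = buffer_params(concentration_uM = 1e-6),
    diffusion = d, t_end_ms = 1, n_tagged = 400, tag_dt_ms = 0.05, seed = 6)
  est <- estimate_effective_D(nob$tagged)
  expect_equal(est$D_eff_um2s, 220, tolerance = 0.1)
  buf <- run_spatial_engine(
    geometry = geom, diffusion = d, t_end_ms = 3, n_tagged = 400,
    tag_dt_ms = 0.1, seed = 7)
  estb <- estimate_effective_D(buf$tagged)
  expect_lt(estb$D_eff_um2s, 90)
  expect_gt(estb$D_eff_um2s, 25)
})

test_that("spatial runs are reproducible for a fixed seed", {
  d <- diffusion_params(dt_ca_us = 2, dt_other_us = 20)
  a <- run_spatial_engine(diffusion = d, t_end_ms = 2, seed = 11)
  b <- run_spatial_engine(diffusion = d, t_end_ms = 2, seed = 11)
  expect_identical(a$traces$conc_uM, b$traces$conc_uM)
  expect_identical(a$diag, b$diag)
})

test_that("hybrid trace is flat without stimuli and superposes across a train", {
  tpl <- hybrid_template()
  none <- hybrid_ca_trace(make_train(0, 100), tpl)
  expect_true(all(none$conc_uM == tpl$baseline_uM))
  single <- hybrid_ca_trace(single_ap_protocol(100), tpl)
  expect_equal(max(single$conc_uM) - tpl$baseline_uM, tpl$peak_uM,
               tolerance = 0.1)
  expect_error(hybrid_template(peak_uM = -1), "nonnegative")
  # train: each transient rides on the previous residue
  train <- hybrid_ca_trace(make_train(10, 400), tpl)
  p1 <- max(train$conc_uM[train$time_ms < 100])
  p2 <- max(train$conc_uM[train$time_ms >= 100 & train$time_ms < 200])
  expect_gt(p2, p1 * 0.99)
  # per-AP peaks occur with the template latency (about 2-3 ms)
  tp <- train$time_ms[train$time_ms < 100][which.max(train$conc_uM[train$time_ms < 100])]
  expect_lt(tp, 5)
})

test_that("trial amplitude factors have unit mean and the template cv", {
  tpl <- hybrid_template(cv = 0.36)
  s <- hybrid_trial_scales(tpl, 20000, seed = 3)
  expect_equal(mean(s), 1, tolerance = 0.02)
  expect_equal(sd(s), 0.36, tolerance = 0.05)
  expect_identical(hybrid_trial_scales(tpl, 100, seed = 4),
                   hybrid_trial_scales(tpl, 100, seed = 4))
})
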