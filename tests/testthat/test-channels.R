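test_that("gating rates follow the exponential voltage law", {
  p <- vdcc_params()
  r0 <- vdcc_rates(0, p)
  expect_equal(r0$a, c(4.04, 6.70, 4.39, 17.33))
  expect_equal(r0$b, c(2.88, 6.30, 8.16, 1.84))
  # a_1 at v = v_1 is a_10 * e
  r1 <- vdcc_rates(49.14, p)
  expect_equal(r1$a[1], 4.04 * exp(1), tolerance = 1e-12)
  # a_i(v) * b_i(v) is voltage independent
  for (v in c(-80, -20, 0, 15, 60)) {
    r <- vdcc_rates(v, p)
    expect_equal(r$a * r$b, r0$a * r0$b, tolerance = 1e-12)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(vdcc_params(n_channels = 0), "between 1 and 208")
  expect_error(vdcc_params(n_channels = 500), "between 1 and 208")
  expect_error(vdcc_params(cluster_radius_nm = 80), "66")
})

test_that("channels rarely open at the resting potential", {
  volt <- tibble::tibble(time_ms = seq(0, 10, by = 0.5), v_mv = -70)
  traj <- simulate_channels(volt, n_channels = 1000, seed = 42)
  opened <- length(unique(traj$channel[traj$state == 4]))
  expect_lt(opened / 1000, 0.01)
})

test_that("stochastic occupancy matches the master equation", {
  n_ch <- 4000
  for (v in c(-40, 0, 20)) {
    volt <- tibble::tibble(time_ms = seq(0, 3, by = 0.1), v_mv = v)
    traj <- simulate_channels(volt, n_channels = n_ch, seed = 7 + v)
    me <- vdcc_open_probability(volt)
    for (tt in c(1, 3)) {
      emp <- channel_occupancy(traj, tt)$fraction
      ref <- unlist(me[me$time_ms == tt, c("p1", "p2", "p3", "p4", "p_open")])
      tv <- sum(abs(emp - ref)) / 2
      expect_lt(tv, 0.03)
    }
  }
})

test_that("channel simulation is reproducible and conserves channel count", {
  volt <- voltage_trace(single_ap_protocol(duration_ms = 5), dt_ms = 0.01)
  a <- simulate_channels(volt, n_channels = 20, seed = 3)
  b <- simulate_channels(volt, n_channels = 20, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$channel %in% 0:19))
  # states only change by one step along the chain
  for (ch in unique(a$channel)) {
    s <- c(0, a$state[a$channel == ch])
    expect_true(all(abs(diff(s)) == 1))
  }
})

test_that("open intervals are disjoint and ion injection is Poisson", {
  volt <- voltage_trace(single_ap_protocol(duration_ms = 6), dt_ms = 0.01)
  traj <- simulate_channels(volt, n_channels = 30, seed = 11)
  oi <- open_intervals(traj)
  expect_true(all(oi$t_close >= oi$t_open))
  by_ch <- split(oi, oi$channel)
  for (g in by_ch) {
    if (nrow(g) > 1) expect_true(all(g$t_open[-1] >= g$t_close[-nrow(g)]))
  }
  # empty interval set gives no ions
  empty <- open_intervals(simulate_channels(
    tibble::tibble(time_ms = c(0, 1), v_mv = -200), n_channels = 1, seed = 1))
  expect_equal(nrow(channel_flux_events(empty, 500)), 0)
  # one 1 ms interval at 500 ions/ms: mean within 3 sigma, and linear in flux
  one <- tibble::tibble(channel = 0L, t_open = 0, t_close = 1)
  tot <- function(flux, seed) {
    sum(channel_flux_events(one, flux, dt_ms = 0.01, seed = seed)$ions)
  }
  draws <- vapply(1:300, function(s) tot(500, s), numeric(1))
  expect_lt(abs(mean(draws) - 500), 3 * sqrt(500 / 300))
  draws2 <- vapply(1:300, function(s) tot(1000, s), numeric(1))
  expect_equal(mean(draws2) / mean(draws), 2, tolerance = 0.05)
  expect_error(channel_flux_events(one, -1), "nonnegative")
  expect_error(channel_flux_events(one, 10, dt_ms = 0), "positive")
})
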