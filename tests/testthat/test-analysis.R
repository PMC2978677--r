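test_that("histogram arithmetic follows the sqrt(r) error rule", {
  ev <- tibble::tibble(trial = 0:99, time_ms = rep(5, 100), vesicle = 0L,
                       pathway = factor(rep("synchronous", 100),
                         levels = c("synchronous", "asynchronous",
                                    "spontaneous")))
  h <- release_histogram(ev, t_b = 10, n_trials = 1e4, window = c(0, 400))
  expect_equal(h$rate_per_ms[1], 1e-3)
  expect_equal(h$std_per_ms[1], 1e-4)
  expect_equal(sum(h$count), 100)
  # empty events give an all-zero histogram
  h0 <- release_histogram(ev[0, ], t_b = 10, n_trials = 10, window = c(0, 100))
  expect_true(all(h0$count == 0))
  expect_error(release_histogram(ev, t_b = 0, n_trials = 10), "positive")
})

test_that("rebinning conserves total counts exactly", {
  fx <- generate_fixture("constant_ca_events", seed = 3)
  h1 <- release_histogram(fx$data, t_b = 1, n_trials = 1000,
                          window = c(0, 400))
  h10 <- release_histogram(fx$data, t_b = 10, n_trials = 1000,
                           window = c(0, 400))
  expect_equal(sum(h1$count), sum(h10$count))
  expect_equal(sum(h1$count), nrow(fx$data))
  # block sums of the fine histogram equal the coarse histogram
  blocks <- tapply(h1$count, rep(seq_len(40), each = 10), sum)
  expect_equal(as.vector(blocks), h10$count)
})

test_that("decay-fit recovers generating time constants on fixture data", {
  fx <- generate_fixture("multi_exp_events",
                         params = list(n_trials = 30000), seed = 1)
  h <- release_histogram(fx$data, t_b = 10, n_trials = 30000,
                         window = c(0, 400))
  f <- fit_release_decay(h, "2exp", constant = fx$params$a2)
  g <- glance(f)
  expect_equal(g$tau_fast, fx$params$tau_fast, tolerance = 0.15)
  expect_equal(g$tau_slow, fx$params$tau_slow, tolerance = 0.15)
  td <- tidy(f)
  expect_equal(td$amplitude[td$component == "fast"], fx$params$a0,
               tolerance = 0.15)
})

test_that("a pure single exponential leaves the second amplitude degenerate", {
  fx <- generate_fixture("multi_exp_events",
                         params = list(a1 = 0, a2 = 0, n_trials = 20000),
                         seed = 2)
  h <- release_histogram(fx$data, t_b = 10, n_trials = 20000,
                         window = c(0, 400))
  f <- fit_release_decay(h, "2exp")
  td <- tidy(f)
  a_slow <- td$amplitude[td$component == "slow"]
  a_fast <- td$amplitude[td$component == "fast"]
  expect_lt(a_slow, 0.02 * a_fast)
})

test_that("release probability and count distribution behave", {
  expect_equal(compute_pr(tibble::tibble(trial = integer(),
                                         time_ms = double()), 100), 0)
  ev <- tibble::tibble(trial = rep(0:49, 2), time_ms = runif(100, 0, 10))
  expect_equal(compute_pr(ev, 50), 1)
  dist <- vesicle_count_distribution(ev, 100)
  expect_equal(sum(dist$p), 1)
  expect_equal(dist$p[dist$k == 2], 0.5)
  expect_equal(max(dist$cum_p), 1)
})

test_that("binomial independence analytics match brute-force enumeration", {
  res <- binomial_independence(0.2, 7)
  expect_equal(res$p_vesicle, 0.031, tolerance = 0.02)
  expect_equal(res$p_multi, 0.02, tolerance = 0.1)
  expect_equal(binomial_independence(0, 7)$p_vesicle, 0)
  expect_equal(binomial_independence(0, 7)$p_multi, 0)
  expect_error(binomial_independence(1, 7), "\\[0, 1\\)")
  # exact oracle: enumerate all 2^7 outcomes
  p <- res$p_vesicle
  outcomes <- expand.grid(rep(list(0:1), 7))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  k <- rowSums(outcomes)
  expect_equal(sum(probs[k >= 1]), 0.2, tolerance = 1e-9)
  expect_equal(sum(probs[k >= 2]), res$p_multi, tolerance = 1e-9)
})

test_that("facilitation statistics are scale invariant", {
  ev <- tibble::tibble(
    trial = 0L,
    time_ms = c(runif(100, 0, 100), runif(150, 100, 200),
                runif(120, 200, 300), runif(90, 300, 400)))
  f <- facilitation(ev, n_stimuli = 4)
  expect_equal(f$facilitation_pct[1], 0)
  expect_equal(attr(f, "max_facilitation_pct"), 50)
  # doubling all counts leaves facilitation unchanged
  ev2 <- dplyr::bind_rows(ev, ev)
  f2 <- facilitation(ev2, n_stimuli = 4)
  expect_equal(f2$facilitation_pct, f$facilitation_pct)
  # identical windows give zero facilitation
  ev3 <- tibble::tibble(trial = 0L, time_ms = rep(1:4 * 100 - 50, each = 10))
  expect_equal(facilitation_pct(ev3, 4), 0)
  expect_error(facilitation(ev, n_stimuli = 1), "two stimuli")
})

test_that("dose-response fit recovers a cooperativity exponent of 4", {
  lev <- c(0.25, 0.5, 1, 1.5, 2)
  truth <- 3.2 * (lev / (lev + 1.1))^4
  # across noise realisations the exponent comes back near 4 (K free makes
  # the problem ill-conditioned, so the tolerance reflects that)
  ns <- vapply(1:5, function(s) {
    set.seed(s)
    noisy <- truth * (1 + rnorm(5, sd = 0.03))
    dodge_rahamimoff_fit(tibble::tibble(level = lev, releases = noisy))$n
  }, numeric(1))
  expect_equal(mean(ns), 4, tolerance = 0.15)
  expect_true(all(abs(ns - 4) / 4 < 0.3))
  expect_error(dodge_rahamimoff_fit(tibble::tibble(level = 1, releases = 1)),
               "4 dose levels")
  expect_warning(
    dodge_rahamimoff_fit(tibble::tibble(level = lev,
                                        releases = c(1, 3, 2, 4, 5))),
    "monotone")
})

test_that("effective-D estimate is zero for immobile particles", {
  tagged <- tidyr::expand_grid(ion = 0:49, time_ms = seq(0, 2, by = 0.1)) |>
    dplyr::mutate(x = 100 + ion, y = 200, z = 300)
  est <- estimate_effective_D(tagged)
  expect_equal(est$D_eff_um2s, 0)
})

test_that("pathway split separates labelled events", {
  lv <- c("synchronous", "asynchronous", "spontaneous")
  ev <- tibble::tibble(trial = 0:9, time_ms = runif(10, 0, 100),
                       vesicle = 0L,
                       pathway = factor("synchronous", levels = lv))
  ps <- pathway_split(ev, t_b = 10, n_trials = 10, window = c(0, 100))
  expect_equal(ps$totals$total[ps$totals$pathway == "synchronous"], 10)
  async_h <- ps$histograms[ps$histograms$pathway == "asynchronous", ]
  expect_true(all(async_h$count == 0))
  expect_equal(ps$async_sync_ratio, 0)
})
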