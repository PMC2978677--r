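test_that("action-potential template respects baseline and peak", {
  ap <- ap_waveform()
  t <- seq(0, 10, by = 0.01)
  tr <- generate_ap_waveform(ap, t)
  expect_equal(nrow(tr), length(t))
  # exact baseline before onset
  ap2 <- ap_waveform(onset_ms = 2)
  tr2 <- generate_ap_waveform(ap2, t)
  expect_true(all(tr2$v_mv[t < 2] == ap2$baseline_mv))
  # unique peak reaching peak_mv within one sample of the 0.01 ms grid
  expect_equal(max(tr$v_mv), ap$peak_mv, tolerance = 1e-3)
  expect_equal(sum(tr$v_mv == max(tr$v_mv)), 1)
  # back to within 1 mV of baseline within 10 ms
  expect_lt(abs(tr$v_mv[length(t)] - ap$baseline_mv), 1)
})

test_that("waveform evaluation is deterministic and validates input", {
  ap <- ap_waveform()
  t <- seq(0, 5, by = 0.05)
  expect_identical(generate_ap_waveform(ap, t), generate_ap_waveform(ap, t))
  expect_error(generate_ap_waveform(ap, c(1, 0.5)), "sorted")
  expect_error(generate_ap_waveform(ap, c(-1, 0)), "nonnegative")
})

test_that("two APs superpose on disjoint supports", {
  ap <- ap_waveform()
  prot2 <- make_train(100, 20) # onsets at 0 and 10 ms
  tr2 <- voltage_trace(prot2, ap, dt_ms = 0.01)
  one <- function(on) {
    p <- make_train(0, 20)
    p$onsets_ms <- on
    voltage_trace(p, ap, dt_ms = 0.01)$v_mv - ap$baseline_mv
  }
  expect_equal(tr2$v_mv, ap$baseline_mv + one(0) + one(10), tolerance = 1e-10)
})

test_that("train construction counts stimuli correctly", {
  expect_equal(length(make_train(10, 400)$onsets_ms), 4)
  expect_equal(length(make_train(100, 200)$onsets_ms), 20)
  expect_equal(length(make_train(0, 400)$onsets_ms), 0)
  expect_error(make_train(-1, 100), "nonnegative")
  # floor(frequency x duration) onsets for first_onset 0 (plus one when the
  # window is not an exact multiple of the period)
  for (f in c(3, 7, 50)) {
    for (dur in c(150, 400)) {
      m <- f * dur / 1000
      expected <- floor(m) + as.integer(m %% 1 > 1e-9)
      expect_equal(length(make_train(f, dur)$onsets_ms), expected,
                   info = sprintf("f=%g dur=%g", f, dur))
    }
  }
})

test_that("voltage traces round-trip through plain text", {
  tr <- voltage_trace(make_train(10, 50), dt_ms = 0.1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_voltage_trace(tr, path)
  back <- read_voltage_trace(path)
  expect_equal(back$time_ms, tr$time_ms)
  expect_equal(back$v_mv, tr$v_mv, tolerance = 1e-9)
})
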