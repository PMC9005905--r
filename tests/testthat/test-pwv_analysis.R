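test_that("resampling preserves band-limited content", {
  # pure sinusoid: amplitude error below 0.1%
  fs0 <- 2000
  tt <- seq(1 / fs0, 0.8, by = 1 / fs0)
  w <- pressure_waveform(tt, 90 + 10 * sin(2 * pi * 5 * tt - 0.3), period = 0.8)
  r <- resample_waveform(w, 900)
  expect_equal(r$fs, 900)
  expect_lt(abs(diff(range(r$pressure)) - diff(range(w$pressure))) / 20, 1e-3)
  # 900 Hz input resampled to 900 Hz is the identity up to interpolation noise
  w900 <- resample_waveform(w, 900)
  again <- resample_waveform(w900, 900)
  expect_equal(again$pressure, w900$pressure, tolerance = 1e-6)
  # dense physiological template: systolic peak preserved within 0.1 mmHg
  dense <- make_delayed_pair(fs = 10000)$proximal
  ds <- resample_waveform(dense, 900)
  expect_lt(abs(max(ds$pressure) - max(dense$pressure)), 0.1)
})

test_that("foot detection finds a constructed foot and is equivariant", {
  fs <- 900
  period <- 0.8
  tt <- seq(1 / fs, period, by = 1 / fs)
  mk <- function(t0) {
    # flat diastole with a physiologically fast sin^2 upstroke starting
    # exactly at t0: the second-derivative maximum sits at the onset corner
    s <- (tt - t0) %% period
    p <- ifelse(s < 0.10, 73 + 45 * sin(pi * s / 0.20)^2,
                ifelse(s < 0.45, 73 + 45 * cos(pi * (s - 0.10) / 0.70)^2, 73))
    pressure_waveform(tt, p, period = period)
  }
  # light smoothing: the waveform is noise-free; the smoothed corner's
  # curvature maximum carries a small systematic offset that cancels in
  # transit-time differences
  expect_lt(abs(foot_time(mk(0.120), cutoff_hz = 100) - 0.120), 5 / fs)
  # a time shift moves the foot by exactly that shift
  f1 <- foot_time(mk(0.120)); f2 <- foot_time(mk(0.220))
  expect_equal(f2 - f1, 0.100, tolerance = 1 / fs)
  # affine amplitude changes leave the foot untouched
  w <- mk(0.120)
  w2 <- pressure_waveform(w$time, 3 * w$pressure + 17, period = period)
  expect_equal(foot_time(w2), foot_time(w), tolerance = 1e-9)
  # flat waveform has no foot
  flat <- pressure_waveform(tt, rep(80, length(tt)), period = period)
  expect_error(foot_time(flat), "flat")
})

test_that("transit time recovers constructed delays and flags degeneracy", {
  pair <- make_delayed_pair(delay = 0.080)
  expect_equal(transit_time(pair$proximal, pair$distal), 0.080,
               tolerance = 1 / 900)
  expect_warning(ptt0 <- transit_time(pair$proximal, pair$proximal),
                 "degenerate")
  expect_equal(ptt0, 0)
  short <- make_delayed_pair(delay = 0.080, period = 0.75)
  expect_error(transit_time(pair$proximal, short$distal), "period")
})

test_that("PWV computation divides distance by transit time", {
  m <- compute_pwv(0.66, 0.1096)
  expect_equal(m$pwv, 6.02, tolerance = 0.01)
  expect_equal(compute_pwv(1.32, 0.1096)$pwv, 2 * m$pwv)
  expect_equal(compute_pwv(0.19, 0.019)$pwv, 10.0)
  # a path measurement carries its distance in cm
  tree <- fixture_tree()
  pm <- compute_pwv(arterial_path(tree, "carotid", "femoral"), 0.1096)
  expect_equal(pm$distance_m, 0.66)
  expect_error(compute_pwv(0.66, 0), "transit")
  expect_error(compute_pwv(0.66, -0.01), "transit")
})

test_that("wave metrics follow the systolic/diastolic conventions", {
  w <- make_delayed_pair(template = "physiologic")$proximal
  m <- wave_metrics(w)
  expect_equal(m$SBP, max(w$pressure))
  expect_equal(m$end_DBP, min(w$pressure))
  expect_equal(m$PP, m$SBP - m$end_DBP)
  expect_true(m$early_DBP >= m$end_DBP && m$early_DBP <= m$SBP)
  # constant waveform collapses all metrics
  flat <- pressure_waveform(w$time, rep(90, length(w$time)), period = w$period)
  mf <- suppressMessages(wave_metrics(flat))
  expect_equal(mf$PP, 0)
  expect_equal(mf$SBP, mf$end_DBP)
})

test_that("synthetic delayed pairs are deterministic under a fixed seed", {
  a <- make_delayed_pair(noise_mmhg = 1, seed = 42)
  b <- make_delayed_pair(noise_mmhg = 1, seed = 42)
  expect_identical(a$proximal$pressure, b$proximal$pressure)
  expect_identical(a$distal$pressure, b$distal$pressure)
  c <- make_delayed_pair(noise_mmhg = 1, seed = 43)
  expect_false(identical(a$proximal$pressure, c$proximal$pressure))
})
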