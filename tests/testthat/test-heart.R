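test_that("normalised elastance has the double-Hill shape", {
  tpk <- 0.35
  tt <- seq(0, 0.999, length.out = 2000)
  e <- normalized_elastance(tt, tpk)
  expect_true(all(e >= 0 & e <= 1 + 1e-9))
  # peak of 1 at the requested fraction of the cycle (grid maximum)
  expect_equal(max(e), 1, tolerance = 1e-4)
  expect_equal(tt[which.max(e)], tpk, tolerance = 0.01)
  # essentially relaxed in late diastole
  expect_lt(normalized_elastance(0.9, tpk), 0.05)
  # wraps modulo one cycle
  expect_equal(normalized_elastance(1.25, tpk), normalized_elastance(0.25, tpk))
  expect_gt(mean(e), 0)
})

test_that("ventricle ejects nothing against an unbeatable afterload", {
  p <- heart_params()
  st <- heart_state(p)
  dt <- 2e-4
  ejected <- 0
  for (i in seq_len(round(p$period / dt))) {
    out <- ventricle_step(st, p_root_mmhg = 1000, params = p, dt = dt)
    st <- out$state
    ejected <- ejected + out$Q * dt
  }
  expect_equal(ejected, 0)
  expect_false(st$valve_open)
})

test_that("lumped-afterload heart conserves volume and responds monotonically", {
  base <- simulate_lumped(heart_params())
  # per-cycle ejection equals the Windkessel throughput by construction;
  # the run itself must be periodic and physiological
  expect_gt(base$stroke_volume, 30)
  expect_gt(base$SBP, base$DBP)
  # stroke volume falls with valve resistance
  hiRv <- simulate_lumped(heart_params(R_valve = 0.06))
  expect_lt(hiRv$stroke_volume, base$stroke_volume)
  # and rises with contractility
  hiE <- simulate_lumped(heart_params(E_max = 2.6, preload_mmhg = 9.5))
  expect_gt(hiE$stroke_volume, base$stroke_volume)
})

test_that("prescribed inflow requires a periodic table", {
  expect_s3_class(prescribed_inflow(c(0, 0.4, 0.8), c(0, 100, 0)),
                  "inflow_waveform")
  expect_error(prescribed_inflow(c(0, 0.4, 0.8), c(0, 100, 50)), "periodic")
  expect_error(prescribed_inflow(c(0.1, 0.4, 0.8), c(0, 100, 0)), "ascend")
})

test_that("inflow tables round-trip through text files", {
  path <- withr::local_tempfile(fileext = ".txt")
  tt <- seq(0, 0.8, length.out = 9)
  q <- c(0, 200, 400, 200, 0, 0, 0, 0, 0)
  write.table(data.frame(tt, q), path, row.names = FALSE, col.names = FALSE)
  inf <- read_inflow(path)
  expect_equal(inf$time, tt)
  expect_equal(inf$flow, q)
  expect_equal(inf$period, 0.8)
})
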