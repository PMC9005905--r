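test_that("single-tube fixtures carry analytic ground truth", {
  for (D in c(27.0, 2.6)) {
    tube <- make_single_tube_fixture(distensibility = D)
    expect_no_error(validate_tree(tube))
    expect_equal(attr(tube, "pwv_ground_truth"), bramwell_hill_pwv(D))
  }
  expect_equal(round(attr(make_single_tube_fixture(distensibility = 27),
                          "pwv_ground_truth"), 1), 5.9)
  expect_equal(round(attr(make_single_tube_fixture(distensibility = 2.6),
                          "pwv_ground_truth"), 1), 19.1)
})

test_that("reference tables are internally consistent", {
  bp <- reference_bp_table()
  expect_equal(nrow(bp), 16)
  pwv <- reference_pwv_table()
  expect_equal(pwv$path, c("cf", "cr", "rd"))
  # reported velocities rise monotonically with kidney removal
  for (k in seq_len(3))
    expect_true(all(diff(unlist(pwv[k, c("2KDN", "1KDN", "0KDN")])) > 0))
})

test_that("study runner produces traceable, converged reports", {
  rep <- suppressWarnings(
    run_kidney_study(fixture_tree(), configs = "2KDN",
                     sites = c("aorta", "carotid"),
                     paths = list(cf = c("carotid", "femoral")),
                     n_cycles = 12, tol_mmhg = 2, dx_cm = 1))
  expect_s3_class(rep, "study_report")
  expect_true(all(rep$convergence$converged))
  expect_setequal(rep$metrics$site, c("aorta", "carotid"))
  expect_true(all(rep$pwv$pwv > 0))
  expect_equal(rep$pwv$distance_m, 0.66)
  expect_true(all(rep$metrics$PP == rep$metrics$SBP - rep$metrics$end_DBP))
})

test_that("uniform stiffening sweep lowers PWV as distensibility grows", {
  # coarse, fast settings: the monotone trend and the square-root scaling
  # survive heavy discretisation
  rep <- suppressWarnings(
    run_distensibility_sweep(fixture_tree(), factors = c(-0.8, 0, 0.8),
                             configs = "2KDN",
                             sites = c("aorta", "carotid"),
                             paths = list(cf = c("carotid", "femoral")),
                             n_cycles = 14, tol_mmhg = 2, dx_cm = 1))
  cf <- rep$pwv[order(rep$pwv$factor), ]
  expect_true(all(diff(cf$pwv) < 0))
  ratio <- cf$pwv[cf$factor == -0.8] / cf$pwv[cf$factor == 0]
  # at fixed pressure an 80% distensibility cut speeds the wave by exactly
  # sqrt(5); on the full tree the stiffened system also settles at a lower
  # diastolic foot pressure, which pulls the measured ratio below that
  expect_gt(ratio, 1.3)
  expect_lt(ratio, sqrt(5) * 1.05)
})

test_that("uniform stiffening follows the square-root law at fixed pressure", {
  # single tube held at the reference operating pressure: the measured
  # foot-to-foot ratio between the stiffened (-80%) and default wall is
  # sqrt(5) without operating-point confounding
  v <- vapply(c(27.0, 27.0 * 0.2), function(D) {
    tube <- make_single_tube_fixture(distensibility = D)
    suppressWarnings(single_tube_wave_speed(tube))$pwv
  }, numeric(1))
  expect_equal(v[2] / v[1], sqrt(5), tolerance = 0.05)
})

test_that("default calibration sits at the resting operating point", {
  st <- fixture_study()
  m <- st$metrics
  ao <- m[m$config == "2KDN" & m$site == "aorta", ]
  # aortic systolic/end-diastolic pressure within 5 mmHg of 118/73 and a
  # cardiac output near 5 L/min at 75 bpm
  expect_lt(abs(ao$SBP - 118), 5)
  expect_lt(abs(ao$end_DBP - 73), 5)
  expect_lt(abs(ao$MAP - 88), 5)
  co <- st$convergence$cardiac_output_lmin[st$convergence$config == "2KDN"]
  expect_lt(abs(co - 5), 0.25)
})
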