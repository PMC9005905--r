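test_that("Bramwell-Hill conversion reproduces tabulated wave speeds", {
  # healthy aortic and diseased radial distensibility round to the
  # conventionally quoted speeds
  expect_equal(round(bramwell_hill_pwv(27.0), 1), 5.9)
  expect_equal(round(bramwell_hill_pwv(2.6), 1), 19.1)
  expect_equal(round(bramwell_hill_pwv(3.5), 1), 16.5)
  # scaling law: quadrupling density halves the speed
  expect_equal(bramwell_hill_pwv(12, rho = 4 * 1050),
               bramwell_hill_pwv(12) / 2)
  expect_error(bramwell_hill_pwv(-1), "positive")
  expect_error(bramwell_hill_pwv(0), "positive")
})

test_that("distensibility_from_pwv is the exact inverse", {
  cs <- c(0.5, 2, 5.9, 6.7, 12.2, 30)
  expect_equal(bramwell_hill_pwv(distensibility_from_pwv(cs)), cs,
               tolerance = 1e-12)
  # inverse direction against the printed table: 6.7 m/s ~ aortic in-vivo 21
  expect_equal(distensibility_from_pwv(6.7), 21.0, tolerance = 0.25)
  expect_error(distensibility_from_pwv(0), "positive")
})

test_that("diameter power law is calibrated and monotone", {
  expect_equal(pwv_from_diameter(25), 5.9, tolerance = 0.02)
  expect_equal(pwv_from_diameter(3), 12.2, tolerance = 0.05)
  # b = 0 collapses to a constant
  expect_equal(pwv_from_diameter(c(1, 10, 30), coeffs = c(a = 7, b = 0)),
               rep(7, 3))
  d <- seq(1, 30, by = 0.5)
  expect_true(all(diff(pwv_from_diameter(d)) <= 0))
})

test_that("area compliance identity links distensibility and wave speed", {
  A <- 1e-4
  c0 <- bramwell_hill_pwv(27.0)
  ca <- compliance_per_length(A, c0)
  # D = C_A / A, back on the printed unit scale
  expect_equal(ca / A / 1e-6, 27.0, tolerance = 1e-12)
  expect_equal(compliance_per_length(2 * A, c0), 2 * ca)
})

test_that("the printed distensibility-PWV table is Bramwell-Hill consistent", {
  tab <- invivo_distensibility_table()
  D <- c(tab$d_default, tab$d_esrd)
  pwv_printed <- c(5.9, 6.4, 9.5, 10.3, 11.4, 12.2, 12.5, 10.8, 13.4, 12.9,
                   6.7, 7.3, 12.0, 13.8, 16.5, 19.1, 14.5, 15.2, 16.7, 17.2)
  fit <- fit_blood_density(D, pwv_printed)
  expect_gt(fit$rho, 1040)
  expect_lt(fit$rho, 1070)
  expect_lt(fit$max_error, 0.05)
})

test_that("uniform distensibility scaling obeys the square-root law", {
  tree <- make_single_tube_fixture(distensibility = 27.0)
  expect_equal(scale_distensibility_uniform(tree, 0)$segments[["1"]]$distensibility,
               27.0)
  expect_equal(scale_distensibility_uniform(tree, -0.40)$segments[["1"]]$distensibility,
               16.2)
  d80 <- scale_distensibility_uniform(tree, -0.80)$segments[["1"]]$distensibility
  expect_equal(bramwell_hill_pwv(d80) / bramwell_hill_pwv(27.0), sqrt(5),
               tolerance = 1e-12)
  expect_error(scale_distensibility_uniform(tree, -1), "factor")
})

test_that("diameter-class rule assigns the stratified reductions", {
  mk <- function(d, D) {
    a <- pi * (d / 1000)^2 / 4
    wk <- windkessel_outlet(0.1, 5, 0.3)
    arterial_tree(list(artery_segment(1, "t", 10, d, d, D, windkessel = wk)))
  }
  red <- function(d, D) {
    out <- scale_distensibility_nonuniform(mk(d, D))
    out$segments[["1"]]$distensibility
  }
  expect_equal(red(20, 27.0), 27.0 * 0.60)   # > 14 mm: -40%
  expect_equal(red(14, 27.0), 27.0 * 0.75)   # boundary 14 mm falls in 11-14
  expect_equal(red(12, 27.0), 27.0 * 0.75)
  expect_equal(red(9, 10), 10 * 0.85)
  expect_equal(red(5, 10), 10 * 0.90)
  expect_equal(red(2, 5.3), 5.3 * 0.95)
  # larger-diameter classes never receive smaller reductions
  rule <- default_diameter_class_rule()
  rule <- rule[order(rule$d_min, decreasing = TRUE), ]
  expect_true(all(diff(rule$reduction) <= 0))
})

test_that("in-vivo override table is applied verbatim with fallback reduction", {
  tree <- make_reference_tree()
  # the full override table names groups absent from the reduced tree
  expect_warning(out <- apply_invivo_table(tree), "matching no segment")
  by_group <- function(t, g) {
    ids <- names(t$segments)[vapply(t$segments, function(s) identical(s$group, g),
                                    logical(1))]
    unique(vapply(ids, function(i) t$segments[[i]]$distensibility, numeric(1)))
  }
  expect_equal(by_group(out, "aorta"), 21.0)
  expect_equal(by_group(out, "carotid"), 18.0)
  expect_equal(by_group(out, "brachial"), 3.5)
  expect_equal(by_group(out, "radial"), 2.6)
  # printed value wins over the 30% rule (6.6, not 10.6 * 0.70)
  expect_equal(by_group(out, "femoral"), 6.6)
  # groups without a printed value get the fallback reduction
  expect_equal(by_group(out, "subclavian"), 8.5 * 0.70)
  # identity when nothing is overridden and the reduction is zero
  same <- apply_invivo_table(tree, overrides = c(), default_reduction = 0)
  expect_equal(same$segments, tree$segments)
  expect_warning(apply_invivo_table(tree, overrides = c(pulmonary = 10)),
                 "matching no segment")
})

test_that("distensibility scenarios dispatch to the right transformation", {
  tree <- make_single_tube_fixture(distensibility = 27.0)
  expect_equal(apply_distensibility_scenario(tree, NULL), tree)
  sc <- distensibility_scenario("uniform_scale", factor = 0.2)
  expect_equal(apply_distensibility_scenario(tree, sc)$segments[["1"]]$distensibility,
               27 * 1.2)
  sc2 <- distensibility_scenario("nonuniform_by_diameter")
  expect_equal(apply_distensibility_scenario(tree, sc2)$segments[["1"]]$distensibility,
               27 * 0.60)
})
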