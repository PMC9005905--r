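# Shared fixtures. The full-tree simulations are expensive, so the staged
# kidney study and the non-uniform comparison are run once on first use and
# cached for all test files.

.fixture_env <- new.env(parent = emptyenv())

fixture_tree <- function() {
  if (is.null(.fixture_env$tree)) .fixture_env$tree <- make_reference_tree()
  .fixture_env$tree
}

fixture_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- suppressWarnings(
      run_kidney_study(fixture_tree(),
                       configs = c("2KDN", "1KDN", "0KDN", "TX"),
                       keep_results = TRUE, tol_mmhg = 0.2, n_cycles = 20))
  }
  .fixture_env$study
}

fixture_nonuniform <- function() {
  if (is.null(.fixture_env$nonuni)) {
    .fixture_env$nonuni <- suppressWarnings(
      run_nonuniform_comparison(fixture_tree(), tol_mmhg = 0.2, n_cycles = 20))
  }
  .fixture_env$nonuni
}

study_pwv <- function(report, cfg, path) {
  tab <- report$pwv
  tab$pwv[tab$config == cfg & tab$path == path]
}

study_metric <- function(report, cfg, site, metric) {
  tab <- report$metrics
  tab[[metric]][tab$config == cfg & tab$site == site]
}

# small tree used by solver unit tests: parent tube feeding one child
two_segment_tree <- function(child_dp = 20, child_dd = 20, D = 27) {
  wk_child <- {
    a <- pi * (child_dd / 1000)^2 / 4
    zc <- 1050 * bramwell_hill_pwv(D) / a / (133.322 / 1e-6)
    windkessel_outlet(R1 = zc, R2 = 6.33 - min(zc, 3), C = 0.3, P_out = 5)
  }
  arterial_tree(list(
    artery_segment(1, "parent", 50, 20, 20, D, group = "tube"),
    artery_segment(2, "child", 50, child_dp, child_dd, D, parent_id = 1,
                   windkessel = wk_child, group = "tube")
  ), sites = list(prox = list(segment = 1L, pos_cm = 25),
                  post = list(segment = 2L, pos_cm = 25)))
}

short_pulse_inflow <- function(q_mean = 15, q_pulse = 30, period = 0.8,
                               duty = 0.06) {
  tt <- seq(0, period, length.out = 1601)
  qb <- q_mean - q_pulse * 0.5 * duty
  q <- qb + ifelse(tt < duty * period, sin(pi * tt / (duty * period))^2, 0) * q_pulse
  q[length(q)] <- q[1]
  prescribed_inflow(tt, q)
}
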