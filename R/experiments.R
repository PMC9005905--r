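# Study runners and synthetic fixtures: the packaged reference tree, the
# staged-kidney-removal study, distensibility sweeps, and waveform
# generators for validating the transit-time estimator.

#' Arctangent compliance-curve parameters per artery class
#'
#' Centre, width and high-pressure cap (mmHg) of the pressure-dependent
#' tube law for the four wall classes of the reference tree. The pairs are
#' a documented calibration of the fixture: central elastic arteries carry
#' a moderately sharp compliance fall-off above diastolic pressure with a
#' linear high-pressure regime, muscular conduit arteries of the arm have a
#' compliance peak just below their diastolic operating point with a sharp
#' fall-off saturating near systole (which makes their foot-to-foot wave
#' speed strongly pressure-sensitive while bounding systolic stiffening),
#' the carotid is kept broad so that the proximal measurement site
#' contributes little pressure sensitivity of its own, and the hand
#' continues the muscular behaviour with a higher cap.
#'
#' @return A named list of per-class `list(p_peak_mmhg, p_width_mmhg,
#'   p_cap_mmhg)` entries.
#' @export
wall_law_classes <- function() {
  list(
    elastic   = list(p_peak_mmhg = 45, p_width_mmhg = 25, p_cap_mmhg = 120),
    carotid   = list(p_peak_mmhg = 30, p_width_mmhg = 50),
    muscular  = list(p_peak_mmhg = 55, p_width_mmhg = 10, p_cap_mmhg = 88),
    hand_foot = list(p_peak_mmhg = 60, p_width_mmhg = 15, p_cap_mmhg = 125),
    visceral  = list(p_peak_mmhg = 60, p_width_mmhg = 30)
  )
}

group_wall_law <- function(group) {
  cls <- wall_law_classes()
  switch(group,
         aorta = , iliac = , femoral = , tibial = cls$elastic,
         carotid = cls$carotid,
         subclavian = , brachial = , radial = cls$muscular,
         digital = cls$hand_foot,
         renal = , mesenteric = cls$visceral,
         cls$elastic)
}

#' Build the packaged reference arterial tree
#'
#' A reduced systemic tree (27 segments) with aorta, left carotid, left
#' arm-to-digital, symmetric iliac-femoral paths, two renal branches and
#' lumped visceral/head/contralateral beds. Segment dimensions follow the
#' classic published systemic-tree tables, with the arm, hand and leg
#' branches scaled so that the three standard measurement paths come out at
#' their conventional lengths: carotid-femoral 66 cm, carotid-radial 70 cm,
#' radial-digital 19 cm. The renal arteries carry ids 36 (left) and 38
#' (right) and the right external iliac id 44, matching the usual numbering
#' of the staged-kidney-removal configurations; all other ids are local to
#' this fixture. This is a calibrated reduced fixture, not a reproduction
#' of the full 143-segment research topology.
#'
#' Terminal Windkessel parameters are derived from the design operating
#' point: total peripheral resistance from the design peripheral pressure
#' drop and cardiac output, distributed over the outlets by their resting
#' flow fractions (the two kidneys together receive about 17% of cardiac
#' output, within the usually quoted 15-20% renal share), proximal
#' resistances matched to the terminal characteristic impedance (capped at
#' half the outlet total), and the peripheral compliance distributed in
#' proportion to flow. With the default elastance heart this lands the
#' model at roughly 114/73 mmHg aortic pressure, MAP 91 mmHg and a cardiac
#' output of 5 L/min at 75 bpm.
#'
#' @param co_lmin Design cardiac output, L/min.
#' @param wk_design_map_mmhg Design mean pressure at the terminal outlets,
#'   mmHg, used to size the Windkessel resistances; it sits below the
#'   aortic mean by the conduit resistive losses.
#' @param p_out_mmhg Venous outflow pressure, mmHg.
#' @param peripheral_compliance Total peripheral (Windkessel) compliance,
#'   mL/mmHg.
#' @param rho Blood density, kg/m3 (for characteristic impedances).
#' @return An [arterial_tree] with named sites `aorta`, `carotid`,
#'   `brachial`, `radial`, `digital`, `abdominal`, `iliac`, `femoral`,
#'   `renal_left`, `renal_right`.
#' @export
make_reference_tree <- function(co_lmin = 5, wk_design_map_mmhg = 81,
                                p_out_mmhg = 5,
                                peripheral_compliance = 0.9, rho = 1050) {
  seg <- function(id, name, group, L, dp, dd, D, parent)
    list(id = id, name = name, group = group, L = L, dp = dp, dd = dd, D = D,
         parent = parent)
  defs <- list(
    seg(1,  "ascending_aorta",      "aorta",      4.0, 29.0, 28.0, 27.0, NA),
    seg(2,  "aortic_arch_a",        "aorta",      2.5, 26.0, 24.5, 27.0, 1),
    seg(3,  "brachiocephalic",      "aorta",      3.5, 13.0, 12.5, 23.0, 1),
    seg(4,  "l_common_carotid",     "carotid",   17.0,  7.5,  6.5, 23.0, 2),
    seg(5,  "aortic_arch_b",        "aorta",      3.0, 24.0, 23.0, 27.0, 2),
    seg(7,  "thoracic_aorta",       "aorta",     16.0, 23.0, 19.0, 27.0, 5),
    seg(8,  "abdominal_aorta_a",    "aorta",      8.0, 18.0, 16.0, 27.0, 7),
    seg(9,  "celiac_mesenteric",    "mesenteric", 6.0,  9.0,  7.0, 10.0, 8),
    seg(10, "abdominal_aorta_b",    "aorta",      6.0, 16.0, 14.0, 27.0, 8),
    seg(36, "l_renal",              "renal",      3.5,  6.0,  5.5,  8.5, 10),
    seg(38, "r_renal",              "renal",      3.5,  6.0,  5.5,  8.5, 10),
    seg(11, "abdominal_aorta_c",    "aorta",     11.0, 13.0, 11.0, 27.0, 10),
    seg(12, "l_common_iliac",       "iliac",      6.0,  8.0,  7.5, 11.5, 11),
    seg(13, "r_common_iliac",       "iliac",      6.0,  8.0,  7.5, 11.5, 11),
    seg(14, "l_external_iliac",     "iliac",      8.5,  7.0,  6.5, 10.6, 12),
    seg(44, "r_external_iliac",     "iliac",      8.5,  7.0,  6.5, 10.6, 13),
    seg(15, "l_femoral",            "femoral",   25.0,  6.5,  5.0, 10.6, 14),
    seg(16, "l_leg_distal",         "tibial",    30.0,  5.5,  4.0,  9.0, 15),
    seg(17, "l_subclavian_axillary","subclavian",15.0,  9.0,  7.5,  8.5, 5),
    seg(18, "l_brachial",           "brachial",  24.0,  7.0,  5.0,  7.3, 17),
    seg(19, "l_radial",             "radial",    24.0,  4.4,  3.7,  6.4, 18),
    seg(21, "l_ulnar",              "radial",    24.0,  4.4,  3.7,  6.4, 18),
    seg(20, "l_hand_digital",       "digital",   20.0,  4.0,  3.5,  5.3, 19),
    seg(23, "r_carotid_head",       "carotid",   17.0,  7.5,  6.5, 23.0, 3),
    seg(24, "r_subclavian_axillary","subclavian",15.0,  9.0,  7.5,  8.5, 3),
    seg(25, "r_brachial",           "brachial",  24.0,  7.0,  5.0,  7.3, 24),
    seg(26, "r_forearm_hand",       "radial",    30.0,  4.4,  3.4,  6.4, 25)
  )
  # resting flow fractions of the terminal outlets (the remaining 1% of the
  # design conductance is carried by the conduit network itself)
  frac <- c("4" = 0.075, "23" = 0.105, "9" = 0.245, "36" = 0.085, "38" = 0.085,
            "16" = 0.13, "44" = 0.13, "21" = 0.045, "20" = 0.025, "26" = 0.065)
  co_mls <- co_lmin * 1000 / 60
  r_net <- (wk_design_map_mmhg - p_out_mmhg) / co_mls
  segments <- lapply(defs, function(d) {
    wk <- NULL
    key <- as.character(d$id)
    if (key %in% names(frac)) {
      r_tot <- r_net / frac[[key]]
      a_dist <- pi * (d$dd / 1000)^2 / 4
      zc <- rho * bramwell_hill_pwv(d$D, rho) / a_dist / RWK_TO_SI
      r1 <- min(zc, 0.5 * r_tot)
      wk <- windkessel_outlet(R1 = r1, R2 = r_tot - r1,
                              C = peripheral_compliance * frac[[key]],
                              P_out = p_out_mmhg)
    }
    artery_segment(d$id, d$name, d$L, d$dp, d$dd, d$D,
                   parent_id = if (is.na(d$parent)) NA_integer_ else d$parent,
                   windkessel = wk, group = d$group,
                   wall = group_wall_law(d$group))
  })
  sites <- list(
    aorta = list(segment = 1L, pos_cm = 2),
    carotid = list(segment = 4L, pos_cm = 5),
    brachial = list(segment = 18L, pos_cm = 12),
    radial = list(segment = 19L, pos_cm = 23),
    digital = list(segment = 20L, pos_cm = 18),
    abdominal = list(segment = 11L, pos_cm = 5.5),
    iliac = list(segment = 14L, pos_cm = 4),
    femoral = list(segment = 15L, pos_cm = 2.5),
    renal_left = list(segment = 36L, pos_cm = 1.75),
    renal_right = list(segment = 38L, pos_cm = 1.75)
  )
  arterial_tree(segments, sites,
                meta = list(description = "reduced reference systemic tree",
                            kidney_configuration = "2KDN"))
}

#' Single uniform tube fixture with a matched Windkessel
#'
#' One straight segment terminated by a Windkessel whose proximal
#' resistance matches the tube's characteristic impedance, with two named
#' sites (`prox`, `dist`) for transit measurements. The analytic
#' Bramwell-Hill wave speed at the reference pressure is attached as
#' `attr(tree, "pwv_ground_truth")`.
#'
#' @param length_m Tube length, m.
#' @param diameter_mm Lumen diameter, mm (no taper).
#' @param distensibility Wall distensibility, kPa^-1 x 10^-3.
#' @param site_sep_m Separation of the two measurement sites, m (centred).
#' @param rho Blood density, kg/m3.
#' @param q_mean_mls Design mean flow used to size the outlet resistance so
#'   the tube rests near the reference pressure.
#' @return An [arterial_tree] of one segment.
#' @export
make_single_tube_fixture <- function(length_m = 1.0, diameter_mm = 20,
                                     distensibility = 27.0, site_sep_m = 0.4,
                                     rho = 1050, q_mean_mls = 15) {
  stopifnot(length_m > 0, diameter_mm > 0, distensibility > 0,
            site_sep_m < length_m)
  c0 <- bramwell_hill_pwv(distensibility, rho)
  a <- pi * (diameter_mm / 1000)^2 / 4
  zc <- rho * c0 / a / RWK_TO_SI
  r_tot <- (100 - 5) / q_mean_mls
  r1 <- min(zc, 0.5 * r_tot)
  s <- artery_segment(1L, "tube", length_m * 100, diameter_mm, diameter_mm,
                      distensibility,
                      windkessel = windkessel_outlet(r1, r_tot - r1, C = 0.3,
                                                     P_out = 5),
                      group = "tube")
  mid <- length_m * 100 / 2
  tree <- arterial_tree(list(s), sites = list(
    prox = list(segment = 1L, pos_cm = mid - site_sep_m * 50),
    dist = list(segment = 1L, pos_cm = mid + site_sep_m * 50)))
  attr(tree, "pwv_ground_truth") <- c0
  tree
}

#' Measure the foot-to-foot wave speed along a single-tube fixture
#'
#' Drives the tube with periodic half-sine inflow pulses around the
#' reference operating pressure, waits for periodicity, and measures the
#' foot-to-foot transit between the two fixture sites.
#'
#' @param tube A [make_single_tube_fixture()] tree.
#' @param q_amp_mls Pulse amplitude, mL/s.
#' @param period Pulse period, s.
#' @param fs Analysis sampling rate, Hz (high, to resolve short transits).
#' @param ... Passed to [simulate()].
#' @return A `pwv_measurement`.
#' @export
single_tube_wave_speed <- function(tube, q_pulse_mls = 30, period = 0.8,
                                   fs = 9000, ...) {
  tt <- seq(0, period, length.out = 1601)
  duty <- 0.06
  # steady base flow holds the tube at its reference operating pressure; a
  # short sharp pulse rides on top so that its foot (much shorter than the
  # tube transit time) can be timed cleanly at both sites
  q_base <- 15 - q_pulse_mls * 0.5 * duty
  q <- q_base + ifelse(tt < duty * period,
                       sin(pi * tt / (duty * period))^2, 0) * q_pulse_mls
  q[length(q)] <- q[1]
  inflow <- prescribed_inflow(tt, q)
  wk <- tube$segments[[1]]$windkessel
  p0 <- wk$P_out + 15 * (wk$R1 + wk$R2)
  res <- simulate(tube, inflow = inflow, fs_out = fs, p_init_mmhg = p0,
                  tol_mmhg = 0.5, ...)
  path <- arterial_path(tube, "prox", "dist")
  # noise-free synthetic run: smooth lightly so the short pulse is not blurred
  ptt <- transit_time(get_waveform(res, "prox"), get_waveform(res, "dist"),
                      cutoff_hz = 100)
  compute_pwv(path, ptt)
}

#' Synthetic delayed waveform pair
#'
#' Constructs a proximal periodic pressure waveform from an analytic
#' template and a distal copy delayed by an exact (continuous) delay, with
#' optional independent Gaussian noise on both, for validating the
#' transit-time estimator against known ground truth.
#'
#' @param template `"physiologic"` (logistic upstroke, exponential decay,
#'   dicrotic bump) or `"gaussian-upstroke"` (Gaussian systolic bump).
#' @param delay Ground-truth delay, s (less than one period).
#' @param fs Sampling rate, Hz.
#' @param period Cardiac period, s.
#' @param noise_mmhg RMS of additive white noise, mmHg.
#' @param seed Seed for the noise generator.
#' @return List with `proximal`, `distal` ([pressure_waveform()]s) and
#'   `delay` (the ground truth).
#' @export
make_delayed_pair <- function(template = c("physiologic", "gaussian-upstroke"),
                              delay = 0.08, fs = 900, period = 0.8,
                              noise_mmhg = 0, seed = NULL) {
  template <- match.arg(template)
  if (delay >= period) stop("delay must be smaller than the period")
  shape <- function(t) {
    s <- (t %% period) / period
    if (template == "gaussian-upstroke") {
      73 + 45 * exp(-((s - 0.35) / 0.10)^2)
    } else {
      up <- 1 / (1 + exp(-(s - 0.15) / 0.016))
      dec <- exp(-pmax(0, s - 0.15) / 0.35)
      dic <- 0.12 * exp(-((s - 0.55) / 0.05)^2)
      73 + 45 * (up * dec + dic) / 1.045
    }
  }
  tt <- seq(1 / fs, period, by = 1 / fs)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tt)
  noise <- function() if (noise_mmhg > 0) stats::rnorm(n, 0, noise_mmhg) else 0
  prox <- pressure_waveform(tt, shape(tt) + noise(), site = "proximal",
                            period = period)
  dist <- pressure_waveform(tt, shape(tt - delay) + noise(), site = "distal",
                            period = period)
  list(proximal = prox, distal = dist, delay = delay)
}

# ---- published reference tables --------------------------------------------

#' Reference blood-pressure values for the four kidney configurations
#'
#' Published reference values (mmHg) for systolic, early-diastolic,
#' end-diastolic and pulse pressure at four arterial sites under the
#' two-kidney control (2KDN), single-kidney (1KDN), no-kidney (0KDN) and
#' transplant (TX) configurations of the full-scale staged-kidney-removal
#' simulation study. Used for consistency cross-checks of the reporting
#' conventions.
#'
#' @return A tibble with columns `site`, `metric`, `2KDN`, `1KDN`, `0KDN`,
#'   `TX`.
#' @export
reference_bp_table <- function() {
  tibble::tribble(
    ~site, ~metric, ~`2KDN`, ~`1KDN`, ~`0KDN`, ~`TX`,
    "aortic",  "SBP",       118, 122, 127, 123,
    "aortic",  "early_DBP",  91,  92,  98,  91,
    "aortic",  "end_DBP",    73,  72,  74,  75,
    "aortic",  "PP",         45,  50,  53,  48,
    "carotid", "SBP",       122, 125, 129, 126,
    "carotid", "early_DBP",  97,  98, 100,  97,
    "carotid", "end_DBP",    76,  74,  75,  77,
    "carotid", "PP",         46,  51,  54,  49,
    "radial",  "SBP",       129, 132, 135, 133,
    "radial",  "early_DBP",  98,  99, 100,  99,
    "radial",  "end_DBP",    70,  71,  69,  72,
    "radial",  "PP",         59,  61,  66,  61,
    "digital", "SBP",       133, 138, 141, 135,
    "digital", "early_DBP", 101, 102, 103, 102,
    "digital", "end_DBP",    73,  75,  74,  76,
    "digital", "PP",         60,  63,  67,  59
  )
}

#' Reference PWV values for the four kidney configurations
#'
#' Published reference foot-to-foot PWV values (m/s) of the full-scale
#' study, by path and configuration, with the default (healthy) wall
#' distensibility.
#'
#' @return A tibble with columns `path`, `2KDN`, `1KDN`, `0KDN`, `TX`.
#' @export
reference_pwv_table <- function() {
  tibble::tribble(
    ~path, ~`2KDN`, ~`1KDN`, ~`0KDN`, ~`TX`,
    "cf", 6.02, 6.50,  6.69,  6.56,
    "cr", 6.33, 7.04,  7.60,  6.79,
    "rd", 10.00, 10.53, 11.11, 10.34
  )
}

# ---- study runners ----------------------------------------------------------

default_paths <- function() {
  list(cf = c("carotid", "femoral"),
       cr = c("carotid", "radial"),
       rd = c("radial", "digital"))
}

run_one_config <- function(tree, config, scenario, heart, wall, sites, paths, ...) {
  cfg_tree <- apply_kidney_configuration(tree, config)
  cfg_tree <- apply_distensibility_scenario(cfg_tree, scenario)
  wanted <- union(sites, unlist(paths, use.names = FALSE))
  extract <- intersect(wanted, names(cfg_tree$sites))
  keep <- intersect(sites, names(cfg_tree$sites))
  res <- simulate(cfg_tree, heart = heart, wall = wall, sites = extract, ...)
  metrics <- do.call(rbind, lapply(keep, function(nm) {
    m <- wave_metrics(get_waveform(res, nm))
    tibble::tibble(config = config, site = nm, SBP = m$SBP,
                   early_DBP = m$early_DBP, end_DBP = m$end_DBP, PP = m$PP,
                   MAP = m$MAP)
  }))
  pwv <- do.call(rbind, lapply(names(paths), function(pn) {
    ab <- paths[[pn]]
    if (!all(ab %in% extract)) return(NULL)
    pm <- measure_pwv(res, cfg_tree, ab[1], ab[2])
    tibble::tibble(config = config, path = pn, distance_m = pm$distance_m,
                   ptt_s = pm$ptt, pwv = pm$pwv)
  }))
  peak_flow <- do.call(rbind, lapply(keep, function(nm) {
    tibble::tibble(config = config, site = nm,
                   peak_flow_mls = max(res$sites[[nm]]$flow),
                   mean_flow_mls = mean(res$sites[[nm]]$flow))
  }))
  conv <- tibble::tibble(config = config, converged = res$converged,
                         cycles = res$cycles_run,
                         cardiac_output_lmin = res$cardiac_output_lmin,
                         stroke_volume_ml = res$stroke_volume_ml)
  list(metrics = metrics, pwv = pwv, peak_flow = peak_flow, convergence = conv,
       result = res)
}

#' Run the staged-kidney-removal study
#'
#' Simulates the requested kidney configurations on the reference tree with
#' identical heart, wall and Windkessel parameters, and collects pressure
#' metrics, foot-to-foot PWV over the standard paths, and peak site flows.
#' Non-converged runs are flagged in the convergence table and excluded
#' from the metric tables.
#'
#' @param tree Reference tree (default [make_reference_tree()]).
#' @param configs Subset of `c("2KDN","1KDN","0KDN","TX")`.
#' @param scenario Optional [distensibility_scenario()] applied to every
#'   configuration.
#' @param heart,wall Model parameters shared by all runs.
#' @param sites Sites to report.
#' @param paths Named list of `c(proximal, distal)` site pairs.
#' @param keep_results Keep the full simulation results in the report.
#' @param ... Passed to [simulate()].
#' @return A list of class `study_report` with tibbles `metrics`, `pwv`,
#'   `peak_flow`, `convergence` (and `results` if requested).
#' @export
run_kidney_study <- function(tree = make_reference_tree(),
                             configs = c("2KDN", "1KDN", "0KDN", "TX"),
                             scenario = NULL,
                             heart = heart_params(), wall = wall_params(),
                             sites = c("aorta", "carotid", "radial", "digital",
                                       "femoral", "abdominal"),
                             paths = default_paths(),
                             keep_results = FALSE, ...) {
  configs <- match.arg(configs, several.ok = TRUE)
  runs <- lapply(configs, function(cfg)
    run_one_config(tree, cfg, scenario, heart, wall, sites, paths, ...))
  names(runs) <- configs
  ok <- vapply(runs, function(r) r$convergence$converged, logical(1))
  rep <- list(
    metrics = do.call(rbind, lapply(runs[ok], `[[`, "metrics")),
    pwv = do.call(rbind, lapply(runs[ok], `[[`, "pwv")),
    peak_flow = do.call(rbind, lapply(runs[ok], `[[`, "peak_flow")),
    convergence = do.call(rbind, lapply(runs, `[[`, "convergence")))
  if (keep_results) rep$results <- lapply(runs, `[[`, "result")
  class(rep) <- "study_report"
  rep
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$convergence)
  if (!is.null(x$pwv)) print(x$pwv)
  invisible(x)
}

#' Run a uniform distensibility sweep
#'
#' Repeats the kidney study over a set of tree-wide distensibility scale
#' factors (negative = stiffening).
#'
#' @param tree Reference tree.
#' @param factors Fractional distensibility changes (each > -1).
#' @param configs Kidney configurations per factor.
#' @param ... Passed to [run_kidney_study()].
#' @return A `study_report` whose tibbles carry an extra `factor` column.
#' @export
run_distensibility_sweep <- function(tree = make_reference_tree(),
                                     factors = c(-0.8, -0.4, -0.2, 0, 0.2, 0.4, 0.8),
                                     configs = c("2KDN", "1KDN", "0KDN", "TX"),
                                     ...) {
  if (any(factors <= -1)) stop("factors must be > -1")
  out <- lapply(factors, function(f) {
    rep <- run_kidney_study(tree, configs = configs,
                            scenario = distensibility_scenario("uniform_scale",
                                                               factor = f), ...)
    for (nm in c("metrics", "pwv", "peak_flow", "convergence"))
      if (!is.null(rep[[nm]]) && nrow(rep[[nm]])) rep[[nm]]$factor <- f
    rep
  })
  rep <- list(metrics = do.call(rbind, lapply(out, `[[`, "metrics")),
              pwv = do.call(rbind, lapply(out, `[[`, "pwv")),
              peak_flow = do.call(rbind, lapply(out, `[[`, "peak_flow")),
              convergence = do.call(rbind, lapply(out, `[[`, "convergence")))
  class(rep) <- "study_report"
  rep
}

#' Compare non-uniform stiffening without kidneys against the control
#'
#' Runs the two-kidney control with default distensibility and the
#' no-kidney configuration with the diameter-stratified distensibility
#' reduction, and reports the paired PWV percentage changes together with
#' the aortic pressure/flow comparison.
#'
#' @param tree Reference tree.
#' @param class_rule Diameter-class rule; default
#'   [default_diameter_class_rule()].
#' @param ... Passed to [run_kidney_study()].
#' @return A list of class `nonuniform_report` with `pwv_change` (per-path
#'   percentages), `control`/`stiffened` study reports and the aortic
#'   waveform comparison table.
#' @export
run_nonuniform_comparison <- function(tree = make_reference_tree(),
                                      class_rule = default_diameter_class_rule(),
                                      ...) {
  control <- run_kidney_study(tree, configs = "2KDN", scenario = NULL,
                              keep_results = TRUE, ...)
  stiff <- run_kidney_study(tree, configs = "0KDN",
                            scenario = distensibility_scenario(
                              "nonuniform_by_diameter", class_rule = class_rule),
                            keep_results = TRUE, ...)
  pc <- merge(control$pwv[, c("path", "pwv")], stiff$pwv[, c("path", "pwv")],
              by = "path", suffixes = c("_control", "_stiffened"))
  pc$pct_change <- 100 * (pc$pwv_stiffened - pc$pwv_control) / pc$pwv_control
  ao_c <- control$results[["2KDN"]]$sites$aorta
  ao_s <- stiff$results[["0KDN"]]$sites$aorta
  aortic <- tibble::tibble(
    quantity = c("SBP_mmHg", "peak_flow_mls"),
    control = c(max(ao_c$pressure), max(ao_c$flow)),
    stiffened = c(max(ao_s$pressure), max(ao_s$flow)))
  structure(list(pwv_change = tibble::as_tibble(pc), aortic = aortic,
                 control = control, stiffened = stiff),
            class = "nonuniform_report")
}

#' @export
print.nonuniform_report <- function(x, ...) {
  cat("<nonuniform_report>\n")
  print(x$pwv_change)
  print(x$aortic)
  invisible(x)
}
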