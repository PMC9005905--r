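#' Wall model parameters
#'
#' Bundles the blood and arterial-wall constants shared by the tube law and
#' the wave-speed conversions.
#'
#' @param rho_blood Blood density in kg/m3. Default 1050, the conventional
#'   value for whole blood.
#' @param mu_blood Dynamic blood viscosity in Pa.s.
#' @param p_ref_mmhg Reference transmural pressure (mmHg) at which segment
#'   distensibility values are defined.
#' @param pwv_diameter_coeffs Numeric `c(a, b)` of the inverse power law
#'   `c = a * d^(-b)` (c in m/s, d in mm) used to fill in wall stiffness for
#'   segments whose distensibility is not given. The defaults are calibrated
#'   so that a 25 mm aorta gives 5.9 m/s and a 3 mm radial artery 12.2 m/s.
#' @param tube_law_kind `"linear-elastic"` (compliance constant around
#'   `p_ref_mmhg`) or `"pressure-dependent"` (arctangent-shaped compliance,
#'   maximal at a segment-specific pressure and falling off on both sides;
#'   constrained to match the segment distensibility at `p_ref_mmhg`).
#' @param pressure_law Numeric `c(p_peak_mmhg, p_width_mmhg)`: default centre
#'   and width of the arctangent compliance curve, used for segments that do
#'   not carry their own `wall` overrides. Ignored by the linear law.
#'
#' @return A list of class `wall_params`.
#' @export
wall_params <- function(rho_blood = 1050,
                        mu_blood = 0.004,
                        p_ref_mmhg = 100,
                        pwv_diameter_coeffs = c(a = 17.8, b = 0.343),
                        tube_law_kind = c("pressure-dependent", "linear-elastic"),
                        pressure_law = c(p_peak_mmhg = 30, p_width_mmhg = 45)) {
  tube_law_kind <- match.arg(tube_law_kind)
  stopifnot(rho_blood > 0, mu_blood > 0, p_ref_mmhg > 0)
  a <- unname(pwv_diameter_coeffs[1]); b <- unname(pwv_diameter_coeffs[2])
  if (!(a > 0) || b < 0) stop("pwv_diameter_coeffs require a > 0 and b >= 0")
  structure(list(rho_blood = rho_blood, mu_blood = mu_blood,
                 p_ref_mmhg = p_ref_mmhg,
                 pwv_diameter_coeffs = c(a = a, b = b),
                 tube_law_kind = tube_law_kind,
                 pressure_law = c(p_peak_mmhg = unname(pressure_law[1]),
                                  p_width_mmhg = unname(pressure_law[2]))),
            class = "wall_params")
}

#' Bramwell-Hill pulse wave velocity from distensibility
#'
#' Converts arterial distensibility to local pulse wave velocity via
#' `PWV = 1 / sqrt(rho * D)`.
#'
#' @param distensibility Distensibility in kPa^-1 x 10^-3 (the unit arterial
#'   distensibility tables are usually printed in, e.g. 27.0 for a healthy
#'   aorta).
#' @param rho Blood density, kg/m3.
#' @return PWV in m/s (vectorised over `distensibility`).
#' @export
#' @examples
#' bramwell_hill_pwv(27.0)  # healthy aortic value -> about 5.9 m/s
bramwell_hill_pwv <- function(distensibility, rho = 1050) {
  if (any(!is.finite(distensibility)) || any(distensibility <= 0))
    stop("distensibility must be positive and finite")
  if (rho <= 0) stop("rho must be positive")
  1 / sqrt(rho * distensibility * DIST_UNIT_TO_PA)
}

#' Distensibility from pulse wave velocity
#'
#' Exact algebraic inverse of [bramwell_hill_pwv()].
#'
#' @param pwv Pulse wave velocity in m/s.
#' @param rho Blood density, kg/m3.
#' @return Distensibility in kPa^-1 x 10^-3.
#' @export
distensibility_from_pwv <- function(pwv, rho = 1050) {
  if (any(!is.finite(pwv)) || any(pwv <= 0)) stop("pwv must be positive and finite")
  1 / (rho * pwv^2) / DIST_UNIT_TO_PA
}

#' PWV from lumen diameter (inverse power law)
#'
#' Approximates local pulse wave velocity as an inverse power function of
#' lumen diameter, `c = a * d^(-b)`. Used only to fill in wall stiffness for
#' segments whose distensibility is not specified.
#'
#' @param diameter_mm Lumen diameter in mm.
#' @param coeffs Numeric `c(a, b)`; see [wall_params()].
#' @return PWV in m/s.
#' @export
pwv_from_diameter <- function(diameter_mm, coeffs = wall_params()$pwv_diameter_coeffs) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  a <- unname(coeffs[1]); b <- unname(coeffs[2])
  if (!(a > 0) || b < 0) stop("coeffs require a > 0 and b >= 0")
  a * diameter_mm^(-b)
}

#' Area compliance per unit length
#'
#' Standard identity `C_A = A / (rho * c^2)` linking cross-sectional area and
#' local wave speed to the tube law slope; equivalently `D = C_A / A`.
#'
#' @param area_m2 Cross-sectional area, m2.
#' @param pwv Local wave speed, m/s.
#' @param rho Blood density, kg/m3.
#' @return Area compliance per unit length, m2/Pa.
#' @export
compliance_per_length <- function(area_m2, pwv, rho = 1050) {
  stopifnot(all(area_m2 > 0), all(pwv > 0), rho > 0)
  area_m2 / (rho * pwv^2)
}

#' Fit a blood density to a printed distensibility-PWV table
#'
#' Brute-force scan for the blood density that makes a set of
#' (distensibility, PWV) pairs maximally consistent with the Bramwell-Hill
#' relation, minimising the largest absolute deviation from the printed PWV
#' values. Useful to recover the density implied by a published table whose
#' source does not state it.
#'
#' @param distensibility Distensibility values, kPa^-1 x 10^-3.
#' @param pwv Printed PWV values, m/s.
#' @param range Density search interval, kg/m3.
#' @param step Scan step, kg/m3.
#' @return List with `rho` (best density) and `max_error` (largest absolute
#'   PWV deviation at that density, m/s).
#' @export
fit_blood_density <- function(distensibility, pwv, range = c(1000, 1100), step = 0.5) {
  stopifnot(length(distensibility) == length(pwv), length(pwv) > 0)
  rhos <- seq(range[1], range[2], by = step)
  errs <- vapply(rhos, function(r) max(abs(bramwell_hill_pwv(distensibility, r) - pwv)),
                 numeric(1))
  list(rho = rhos[which.min(errs)], max_error = min(errs))
}

#' Reference distensibility override table
#'
#' Segmental arterial distensibility (kPa^-1 x 10^-3) for the healthy
#' default model (`d_default`) and for end-stage renal disease subjects
#' (`d_esrd`), as compiled from the published in-vivo literature. Values
#' measured in vivo exist for the aorta, carotid, brachial and radial
#' arteries; the remaining groups are interpolated diseased estimates.
#'
#' @return A tibble with columns `group`, `d_default`, `d_esrd`, `source`
#'   (`"in_vivo"` or `"interpolated"`).
#' @export
invivo_distensibility_table <- function() {
  tibble::tibble(
    group     = c("aorta", "carotid", "femoral", "tibial", "brachial",
                  "radial", "coronary", "cerebral", "digital", "dorsal"),
    d_default = c(27.0, 23.0, 10.6, 9.0, 7.3, 6.4, 6.1, 8.1, 5.3, 5.7),
    d_esrd    = c(21.0, 18.0, 6.6, 5.0, 3.5, 2.6, 4.5, 4.1, 3.4, 3.2),
    source    = c("in_vivo", "in_vivo", "interpolated", "interpolated",
                  "in_vivo", "in_vivo", "interpolated", "interpolated",
                  "interpolated", "interpolated")
  )
}

#' Uniformly scale distensibility of every segment
#'
#' Multiplies every segment's distensibility by `1 + factor`, emulating a
#' tree-wide proportional stiffening (`factor < 0`) or softening
#' (`factor > 0`).
#'
#' @param tree An [arterial_tree].
#' @param factor Fractional change, must be greater than -1 (e.g. -0.4 for a
#'   40% distensibility reduction).
#' @return The modified tree.
#' @export
scale_distensibility_uniform <- function(tree, factor) {
  stopifnot(inherits(tree, "arterial_tree"))
  if (!is.finite(factor) || factor <= -1) stop("factor must be > -1")
  for (id in names(tree$segments))
    tree$segments[[id]]$distensibility <- tree$segments[[id]]$distensibility * (1 + factor)
  tree
}

#' Default diameter-class stiffening rule
#'
#' The diameter-stratified distensibility reduction emulating stronger
#' stiffening of central elastic arteries than of peripheral muscular ones:
#' -40% for mean lumen diameter > 14 mm, -25% for 11-14 mm, -15% for
#' 8-11 mm, -10% for 3-8 mm and -5% at or below 3 mm.
#'
#' @return A data.frame with columns `d_min`, `d_max` (mm, lower-exclusive /
#'   upper-inclusive) and `reduction` (fraction).
#' @export
default_diameter_class_rule <- function() {
  data.frame(d_min = c(14, 11, 8, 3, 0),
             d_max = c(Inf, 14, 11, 8, 3),
             reduction = c(0.40, 0.25, 0.15, 0.10, 0.05))
}

#' Diameter-stratified distensibility reduction
#'
#' Reduces each segment's distensibility by the fraction of the diameter
#' class its mean lumen diameter falls in. Classes are lower-exclusive and
#' upper-inclusive (a 14 mm vessel belongs to the 11-14 mm class).
#'
#' @param tree An [arterial_tree].
#' @param class_rule Data frame as returned by
#'   [default_diameter_class_rule()]; classes must partition the positive
#'   diameters without overlap.
#' @return The modified tree.
#' @export
scale_distensibility_nonuniform <- function(tree, class_rule = default_diameter_class_rule()) {
  stopifnot(inherits(tree, "arterial_tree"))
  rule <- class_rule[order(class_rule$d_min), ]
  if (any(rule$d_max[-nrow(rule)] != rule$d_min[-1]) && nrow(rule) > 1) {
    # partition check: sorted classes must tile (0, Inf]
    if (!all(abs(rule$d_max[-nrow(rule)] - rule$d_min[-1]) < 1e-12))
      stop("class_rule does not partition diameters")
  }
  if (rule$d_min[1] > 0 || !is.infinite(rule$d_max[nrow(rule)]))
    stop("class_rule must cover all positive diameters")
  if (any(rule$reduction <= -1)) stop("reductions must be > -1")
  for (id in names(tree$segments)) {
    seg <- tree$segments[[id]]
    d <- (seg$diam_prox_mm + seg$diam_dist_mm) / 2
    k <- which(d > rule$d_min & d <= rule$d_max)
    if (length(k) != 1) stop("diameter ", d, " mm not classifiable by rule")
    tree$segments[[id]]$distensibility <- seg$distensibility * (1 - rule$reduction[k])
  }
  tree
}

#' Apply an in-vivo distensibility override table
#'
#' Sets the distensibility of segments whose `group` appears in the override
#' table to the tabulated in-vivo value, and reduces every other segment by
#' `default_reduction` to emulate diffusely diseased vessels. Printed
#' override values are applied verbatim; the fractional reduction is used
#' only for groups without a printed value.
#'
#' @param tree An [arterial_tree].
#' @param overrides Named numeric vector (group -> distensibility,
#'   kPa^-1 x 10^-3) or a data frame with columns `group` and one of
#'   `d_esrd`/`value`. Defaults to the in-vivo/interpolated column of
#'   [invivo_distensibility_table()].
#' @param default_reduction Fractional reduction applied to segments whose
#'   group has no override. Default 0.30.
#' @return The modified tree.
#' @export
apply_invivo_table <- function(tree,
                               overrides = invivo_distensibility_table(),
                               default_reduction = 0.30) {
  stopifnot(inherits(tree, "arterial_tree"))
  if (is.data.frame(overrides)) {
    val <- if ("d_esrd" %in% names(overrides)) overrides$d_esrd else overrides$value
    overrides <- stats::setNames(val, overrides$group)
  }
  if (is.null(overrides) || length(overrides) == 0) overrides <- stats::setNames(numeric(0), character(0))
  if (!is.numeric(overrides) || (length(overrides) && is.null(names(overrides))))
    stop("overrides must map artery group names to distensibility values")
  if (default_reduction <= -1) stop("default_reduction must be > -1")
  groups <- vapply(tree$segments, function(s) s$group %||% "", character(1))
  unused <- setdiff(names(overrides), groups)
  if (length(unused) && length(overrides))
    warning("override groups matching no segment: ", paste(unused, collapse = ", "))
  for (id in names(tree$segments)) {
    g <- tree$segments[[id]]$group %||% ""
    if (g %in% names(overrides)) {
      tree$segments[[id]]$distensibility <- unname(overrides[[g]])
    } else {
      tree$segments[[id]]$distensibility <-
        tree$segments[[id]]$distensibility * (1 - default_reduction)
    }
  }
  tree
}

#' Distensibility scenario descriptor
#'
#' Declares how segment distensibility should be modified before a
#' simulation: not at all (`"default"`), scaled by the same fraction
#' everywhere (`"uniform_scale"`), reduced per diameter class
#' (`"nonuniform_by_diameter"`), or overridden from an in-vivo table with a
#' fallback reduction (`"invivo_overrides"`).
#'
#' @param kind Scenario kind.
#' @param factor Fractional change for `"uniform_scale"` (> -1).
#' @param class_rule Diameter-class rule for `"nonuniform_by_diameter"`;
#'   default [default_diameter_class_rule()].
#' @param overrides Override table for `"invivo_overrides"`; default
#'   [invivo_distensibility_table()].
#' @param default_reduction Fallback reduction for `"invivo_overrides"`.
#' @return A list of class `distensibility_scenario`.
#' @export
distensibility_scenario <- function(kind = c("default", "uniform_scale",
                                             "nonuniform_by_diameter",
                                             "invivo_overrides"),
                                    factor = 0,
                                    class_rule = default_diameter_class_rule(),
                                    overrides = invivo_distensibility_table(),
                                    default_reduction = 0.30) {
  kind <- match.arg(kind)
  if (kind == "uniform_scale" && factor <= -1) stop("factor must be > -1")
  structure(list(kind = kind, factor = factor, class_rule = class_rule,
                 overrides = overrides, default_reduction = default_reduction),
            class = "distensibility_scenario")
}

#' Apply a distensibility scenario to a tree
#'
#' @param tree An [arterial_tree].
#' @param scenario A [distensibility_scenario()] (or `NULL` for default).
#' @return The modified tree.
#' @export
apply_distensibility_scenario <- function(tree, scenario = NULL) {
  if (is.null(scenario)) return(tree)
  stopifnot(inherits(scenario, "distensibility_scenario"))
  switch(scenario$kind,
         default = tree,
         uniform_scale = scale_distensibility_uniform(tree, scenario$factor),
         nonuniform_by_diameter =
           scale_distensibility_nonuniform(tree, scenario$class_rule),
         invivo_overrides =
           apply_invivo_table(tree, scenario$overrides, scenario$default_reduction))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
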