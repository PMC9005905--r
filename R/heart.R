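#' Elastance heart model parameters
#'
#' Parameters of the time-varying elastance left ventricle that drives the
#' aortic root: chamber pressure is `P_lv = E(t) * (V_lv - V0)` with `E(t)`
#' cycling between `E_min` and `E_max` along a double-Hill activation curve.
#' Ejection passes through an ideal valve with a small series resistance; the
#' ventricle refills from a constant-pressure preload through a filling
#' resistance (no atrium is modelled).
#'
#' The defaults are a calibration to a resting healthy adult operating
#' point: heart rate 75 bpm, cardiac output near 5 L/min and aortic pressure
#' near 118/73 mmHg when coupled to the reference arterial tree.
#'
#' @param E_max,E_min Peak systolic / diastolic elastance, mmHg/mL.
#' @param V0 Unstressed (dead) volume, mL.
#' @param period Cardiac period, s (0.8 s = 75 bpm).
#' @param t_peak_frac Fraction of the cycle at which elastance peaks.
#' @param preload_mmhg Constant filling pressure, mmHg.
#' @param R_valve Aortic valve series resistance, mmHg.s/mL.
#' @param R_fill Filling resistance, mmHg.s/mL.
#' @param V_init Initial ventricular volume, mL.
#' @return A list of class `heart_params`.
#' @export
heart_params <- function(E_max = 1.75, E_min = 0.07, V0 = 10, period = 0.8,
                         t_peak_frac = 0.381, preload_mmhg = 9.5,
                         R_valve = 0.006, R_fill = 0.01, V_init = 125) {
  stopifnot(E_max > E_min, E_min > 0, period > 0,
            t_peak_frac > 0, t_peak_frac < 1,
            R_valve > 0, R_fill > 0, V_init > V0)
  structure(list(E_max = E_max, E_min = E_min, V0 = V0, period = period,
                 t_peak_frac = t_peak_frac, preload_mmhg = preload_mmhg,
                 R_valve = R_valve, R_fill = R_fill, V_init = V_init),
            class = "heart_params")
}

# Raw (unnormalised) double-Hill activation shape on t in [0, 1).
# Shape constants follow the standard normalised elastance curve family;
# tau1/tau2 are rescaled with t_peak_frac so the peak lands where requested.
double_hill_raw <- function(t_frac, t_peak_frac) {
  scale <- t_peak_frac / 0.38115   # unscaled curve peaks at 0.38115 of the cycle
  tau1 <- 0.269 * scale
  tau2 <- 0.452 * scale
  g1 <- (t_frac / tau1)^1.32
  g2 <- (t_frac / tau2)^21.9
  (g1 / (1 + g1)) * (1 / (1 + g2))
}

#' Normalised elastance curve
#'
#' Double-Hill activation: a smooth systolic rise to 1 at `t_peak_frac`
#' followed by rapid relaxation, essentially zero through diastole.
#' Out-of-range times are wrapped modulo one cycle.
#'
#' @param t_frac Time as a fraction of the cardiac cycle.
#' @param t_peak_frac Fraction of the cycle at which the curve peaks.
#' @return Values in `[0, 1]` (vectorised).
#' @export
normalized_elastance <- function(t_frac, t_peak_frac = 0.381) {
  t_frac <- t_frac %% 1
  peak <- stats::optimize(double_hill_raw, c(0.05, 0.95), maximum = TRUE,
                          t_peak_frac = t_peak_frac)$objective
  double_hill_raw(t_frac, t_peak_frac) / peak
}

#' Initial heart state
#' @param params [heart_params()].
#' @return A list of class `heart_state` with ventricular volume `V_lv`
#'   (mL), `valve_open` flag, outflow `Q_out` (mL/s) and cycle time `t` (s).
#' @export
heart_state <- function(params = heart_params()) {
  structure(list(V_lv = params$V_init, valve_open = FALSE, Q_out = 0, t = 0),
            class = "heart_state")
}

#' Advance the ventricle one time step against a given root pressure
#'
#' One explicit step of the elastance ventricle: the valve opens when
#' ventricular pressure exceeds root pressure, ejects through the valve
#' resistance, and closes on flow reversal (no regurgitation); the chamber
#' refills from the constant preload whenever ventricular pressure is below
#' it.
#'
#' @param state A [heart_state()].
#' @param p_root_mmhg Arterial root pressure, mmHg.
#' @param params [heart_params()].
#' @param dt Time step, s (must be much smaller than the period).
#' @return List with `state` (advanced) and `Q` (flow into the root, mL/s).
#' @export
ventricle_step <- function(state, p_root_mmhg, params, dt) {
  e <- normalized_elastance(state$t / params$period, params$t_peak_frac)
  E <- params$E_min + (params$E_max - params$E_min) * e
  P_lv <- E * (state$V_lv - params$V0)
  if (state$valve_open) {
    Q <- (P_lv - p_root_mmhg) / params$R_valve
    if (Q <= 0) { Q <- 0; state$valve_open <- FALSE }
  } else {
    if (P_lv > p_root_mmhg) {
      state$valve_open <- TRUE
      Q <- (P_lv - p_root_mmhg) / params$R_valve
    } else Q <- 0
  }
  Q_fill <- max(0, (params$preload_mmhg - P_lv) / params$R_fill)
  state$V_lv <- max(params$V0 + 1e-6, state$V_lv + dt * (Q_fill - Q))
  state$Q_out <- Q
  state$t <- state$t + dt
  list(state = state, Q = Q)
}

#' Simulate the elastance heart against a lumped Windkessel afterload
#'
#' Zero-dimensional companion to the full tree simulation: the ventricle
#' ejects into a single three-element Windkessel. Used for calibrating and
#' testing the heart model in isolation.
#'
#' @param params [heart_params()].
#' @param wk [windkessel_outlet()] afterload.
#' @param n_cycles Number of cardiac cycles to run.
#' @param dt Time step, s.
#' @return List with per-sample traces (`time`, `P_root`, `P_lv`, `Q`,
#'   `V_lv`) of the final cycle and summary scalars `stroke_volume` (mL),
#'   `cardiac_output` (L/min), `SBP`, `DBP` (mmHg) and `outflow_volume`
#'   (mL through the Windkessel over the final cycle).
#' @export
simulate_lumped <- function(params = heart_params(),
                            wk = windkessel_outlet(0.035, 0.97, 1.8),
                            n_cycles = 12, dt = 2e-4) {
  n_per <- round(params$period / dt)
  state <- heart_state(params)
  P_wk <- 75
  trace <- NULL
  for (cy in seq_len(n_cycles)) {
    tr <- matrix(0, n_per, 5, dimnames = list(NULL, c("time", "P_root", "P_lv", "Q", "V_lv")))
    for (i in seq_len(n_per)) {
      e <- normalized_elastance(state$t / params$period, params$t_peak_frac)
      E <- params$E_min + (params$E_max - params$E_min) * e
      P_lv <- E * (state$V_lv - params$V0)
      # valve logic with the series R1 absorbed into the ejection path
      if (!state$valve_open && P_lv > P_wk) state$valve_open <- TRUE
      Q <- if (state$valve_open) (P_lv - P_wk) / (params$R_valve + wk$R1) else 0
      if (Q <= 0) { Q <- 0; state$valve_open <- FALSE }
      P_root <- P_wk + Q * wk$R1
      # implicit update of the Windkessel storage pressure
      P_wk <- (P_wk + dt / wk$C * (Q + wk$P_out / wk$R2)) / (1 + dt / (wk$R2 * wk$C))
      Q_fill <- max(0, (params$preload_mmhg - P_lv) / params$R_fill)
      state$V_lv <- max(params$V0 + 1e-6, state$V_lv + dt * (Q_fill - Q))
      state$t <- state$t + dt
      tr[i, ] <- c(state$t, P_root, P_lv, Q, state$V_lv)
    }
    trace <- tr
  }
  sv <- sum(trace[, "Q"]) * dt
  list(time = trace[, "time"], P_root = trace[, "P_root"], P_lv = trace[, "P_lv"],
       Q = trace[, "Q"], V_lv = trace[, "V_lv"],
       stroke_volume = sv,
       cardiac_output = sv / params$period * 60 / 1000,
       SBP = max(trace[, "P_root"]), DBP = min(trace[, "P_root"]),
       outflow_volume = sv)
}

#' Prescribed aortic inflow boundary
#'
#' Wraps a periodic time/flow table for use as the proximal boundary in
#' place of the elastance heart (controlled solver tests).
#'
#' @param time Sample times, s, ascending from 0; the last time is the
#'   period.
#' @param flow Flow samples, mL/s; must close periodically
#'   (`flow[1] == flow[n]` within tolerance).
#' @return A list of class `inflow_waveform`.
#' @export
prescribed_inflow <- function(time, flow) {
  stopifnot(length(time) == length(flow), length(time) >= 3)
  if (time[1] != 0 || any(diff(time) <= 0)) stop("time must ascend from 0")
  n <- length(flow)
  if (abs(flow[n] - flow[1]) > 1e-6 * max(abs(flow)) + 1e-9)
    stop("inflow waveform is not periodic: endpoints differ")
  structure(list(time = time, flow = flow, period = time[n]),
            class = "inflow_waveform")
}

#' Read a prescribed inflow from a two-column text table
#' @param path Path to a whitespace- or comma-separated table with columns
#'   time (s) and flow (mL/s).
#' @return An [prescribed_inflow()] object.
#' @export
read_inflow <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#")
  if (ncol(tab) == 1) tab <- utils::read.csv(path, header = FALSE)
  prescribed_inflow(tab[[1]], tab[[2]])
}
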