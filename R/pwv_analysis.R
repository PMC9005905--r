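#' Periodic pressure waveform
#'
#' Uniformly sampled pressure (or flow) samples covering one full cardiac
#' period.
#'
#' @param time Sample times, s (uniform spacing; the first sample is one
#'   step after the cycle origin).
#' @param pressure Samples, mmHg.
#' @param site Site name label.
#' @param period Cardiac period, s; defaults to `time` span plus one step.
#' @return A list of class `pressure_waveform` with fields `time`,
#'   `pressure`, `fs`, `period`, `site`.
#' @export
pressure_waveform <- function(time, pressure, site = "site", period = NULL) {
  stopifnot(length(time) == length(pressure), length(time) >= 8)
  dtv <- diff(time)
  if (max(abs(dtv - dtv[1])) > 1e-6 * dtv[1])
    stop("waveform must be uniformly sampled")
  fs <- 1 / dtv[1]
  if (is.null(period)) period <- time[length(time)] - time[1] + dtv[1]
  if (length(time) * dtv[1] < period - 1e-9)
    stop("waveform must cover at least one full period")
  structure(list(time = time, pressure = pressure, fs = fs,
                 period = period, site = site),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat("<pressure_waveform> '", x$site, "', ", length(x$time), " samples @ ",
      round(x$fs, 1), " Hz, period ", x$period, " s\n", sep = "")
  invisible(x)
}

#' Resample a waveform onto a uniform grid
#'
#' Interpolates (cubic spline, exact for band-limited physiological
#' pressure signals sampled well above their bandwidth) onto a uniform grid
#' at the requested rate over one period.
#'
#' @param waveform A [pressure_waveform()].
#' @param fs Target sampling frequency, Hz (default 900, an order of
#'   magnitude above the 100 Hz temporal-resolution floor for transit-time
#'   work).
#' @return A resampled [pressure_waveform()].
#' @export
resample_waveform <- function(waveform, fs = 900) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  t0 <- waveform$time[1] - 1 / waveform$fs
  tout <- seq(t0 + 1 / fs, t0 + waveform$period, by = 1 / fs)
  # wrap periodically so the spline has support beyond both ends
  tt <- c(waveform$time - waveform$period, waveform$time,
          waveform$time + waveform$period)
  pp <- rep(waveform$pressure, 3)
  y <- stats::spline(tt, pp, xout = tout)$y
  pressure_waveform(tout, y, site = waveform$site, period = waveform$period)
}

# Zero-phase low-pass smoothing of a periodic signal: the cycle is tiled
# three times, filtered forwards and backwards, and the middle copy kept,
# so that filter transients never touch the analysed cycle.
smooth_periodic <- function(p, fs, cutoff_hz = 25) {
  if (cutoff_hz >= fs / 2) return(p)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  n <- length(p)
  y <- signal::filtfilt(bf, rep(p, 3))
  y[(n + 1):(2 * n)]
}

#' Diastolic foot of a pressure wave (maximum second derivative)
#'
#' Locates the foot of the systolic upstroke as the time of the maximum of
#' the second time-derivative, searched between the end-diastolic minimum
#' and the systolic peak. The waveform is low-pass smoothed (zero-phase,
#' `cutoff_hz`) before double differencing, and the discrete maximum is
#' refined by parabolic interpolation of the second-derivative peak.
#'
#' @param waveform A [pressure_waveform()] covering one period.
#' @param cutoff_hz Smoothing cutoff, Hz.
#' @return Foot time, s (on the waveform's own time base).
#' @export
foot_time <- function(waveform, cutoff_hz = 25) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  p <- waveform$pressure
  n <- length(p)
  if (max(p) - min(p) < 1e-9) stop("flat waveform: no foot detectable")
  ps <- smooth_periodic(p, waveform$fs, cutoff_hz)
  # second derivative on the periodic extension
  d2 <- (c(ps[-1], ps[1]) - 2 * ps + c(ps[n], ps[-n])) * waveform$fs^2
  ipk <- which.max(ps)
  imin <- which.min(ps)
  # indices on the upstroke: from the minimum forward to the peak (cyclic)
  span <- (ipk - imin) %% n
  if (span == 0) span <- n
  idx <- ((imin - 1 + 0:span) %% n) + 1
  k <- idx[which.max(d2[idx])]
  # parabolic sub-sample refinement
  km <- if (k == 1) n else k - 1
  kp <- if (k == n) 1 else k + 1
  denom <- d2[km] - 2 * d2[k] + d2[kp]
  delta <- if (abs(denom) > 1e-12) 0.5 * (d2[km] - d2[kp]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  waveform$time[k] + delta / waveform$fs
}

#' Foot-to-foot pulse transit time
#'
#' Difference of the foot times of a distal and a proximal waveform sharing
#' the same cardiac period, wrapped into `(0, period)`.
#'
#' @param proximal,distal [pressure_waveform()]s with equal periods.
#' @param cutoff_hz Smoothing cutoff passed to [foot_time()].
#' @return Transit time, s. A zero transit time (identical feet) is
#'   returned as 0 with a warning.
#' @export
transit_time <- function(proximal, distal, cutoff_hz = 25) {
  if (abs(proximal$period - distal$period) > 1e-9)
    stop("waveforms have different cardiac periods")
  ptt <- (foot_time(distal, cutoff_hz) - foot_time(proximal, cutoff_hz)) %%
    proximal$period
  if (ptt == 0) warning("degenerate transit time of 0 s (identical feet)")
  # delays within half a sample of a full period are wrap-around zeros
  if (ptt > proximal$period - 0.5 / proximal$fs) ptt <- 0
  ptt
}

#' Pulse wave velocity from a path and a transit time
#'
#' @param path A [arterial_path()] measurement, or a travel distance in m.
#' @param ptt Pulse transit time, s (positive).
#' @param foot_times Optional numeric `c(proximal, distal)` foot times to
#'   carry in the measurement record.
#' @return A list of class `pwv_measurement` with `distance_m`, `ptt`,
#'   `pwv` (m/s) and the path (if supplied).
#' @export
compute_pwv <- function(path, ptt, foot_times = NULL) {
  if (!is.finite(ptt) || ptt <= 0)
    stop("non-positive transit time: foot detection likely failed")
  if (inherits(path, "path_measurement")) {
    dist_m <- path$distance_cm / 100
  } else {
    dist_m <- path; path <- NULL
  }
  structure(list(path = path, distance_m = dist_m, ptt = ptt,
                 pwv = dist_m / ptt, foot_times = foot_times),
            class = "pwv_measurement")
}

#' @export
print.pwv_measurement <- function(x, ...) {
  cat("<pwv> ", round(x$distance_m, 3), " m / ", round(x$ptt * 1000, 1),
      " ms = ", round(x$pwv, 2), " m/s\n", sep = "")
  invisible(x)
}

#' Measure PWV between two sites of a simulation result
#'
#' Convenience wrapper: extracts both site waveforms, measures the
#' foot-to-foot transit time and divides the anatomical path distance by it.
#'
#' @param result A [simulate()] result.
#' @param tree The simulated [arterial_tree] (for the path distance).
#' @param from,to Site names (proximal, distal).
#' @return A `pwv_measurement`.
#' @export
measure_pwv <- function(result, tree, from, to) {
  wp <- get_waveform(result, from)
  wd <- get_waveform(result, to)
  ft <- c(foot_time(wp), foot_time(wd))
  ptt <- (ft[2] - ft[1]) %% wp$period
  compute_pwv(arterial_path(tree, from, to), ptt, foot_times = ft)
}

#' Waveform pressure metrics
#'
#' Systolic pressure (cycle maximum), end-diastolic pressure (the cycle
#' minimum at the wave foot), early-diastolic pressure (first local minimum
#' after the systolic peak, in the incisura region), pulse pressure
#' (`SBP - end_DBP`) and the time-averaged mean pressure.
#'
#' @param waveform A [pressure_waveform()] covering one converged cycle.
#' @return A list of class `wave_metrics` with `SBP`, `early_DBP`,
#'   `end_DBP`, `PP`, `MAP` (all mmHg). `early_DBP` is `NA` (with a
#'   message) if no post-systolic local minimum exists.
#' @export
wave_metrics <- function(waveform) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  p <- waveform$pressure
  n <- length(p)
  sbp <- max(p); end_dbp <- min(p)
  ps <- if (sbp - end_dbp > 1e-9) smooth_periodic(p, waveform$fs, 25) else p
  ipk <- which.max(ps); imin <- which.min(ps)
  # walk from the peak towards the end-diastolic minimum; the first local
  # minimum strictly before it is the early-diastolic (post-incisura) value
  early <- NA_real_
  span <- (imin - ipk) %% n
  if (span > 2) {
    idx <- ((ipk - 1 + 1:(span - 1)) %% n) + 1
    seg <- ps[idx]
    loc <- which(diff(sign(diff(seg))) > 0) + 1
    if (length(loc)) early <- p[idx[loc[1]]]
  }
  if (is.na(early)) message("no incisura detected: early_DBP not available")
  structure(list(SBP = sbp, early_DBP = early, end_DBP = end_dbp,
                 PP = sbp - end_dbp, MAP = mean(p)),
            class = "wave_metrics")
}

#' @export
print.wave_metrics <- function(x, ...) {
  cat("SBP ", round(x$SBP, 1), "  early-DBP ", round(x$early_DBP, 1),
      "  end-DBP ", round(x$end_DBP, 1), "  PP ", round(x$PP, 1),
      "  MAP ", round(x$MAP, 1), " mmHg\n", sep = "")
  invisible(x)
}

#' Read a waveform from a two-column CSV (time s, pressure mmHg)
#' @param path CSV file path.
#' @param site Site label.
#' @return A [pressure_waveform()].
#' @export
read_waveform_csv <- function(path, site = basename(path)) {
  tab <- utils::read.csv(path)
  pressure_waveform(tab[[1]], tab[[2]], site = site)
}
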