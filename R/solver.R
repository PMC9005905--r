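# Grid construction and the user-facing simulate() wrapper around the
# compiled Lax-Wendroff core.

# Breadth-first segment ordering from the root; junction/terminal index
# tables; per-node reference areas and tube-law parameters (SI units).
build_grid <- function(tree, wall, dx_cm = 0.5, sites = names(tree$sites)) {
  validate_tree(tree)
  order_ids <- integer(0)
  queue <- tree$root_id
  while (length(queue)) {
    id <- queue[[1]]; queue <- queue[-1]
    order_ids <- c(order_ids, id)
    queue <- c(queue, tree$segments[[as.character(id)]]$child_ids)
  }
  nseg <- length(order_ids)
  seg_index <- stats::setNames(seq_len(nseg), as.character(order_ids)) # 1-based

  n_nodes <- integer(nseg); dx <- numeric(nseg)
  Aref <- Cref <- Pm <- Pw <- Pcap <- list()
  nonlinear <- wall$tube_law_kind == "pressure-dependent"
  for (k in seq_len(nseg)) {
    seg <- tree$segments[[as.character(order_ids[k])]]
    L <- seg$length_cm / 100
    ncell <- max(2L, as.integer(round(seg$length_cm / dx_cm)))
    n <- ncell + 1L
    n_nodes[k] <- n
    dx[k] <- L / ncell
    xfrac <- seq(0, 1, length.out = n)
    d_m <- (seg$diam_prox_mm + (seg$diam_dist_mm - seg$diam_prox_mm) * xfrac) / 1000
    A <- pi * d_m^2 / 4
    Aref[[k]] <- A
    Cref[[k]] <- A * seg$distensibility * DIST_UNIT_TO_PA
    pl <- seg$wall %||% list()
    Pm[[k]] <- rep(pa(pl$p_peak_mmhg %||% wall$pressure_law[["p_peak_mmhg"]]), n)
    Pw[[k]] <- rep(pa(pl$p_width_mmhg %||% wall$pressure_law[["p_width_mmhg"]]), n)
    Pcap[[k]] <- rep(pa(pl$p_cap_mmhg %||% 1e6), n)
  }
  offset <- c(0L, cumsum(n_nodes))[seq_len(nseg)]

  jparent <- integer(0); jchildren <- list()
  term_seg <- integer(0); tR1 <- tR2 <- tC <- tPout <- numeric(0)
  for (k in seq_len(nseg)) {
    seg <- tree$segments[[as.character(order_ids[k])]]
    if (length(seg$child_ids)) {
      jparent <- c(jparent, k - 1L)
      jchildren <- c(jchildren, list(as.integer(seg_index[as.character(seg$child_ids)] - 1L)))
    } else {
      wk <- seg$windkessel
      term_seg <- c(term_seg, k - 1L)
      tR1 <- c(tR1, wk$R1 * RWK_TO_SI); tR2 <- c(tR2, wk$R2 * RWK_TO_SI)
      tC <- c(tC, wk$C * CWK_TO_SI); tPout <- c(tPout, pa(wk$P_out))
    }
  }

  site_node <- integer(0)
  for (nm in sites) {
    st <- tree$sites[[nm]]
    if (is.null(st)) stop("unknown site '", nm, "'")
    k <- seg_index[[as.character(st$segment)]]
    seg <- tree$segments[[as.character(st$segment)]]
    node <- as.integer(round(st$pos_cm / seg$length_cm * (n_nodes[k] - 1L)))
    site_node <- c(site_node, offset[k] + node)
  }

  term_ids <- order_ids[term_seg + 1L]
  list(n_nodes = n_nodes, offset = as.integer(offset), dx = dx,
       Aref = unlist(Aref), Cref = unlist(Cref),
       Pm = unlist(Pm), Pw = unlist(Pw), Pcap = unlist(Pcap),
       Pref = pa(wall$p_ref_mmhg), nonlinear = nonlinear,
       junction_parent = as.integer(jparent), junction_children = jchildren,
       terminal_seg = as.integer(term_seg), terminal_ids = term_ids,
       term_R1 = tR1, term_R2 = tR2, term_C = tC, term_Pout = tPout,
       root_seg = 0L, site_node = as.integer(site_node), site_names = sites,
       order_ids = order_ids)
}

#' Simulate pulse propagation over an arterial tree
#'
#' Integrates the one-dimensional continuity and momentum equations over the
#' whole network with a two-step Lax-Wendroff scheme (time step capped by
#' the CFL stability limit), coupled to three-element Windkessel terminal
#' loads and driven at the root either by the time-varying elastance
#' ventricle or by a prescribed periodic inflow. Cycles are repeated until
#' the largest cycle-to-cycle pressure change at any extracted site falls
#' below `tol_mmhg` (or `n_cycles` is reached, with a warning). Site
#' waveforms of the final cycle are resampled to `fs_out`.
#'
#' @param tree A validated [arterial_tree].
#' @param heart [heart_params()] proximal boundary (ignored when `inflow`
#'   is given).
#' @param wall [wall_params()]; sets blood properties, the reference
#'   pressure, and the tube-law kind.
#' @param inflow Optional [prescribed_inflow()] replacing the heart model.
#' @param n_cycles Maximum number of cardiac cycles.
#' @param tol_mmhg Cycle-to-cycle convergence tolerance, mmHg.
#' @param dt Solver time step, s (reduced automatically if the stability
#'   limit requires it).
#' @param dx_cm Target spatial step, cm (at least 3 nodes per segment).
#' @param sites Site names to extract (default: all named sites).
#' @param fs_out Output sampling frequency, Hz.
#' @param zeta Velocity-profile exponent of the friction model,
#'   `k_f = 2*pi*(zeta + 2)`; the default 9 is a near-plug profile.
#' @param p_init_mmhg Initial uniform pressure, mmHg.
#' @return A list of class `simulation_result`: `sites` (named list of
#'   tibbles with `time`, `pressure` (mmHg), `flow` (mL/s) on the uniform
#'   `fs_out` grid over one period), `period`, `fs`, `converged`,
#'   `cycles_run`, `cycle_delta_mmhg`, `inflow_volume_ml`,
#'   `terminal_volumes_ml` (named by segment id), `stroke_volume_ml`,
#'   `cardiac_output_lmin` and the solver step actually used.
#' @export
simulate <- function(tree, heart = heart_params(), wall = wall_params(),
                     inflow = NULL, n_cycles = 12, tol_mmhg = 0.5,
                     dt = 1e-4, dx_cm = 0.5, sites = names(tree$sites),
                     fs_out = 900, zeta = 9, p_init_mmhg = 90) {
  stopifnot(inherits(tree, "arterial_tree"), n_cycles >= 2)
  grid <- build_grid(tree, wall, dx_cm = dx_cm, sites = sites)
  use_heart <- is.null(inflow)
  period <- if (use_heart) heart$period else inflow$period
  run <- list(rho = wall$rho_blood, mu = wall$mu_blood,
              kf = 2 * pi * (zeta + 2), period = period,
              n_cycles = as.integer(n_cycles), tol = pa(tol_mmhg),
              p_init = pa(p_init_mmhg), dt = dt, use_heart = use_heart)
  if (use_heart) {
    et <- seq(0, 1, length.out = 801)
    run$heart <- c(unclass(heart),
                   list(elast_t = et,
                        elast_e = normalized_elastance(et, heart$t_peak_frac)))
  } else {
    run$inflow_t <- inflow$time
    run$inflow_q <- inflow$flow * 1e-6
  }
  out <- pt_simulate_core(grid, run)
  if (!out$converged)
    warning("simulation did not converge within ", n_cycles,
            " cycles (last cycle-to-cycle change ",
            round(mmhg(min(out$cycle_delta[out$cycle_delta > 0], na.rm = TRUE)), 2),
            " mmHg)")

  t900 <- seq(1 / fs_out, period, by = 1 / fs_out)
  site_tabs <- list()
  for (i in seq_along(grid$site_names)) {
    p_mmhg <- mmhg(out$site_p[, i])
    q_mls <- out$site_q[, i] * 1e6
    site_tabs[[grid$site_names[i]]] <- tibble::tibble(
      time = t900,
      pressure = stats::spline(out$time, p_mmhg, xout = t900)$y,
      flow = stats::spline(out$time, q_mls, xout = t900)$y)
  }
  sv_ml <- out$inflow_volume * 1e6
  res <- list(sites = site_tabs, period = period, fs = fs_out,
              converged = out$converged, cycles_run = out$cycles_run,
              cycle_delta_mmhg = mmhg(out$cycle_delta[seq_len(out$cycles_run)]),
              inflow_volume_ml = sv_ml,
              terminal_volumes_ml = stats::setNames(out$terminal_volumes * 1e6,
                                                    as.character(grid$terminal_ids)),
              stroke_volume_ml = sv_ml,
              cardiac_output_lmin = sv_ml / period * 60 / 1000,
              dt = out$dt, solver_time = out$time,
              kidney_configuration = tree$meta$kidney_configuration %||% NA_character_)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$sites), " sites, period ", x$period,
      " s, ", if (x$converged) "converged" else "NOT converged",
      " after ", x$cycles_run, " cycles\n", sep = "")
  cat("stroke volume ", round(x$stroke_volume_ml, 1), " mL, cardiac output ",
      round(x$cardiac_output_lmin, 2), " L/min\n", sep = "")
  invisible(x)
}

#' Extract a site waveform from a simulation result
#'
#' @param result A [simulate()] result.
#' @param site Site name.
#' @param what `"pressure"` or `"flow"`.
#' @return A [pressure_waveform()] (pressure in mmHg or flow in mL/s).
#' @export
get_waveform <- function(result, site, what = c("pressure", "flow")) {
  what <- match.arg(what)
  tab <- result$sites[[site]]
  if (is.null(tab)) stop("no site '", site, "' in result")
  pressure_waveform(tab$time, tab[[what]], site = site, period = result$period)
}

#' One implicit-Euler update of a three-element Windkessel
#'
#' Advances the storage (peripheral) pressure of an RCR Windkessel by one
#' time step given the inflow, and reports the inlet pressure. This is the
#' same discrete update used at the terminal boundaries of [simulate()].
#'
#' @param p_wk Current storage pressure, mmHg.
#' @param q_in Inflow, mL/s.
#' @param outlet A [windkessel_outlet()].
#' @param dt Time step, s.
#' @return List with `p_wk` (advanced storage pressure, mmHg) and
#'   `p_inlet = p_wk + q_in * R1`.
#' @export
windkessel_update <- function(p_wk, q_in, outlet, dt) {
  denom <- 1 + dt / (outlet$R2 * outlet$C)
  p_new <- (p_wk + dt / outlet$C * (q_in + outlet$P_out / outlet$R2)) / denom
  list(p_wk = p_new, p_inlet = p_new + q_in * outlet$R1)
}

#' Export site waveforms as CSV tables
#'
#' Writes one `<site>.csv` per extracted site (columns `time` s, `pressure`
#' mmHg, `flow` mL/s) into a directory.
#'
#' @param result A [simulate()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_result_csv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(result$sites))
    utils::write.csv(result$sites[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
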