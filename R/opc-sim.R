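#' Jet-flow OPC chamber geometry
#'
#' Describes the apparatus: a 0.6 m diameter, 1.8 m long steel vessel split
#' by a partition into a pressurized Driver Section and a Test Section, with
#' a 14 cm venting aperture in the partition and the specimen station about
#' 12.7 cm downstream of the aperture plane.
#'
#' For the quasi-1D model the chamber is represented by an axial
#' cross-section profile: full bore in both sections, a cosine contraction
#' to the aperture area over `taper_upstream` (the converging sink-flow
#' region ahead of the orifice, about one aperture diameter), a collimated
#' jet-core segment of constant aperture area extending `core_length`
#' beyond the partition (a stream-tube surrogate for the collimated jet,
#' whose potential core spans several aperture diameters and comfortably
#' covers the specimen standoff), and a cosine expansion back to the bore
#' over `taper_downstream`. Driver and test volumes are integrals of this
#' same profile, so lumped and PDE equilibria refer to identical volumes.
#'
#' @param diameter Vessel bore, m.
#' @param total_length Vessel length, m.
#' @param driver_length Driver Section length, m. Not printed for the
#'   apparatus; the default is calibrated so that the two-volume
#'   equilibrium of a 138 kPa burst sits at the observed ~15 kPa
#'   quasi-static level.
#' @param aperture_diameter Venting aperture diameter, m.
#' @param specimen_standoff Specimen station distance from the aperture
#'   plane, m.
#' @param probe_stations Data frame with columns `x` (axial position, m)
#'   and `role` (one of "static", "stagnation", "driver"). Defaults to a
#'   driver gauge at mid-driver, static + stagnation at the specimen
#'   station, and a static gauge at the closed end wall.
#' @param taper_upstream,core_length,taper_downstream Stream-tube profile
#'   lengths, m (see Details).
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(diameter = 0.6, total_length = 1.8,
                             driver_length = 0.20,
                             aperture_diameter = 0.14,
                             specimen_standoff = 0.127,
                             probe_stations = NULL,
                             taper_upstream = 0.07,
                             core_length = 0.20,
                             taper_downstream = 0.10) {
  stopifnot(driver_length > 0, driver_length < total_length,
            aperture_diameter < diameter, specimen_standoff > 0,
            taper_upstream > 0, taper_upstream < driver_length,
            core_length > specimen_standoff,
            driver_length + core_length + taper_downstream < total_length)
  if (is.null(probe_stations)) {
    probe_stations <- data.frame(
      x = c(driver_length / 2,
            driver_length + specimen_standoff,
            driver_length + specimen_standoff,
            total_length),
      role = c("driver", "static", "stagnation", "static"),
      label = c("driver", "specimen_static", "specimen_stagnation",
                "end_wall"),
      stringsAsFactors = FALSE)
  }
  g <- structure(list(diameter = diameter, total_length = total_length,
                      driver_length = driver_length,
                      aperture_diameter = aperture_diameter,
                      specimen_standoff = specimen_standoff,
                      probe_stations = probe_stations,
                      taper_upstream = taper_upstream,
                      core_length = core_length,
                      taper_downstream = taper_downstream),
                 class = "chamber_geometry")
  g
}

#' Axial cross-section area profile of the chamber stream tube
#'
#' @param geom A [chamber_geometry()].
#' @param x Axial positions, m (0 = upstream end wall of the driver).
#' @return Cross-section areas, m^2.
#' @export
area_profile <- function(geom, x) {
  A_c <- pi / 4 * geom$diameter^2
  A_a <- pi / 4 * geom$aperture_diameter^2
  d <- geom$driver_length
  x1 <- d - geom$taper_upstream          # start of contraction
  x2 <- d + geom$core_length             # end of jet core
  x3 <- x2 + geom$taper_downstream       # end of expansion
  A <- rep(A_c, length(x))
  i <- x >= x1 & x < d
  A[i] <- A_a + (A_c - A_a) * 0.5 * (1 + cos(pi * (x[i] - x1) /
                                             (d - x1)))
  i <- x >= d & x <= x2
  A[i] <- A_a
  i <- x > x2 & x < x3
  A[i] <- A_a + (A_c - A_a) * 0.5 * (1 - cos(pi * (x[i] - x2) /
                                             (x3 - x2)))
  A
}

#' Driver and Test Section volumes of the stream tube
#'
#' @param geom A [chamber_geometry()].
#' @return List with `V_driver` and `V_test`, m^3.
#' @export
section_volumes <- function(geom) {
  V_d <- stats::integrate(function(x) area_profile(geom, x),
                          0, geom$driver_length,
                          subdivisions = 400L, rel.tol = 1e-10)$value
  V_t <- stats::integrate(function(x) area_profile(geom, x),
                          geom$driver_length, geom$total_length,
                          subdivisions = 400L, rel.tol = 1e-10)$value
  list(V_driver = V_d, V_test = V_t)
}

#' Diaphragm burst model
#'
#' @param burst_gauge_pressure Driver gauge pressure at rupture, Pa
#'   (default the nominal 138 kPa / 20 psi burst condition).
#' @param petal_duration Time for the Mylar membrane to petal fully open,
#'   s (default 0.3 ms; radial tears with flaps folding back).
#' @param bulge_radius Radius of the pressurized hemispherical bulge of
#'   the diaphragm, m (default the aperture radius).
#' @param opening_profile `"linear_ramp"` (area grows linearly over
#'   `petal_duration`) or `"instantaneous"`.
#' @param shock_fraction Probability that a given rupture is clean enough
#'   to launch a true shock front at the specimen (default 0.10).
#' @return An object of class `burst_model`.
#' @export
burst_model <- function(burst_gauge_pressure = 138e3,
                        petal_duration = 3e-4,
                        bulge_radius = 0.07,
                        opening_profile = c("linear_ramp", "instantaneous"),
                        shock_fraction = 0.10) {
  opening_profile <- match.arg(opening_profile)
  stopifnot(burst_gauge_pressure > 0, petal_duration >= 0,
            bulge_radius > 0,
            shock_fraction >= 0, shock_fraction <= 1)
  structure(list(burst_gauge_pressure = burst_gauge_pressure,
                 petal_duration = petal_duration,
                 bulge_radius = bulge_radius,
                 opening_profile = opening_profile,
                 shock_fraction = shock_fraction),
            class = "burst_model")
}

#' Lumped two-volume blowdown of the driver
#'
#' Orifice-discharge ODE between the Driver and Test Section volumes:
#' choked or subcritical isentropic mass flux through the aperture
#' (ramped open over the petal duration), with total-enthalpy transport.
#' Both volumes converge to the mass/energy-conserving equilibrium
#' absolute pressure (p_d V_d + p_t V_t) / (V_d + V_t).
#'
#' @param geom A [chamber_geometry()].
#' @param burst A [burst_model()].
#' @param t_end End time, s.
#' @param c A [gas_constants()] object.
#' @param discharge_coeff Orifice discharge coefficient (default 1).
#' @param dt Output sampling interval, s.
#' @return List with `trace` (driver [pressure_trace()], gauge Pa),
#'   `test_trace` (test-section pressure), `quasi_static` (equilibrium
#'   gauge level, Pa), `efold_time` (time for the driver overpressure
#'   above equilibrium to fall by 1/e, s).
#' @export
lumped_blowdown <- function(geom, burst, t_end = 0.06,
                            c = gas_constants(),
                            discharge_coeff = 1, dt = 1e-5) {
  stopifnot(t_end > 0)
  A_a <- pi / 4 * geom$aperture_diameter^2
  if (A_a * discharge_coeff <= 0)
    stop("degenerate aperture: zero effective area, no flow")
  vols <- section_volumes(geom)
  V_d <- vols$V_driver
  V_t <- vols$V_test
  g <- c$gamma
  cp <- g * c$R_air / (g - 1)
  cv <- c$R_air / (g - 1)
  p_d0 <- c$p_amb + burst$burst_gauge_pressure
  crit <- (2 / (g + 1))^(g / (g - 1))

  state0 <- c(m_d = p_d0 * V_d / (c$R_air * c$T_amb),
              E_d = p_d0 * V_d / (g - 1),
              m_t = c$p_amb * V_t / (c$R_air * c$T_amb),
              E_t = c$p_amb * V_t / (g - 1))

  deriv <- function(t, y, parms) {
    p_d <- (g - 1) * y[2] / V_d
    T_d <- y[2] / (cv * y[1])
    p_t <- (g - 1) * y[4] / V_t
    T_t <- y[4] / (cv * y[3])
    ramp <- if (burst$opening_profile == "instantaneous" ||
                burst$petal_duration == 0) 1
            else min(1, max(0, t / burst$petal_duration))
    A <- A_a * discharge_coeff * ramp
    if (p_d >= p_t) { p_up <- p_d; T_up <- T_d; sgn <- 1 }
    else            { p_up <- p_t; T_up <- T_t; sgn <- -1 }
    r <- min(p_d, p_t) / p_up
    mdot <- if (r <= crit) {
      A * p_up * sqrt(g / (c$R_air * T_up)) *
        (2 / (g + 1))^((g + 1) / (2 * (g - 1)))
    } else {
      A * p_up * sqrt(2 * g / ((g - 1) * c$R_air * T_up) *
                        (r^(2 / g) - r^((g + 1) / g)))
    }
    mdot <- sgn * mdot
    list(c(-mdot, -mdot * cp * T_up, mdot, mdot * cp * T_up))
  }

  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = state0, times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8)
  p_d <- (g - 1) * sol[, "E_d"] / V_d
  p_t <- (g - 1) * sol[, "E_t"] / V_t
  p_eq <- (p_d0 * V_d + c$p_amb * V_t) / (V_d + V_t)

  over <- p_d - p_eq
  i_e <- which(over <= over[1] / exp(1))[1]
  efold <- if (is.na(i_e)) NA_real_ else times[i_e]

  list(trace = pressure_trace(p_d - c$p_amb, sample_rate = 1 / dt,
                              t0 = 0, channel_id = "driver",
                              role = "driver"),
       test_trace = pressure_trace(p_t - c$p_amb, sample_rate = 1 / dt,
                                   t0 = 0, channel_id = "test_section",
                                   role = "static"),
       quasi_static = p_eq - c$p_amb,
       efold_time = efold)
}

#' Generic quasi-1D Euler finite-volume solve
#'
#' Low-level entry to the compiled HLLC / minmod-MUSCL / SSP-RK2 kernel on
#' an arbitrary axial area profile with reflective end walls. Used by
#' [solve_quasi1d()] and [solve_spherical_burst()]; also convenient for
#' shock-tube verification problems (uniform area reduces the scheme to
#' plain 1D Euler).
#'
#' @param x_face Face coordinates, length `n_cells + 1`, strictly
#'   increasing, m.
#' @param A_face Face areas, m^2 (same length).
#' @param init Function of cell-center position returning a list/data frame
#'   with `rho`, `u`, `p`, `s` (passive scalar), or a data frame with those
#'   columns of length `n_cells`.
#' @param t_end End time, s.
#' @param gamma Ratio of specific heats.
#' @param cfl CFL number in (0, 1].
#' @param diaphragm_face Face index (1-based, interior) acting as a ramped
#'   diaphragm, or `NA` for none.
#' @param petal_duration Diaphragm opening time, s (0 = instantaneous).
#' @param probe_cells Cell indices (1-based) whose state is recorded every
#'   step.
#' @param snap_dt Field snapshot interval, s.
#' @param track_x_from Axial position from which tracer arrival, minimum
#'   temperature and peak speed are tracked, m.
#' @param track_t_max Time horizon for the minimum-temperature search, s.
#' @param R_air Specific gas constant, J/(kg K).
#' @param loss_profile Per-cell quadratic loss coefficient, 1/m (length
#'   `n_cells`, or empty for none): a momentum sink
#'   -(1/2) f rho u |u| that leaves total energy untouched, converting
#'   kinetic energy to heat (sudden-enlargement / jet-mixing losses).
#'   Applied to forward (u > 0) flow; see `loss_profile_rev`.
#' @param loss_profile_rev Loss coefficient applied to reverse (u < 0)
#'   flow (default: same as `loss_profile`). Enlargement losses are
#'   directional - each side of a constriction dissipates when it is the
#'   one receiving the jet.
#' @return Raw solver output list (probe records, snapshots, conservation
#'   totals, tracer arrival times, extremes).
#' @export
solve_euler1d <- function(x_face, A_face, init, t_end,
                          gamma = 1.4, cfl = 0.5,
                          diaphragm_face = NA, petal_duration = 0,
                          probe_cells = integer(0), snap_dt = 1e-4,
                          track_x_from = -Inf, track_x_to = Inf,
                          track_t_max = Inf,
                          R_air = 287.05, loss_profile = numeric(0),
                          loss_profile_rev = loss_profile) {
  n <- length(x_face) - 1
  if (n < 2) stop("need at least 2 cells")
  if (any(diff(x_face) <= 0)) stop("x_face must be strictly increasing")
  xc <- 0.5 * (x_face[-1] + x_face[-(n + 1)])
  st <- if (is.function(init)) init(xc) else init
  st <- as.data.frame(st)
  stopifnot(nrow(st) == n, all(c("rho", "u", "p", "s") %in% names(st)))
  dia <- if (is.na(diaphragm_face)) -1L else as.integer(diaphragm_face) - 1L
  .euler1d_run(x_face, A_face, st$rho, st$u, st$p, st$s,
               gamma, t_end, cfl, dia, petal_duration,
               loss_profile, loss_profile_rev,
               as.integer(probe_cells) - 1L, snap_dt,
               track_x_from,
               if (is.finite(track_x_to)) track_x_to else 1e30,
               if (is.finite(track_t_max)) track_t_max else 1e30,
               R_air)
}

#' Simulate the OPC venting event (quasi-1D Euler)
#'
#' Finite-volume simulation of the diaphragm-burst venting flow on the
#' chamber stream tube: driver blowdown through the aperture, jet
#' development and decay, longitudinal reverberation of the test section
#' and equilibration to the quasi-static level. The diaphragm is a
#' time-ramped area restriction at the partition face (linear over the
#' petal duration). A passive scalar initialized to 1 in the driver gas
#' tracks the vented-gas contact surface.
#'
#' @param geom A [chamber_geometry()].
#' @param burst A [burst_model()].
#' @param t_end End time, s (default 60 ms: well past equilibration).
#' @param n_cells Number of cells (default 720, i.e. 2.5 mm).
#' @param cfl CFL number (default 0.5).
#' @param c A [gas_constants()] object.
#' @param snap_dt Field snapshot interval, s.
#' @param sample_rate Probe trace resampling rate, Hz (default 200 kHz;
#'   the solver step is ~2 microseconds so this loses nothing).
#' @param expansion_loss Sudden-enlargement (Borda-Carnot) loss
#'   coefficient applied across the downstream area expansion; default
#'   `(1 - A_aperture/A_chamber)^2` from the geometry. The loss enters
#'   as a quadratic momentum sink that turns jet kinetic energy into
#'   heat, standing in for the turbulent dissipation of the dumped jet
#'   that one-dimensional inviscid flow otherwise lacks.
#' @param dump_loss Bulk quadratic loss coefficient, 1/m, applied from
#'   the end of the expansion to the end wall (residual mixing of the
#'   dumped jet; quadratic in velocity, so the weak longitudinal
#'   reverberation wave is essentially untouched).
#' @param reverse_loss Quadratic loss coefficient, 1/m, applied to
#'   reverse (u < 0) flow along the constriction. The collimated core
#'   only exists for the forward jet; backflow converges from the bore
#'   into the orifice and dumps into the driver, dissipating there, so
#'   reverse flow through the neck is lossy. This damps the
#'   driver/test-section volume-exchange (Helmholtz) oscillation the
#'   same way the real separated orifice flow does.
#' @return An object of class `opc_field_history`: snapshot `times`,
#'   `x` cell centers, field matrices `rho`, `u`, `p`, `scalar`
#'   (cells x snapshots), `probes` (list of [pressure_trace()], gauge,
#'   with stagnation channels reduced via the Pitot forward relation),
#'   `probe_flow` (per-station data frames of rho, u, p, T), tracer
#'   `arrival` times per cell, conservation totals, extremes, and the
#'   geometry/burst used. The minimum-temperature and peak-speed
#'   extremes are tracked over the collimated jet column (aperture plane
#'   to the end of the core segment): the downstream expansion carries
#'   the artificial mixing loss and is not part of the resolved jet.
#' @export
solve_quasi1d <- function(geom, burst, t_end = 0.06, n_cells = 720,
                          cfl = 0.5, c = gas_constants(),
                          snap_dt = 2e-4, sample_rate = 2e5,
                          expansion_loss = NULL, dump_loss = 4,
                          reverse_loss = 5) {
  stopifnot(n_cells >= 100, cfl > 0, cfl <= 1)
  x_face <- seq(0, geom$total_length, length.out = n_cells + 1)
  A_face <- area_profile(geom, x_face)
  # diaphragm face: the face nearest the partition plane
  dia <- which.min(abs(x_face - geom$driver_length))
  if (dia == 1 || dia == n_cells + 1) stop("partition outside domain")
  petal <- if (burst$opening_profile == "instantaneous") 0
           else burst$petal_duration
  p_d <- c$p_amb + burst$burst_gauge_pressure
  xc <- 0.5 * (x_face[-1] + x_face[-(n_cells + 1)])
  driver <- xc < x_face[dia]
  init <- data.frame(
    rho = ifelse(driver, p_d, c$p_amb) / (c$R_air * c$T_amb),
    u = 0,
    p = ifelse(driver, p_d, c$p_amb),
    s = as.numeric(driver))

  stations <- geom$probe_stations
  probe_cells <- vapply(stations$x, function(x0)
    which.min(abs(xc - x0)), integer(1))

  A_c <- pi / 4 * geom$diameter^2
  A_a <- pi / 4 * geom$aperture_diameter^2
  if (is.null(expansion_loss)) expansion_loss <- (1 - A_a / A_c)^2
  x1 <- geom$driver_length - geom$taper_upstream
  x2 <- geom$driver_length + geom$core_length
  x3 <- x2 + geom$taper_downstream
  # forward flow dumps into the test section; reverse flow dumps into
  # the driver: the enlargement loss sits on the receiving side
  fric <- numeric(n_cells)
  fric[xc >= x2 & xc < x3] <- expansion_loss / geom$taper_downstream
  fric[xc >= x3] <- dump_loss
  # Reverse flow has no collimated channel: it converges from the bore
  # into the orifice and dumps into the driver, so the enlargement loss
  # is spread along the whole constriction for u < 0.
  fric_rev <- numeric(n_cells)
  fric_rev[xc >= x1 & xc < x3] <- reverse_loss
  fric_rev[xc >= x3] <- dump_loss

  out <- solve_euler1d(x_face, A_face, init, t_end,
                       gamma = c$gamma, cfl = cfl,
                       diaphragm_face = dia, petal_duration = petal,
                       probe_cells = probe_cells, snap_dt = snap_dt,
                       track_x_from = x_face[dia],
                       track_x_to = x2,
                       track_t_max = 0.010, R_air = c$R_air,
                       loss_profile = fric,
                       loss_profile_rev = fric_rev)

  # uniform resampling of the per-step probe records
  tt <- seq(0, t_end, by = 1 / sample_rate)
  probes <- vector("list", nrow(stations))
  probe_flow <- vector("list", nrow(stations))
  names(probes) <- names(probe_flow) <- stations$label
  for (k in seq_len(nrow(stations))) {
    p <- stats::approx(out$probe_times, out$probe_p[, k], tt)$y
    rho <- stats::approx(out$probe_times, out$probe_rho[, k], tt)$y
    u <- stats::approx(out$probe_times, out$probe_u[, k], tt)$y
    Tg <- p / (rho * c$R_air)
    probe_flow[[k]] <- data.frame(time = tt, rho = rho, u = u, p = p,
                                  T = Tg)
    role <- stations$role[k]
    val <- if (role == "stagnation") {
      pitot_pressure(p, rho, u, c) - c$p_amb
    } else {
      p - c$p_amb
    }
    probes[[k]] <- pressure_trace(val, sample_rate = sample_rate, t0 = 0,
                                  channel_id = stations$label[k],
                                  role = role)
  }

  structure(list(
    times = out$snap_times, x = out$x_center,
    rho = out$snap_rho, u = out$snap_u, p = out$snap_p,
    scalar = out$snap_s,
    probes = probes, probe_flow = probe_flow,
    arrival = out$arrival_time,
    mass = out$mass, energy = out$energy,
    cell_volume = out$cell_volume,
    min_T = out$min_T, min_T_time = out$min_T_time,
    min_T_x = out$min_T_x,
    max_speed = out$max_speed, max_speed_time = out$max_speed_time,
    max_speed_x = out$max_speed_x,
    n_steps = out$n_steps,
    geometry = geom, burst = burst, constants = c,
    aperture_x = x_face[dia]),
    class = "opc_field_history")
}

#' @export
print.opc_field_history <- function(x, ...) {
  cat("<opc_field_history>\n")
  cat(sprintf("  %d cells, %d snapshots, t = [0, %.1f ms], %d steps\n",
              length(x$x), length(x$times), 1e3 * max(x$times),
              as.integer(x$n_steps)))
  cat(sprintf("  probes: %s\n", paste(names(x$probes), collapse = ", ")))
  cat(sprintf("  min jet temperature %.1f degC at x = %.3f m, t = %.2f ms\n",
              x$min_T - 273.15, x$min_T_x, 1e3 * x$min_T_time))
  cat(sprintf("  peak jet speed %.0f m/s at x = %.3f m, t = %.2f ms\n",
              x$max_speed, x$max_speed_x, 1e3 * x$max_speed_time))
  invisible(x)
}

#' Spherically symmetric burst of the diaphragm bulge (precursor wavelet)
#'
#' 1D Euler solve in spherical symmetry (face areas proportional to r^2)
#' of a pressurized sphere of `bulge_radius` released into ambient air:
#' the surrogate for the weak, spherically expanding precursor shock
#' ("wavelet") produced at rupture by the pressurized volume within the
#' hemispherical bulge of the diaphragm.
#'
#' @param burst A [burst_model()].
#' @param r_target Range at which the overpressure trace is recorded, m
#'   (must exceed the bulge radius).
#' @param t_end End time, s.
#' @param c A [gas_constants()] object.
#' @param n_cells Number of radial cells.
#' @param r_max Outer domain radius, m (large enough that the outer-wall
#'   reflection cannot reach `r_target` within `t_end`).
#' @param sample_rate Trace resampling rate, Hz.
#' @return A [pressure_trace()] of static overpressure at `r_target`
#'   (gauge Pa), with attributes `peak` (Pa) and `positive_duration` (s).
#' @export
solve_spherical_burst <- function(burst, r_target, t_end = 1.5e-3,
                                  c = gas_constants(), n_cells = 1500,
                                  r_max = NULL, sample_rate = 8e5) {
  if (r_target <= burst$bulge_radius)
    stop("r_target lies inside the initial pressurized bulge")
  if (is.null(r_max))
    r_max <- r_target + 1.05 * (sound_speed(c$T_amb, c) * 2) * t_end
  r_face <- seq(1e-4, r_max, length.out = n_cells + 1)
  A_face <- r_face^2                    # solid-angle factor cancels
  p_in <- c$p_amb + burst$burst_gauge_pressure
  init <- function(rc) data.frame(
    rho = ifelse(rc <= burst$bulge_radius, p_in, c$p_amb) /
      (c$R_air * c$T_amb),
    u = 0,
    p = ifelse(rc <= burst$bulge_radius, p_in, c$p_amb),
    s = as.numeric(rc <= burst$bulge_radius))
  rc <- 0.5 * (r_face[-1] + r_face[-(n_cells + 1)])
  probe <- which.min(abs(rc - r_target))
  out <- solve_euler1d(r_face, A_face, init, t_end,
                       gamma = c$gamma, cfl = 0.5,
                       probe_cells = probe, snap_dt = t_end,
                       R_air = c$R_air)
  tt <- seq(0, t_end, by = 1 / sample_rate)
  p <- stats::approx(out$probe_times, out$probe_p[, 1], tt)$y - c$p_amb
  tr <- pressure_trace(p, sample_rate = sample_rate, t0 = 0,
                       channel_id = sprintf("r=%.3fm", r_target),
                       role = "static")
  ipk <- which.max(p)
  izero <- which(p[seq(ipk, length(p))] <= 0)[1]
  attr(tr, "peak") <- p[ipk]
  ionset <- which(p > 0.05 * p[ipk])[1]
  attr(tr, "positive_duration") <-
    if (is.na(izero) || is.na(ionset)) NA_real_
    else tt[ipk + izero - 1] - tt[ionset]
  tr
}

#' Mean speed of the vented-gas front across an axial window
#'
#' The contact surface between driver and test gas is tracked by the
#' advected passive scalar (threshold 0.5). The front speed is the window
#' width divided by the difference of first-arrival times at its ends.
#'
#' @param h An `opc_field_history` from [solve_quasi1d()].
#' @param window Numeric length-2: axial positions (m) of the window ends;
#'   default aperture plane to specimen station.
#' @return Mean front speed, m/s.
#' @export
jet_front_speed <- function(h, window = NULL) {
  if (is.null(window))
    window <- c(h$aperture_x,
                h$geometry$driver_length + h$geometry$specimen_standoff)
  stopifnot(length(window) == 2, window[2] > window[1])
  if (window[1] < h$aperture_x - 1e-9)
    stop("window must lie downstream of the aperture")
  t_at <- function(x0) {
    ok <- !is.na(h$arrival) & h$x >= h$aperture_x
    if (!any(ok & h$x >= x0))
      stop("vented-gas front never reached x = ", x0, " m")
    stats::approx(h$x[ok], h$arrival[ok], x0, rule = 2)$y
  }
  t1 <- t_at(window[1])
  t2 <- t_at(window[2])
  if (t2 <= t1) stop("front arrival times are not ordered across window")
  (window[2] - window[1]) / (t2 - t1)
}
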