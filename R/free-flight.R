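#' Specification of a free-flight test sphere
#'
#' The demonstration object is a 40 mm ball ballasted to 1.1 g/cm^3,
#' sized to match the flow Reynolds number of a small-rodent-scale target.
#'
#' @param diameter Sphere diameter, m.
#' @param density Ballasted density, kg/m^3.
#' @param drag_coefficient Dimensionless drag coefficient (default 0.5,
#'   subcritical sphere).
#' @return An object of class `sphere_spec` with derived `mass` (kg) and
#'   frontal `area` (m^2).
#' @export
sphere_spec <- function(diameter = 0.040, density = 1100,
                        drag_coefficient = 0.5) {
  stopifnot(diameter > 0, density > 0, drag_coefficient > 0)
  structure(list(diameter = diameter, density = density,
                 drag_coefficient = drag_coefficient,
                 mass = sphere_mass(diameter, density),
                 area = pi / 4 * diameter^2),
            class = "sphere_spec")
}

#' Mass of a uniform sphere
#'
#' @param diameter Diameter, m.
#' @param density Density, kg/m^3.
#' @return Mass (pi/6) d^3 rho, kg.
#' @examples
#' sphere_mass(0.040, 1100) # ~0.0369 kg
#' @export
sphere_mass <- function(diameter, density) {
  stopifnot(diameter > 0, density > 0)
  pi / 6 * diameter^3 * density
}

#' Time-stamped displacement record of a free-flight object
#'
#' @param times Sample times, s (strictly increasing).
#' @param positions Displacement along the jet axis, m.
#' @param frame_rate Nominal acquisition frame rate, Hz (default the
#'   median sampling rate of `times`).
#' @return An object of class `track_record`.
#' @export
track_record <- function(times, positions, frame_rate = NULL) {
  stopifnot(length(times) == length(positions))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(times))
  structure(list(times = times, positions = positions,
                 frame_rate = frame_rate),
            class = "track_record")
}

#' Forward-simulate free-flight sphere motion under jet loading
#'
#' Point-mass drag law m dv/dt = (1/2) rho Cd A |u - v| (u - v) driven by
#' the local flow history (density, velocity) at the sphere location,
#' integrated with an adaptive explicit Runge-Kutta scheme. Drag can only
#' relax the sphere velocity toward the local flow velocity, so quiescent
#' flow leaves the sphere motionless.
#'
#' @param s A [sphere_spec()].
#' @param flow Data frame with columns `time` (s), `rho` (kg/m^3) and `u`
#'   (m/s): the flow history at the sphere location, sampled at least
#'   every 0.1 ms.
#' @param t_end End time, s (default end of the flow history).
#' @return A [track_record()] sampled on the flow history's time base,
#'   with attributes `velocity` (integrator velocity samples, m/s) and
#'   `force` (instantaneous drag force, N) for momentum bookkeeping.
#' @export
simulate_sphere <- function(s, flow, t_end = max(flow$time)) {
  stopifnot(inherits(s, "sphere_spec"),
            all(c("time", "rho", "u") %in% names(flow)))
  if (max(diff(flow$time)) > 1e-4 + 1e-12)
    stop("flow history must be sampled at least every 0.1 ms")
  rho_f <- stats::approxfun(flow$time, flow$rho, rule = 2)
  u_f <- stats::approxfun(flow$time, flow$u, rule = 2)
  k <- 0.5 * s$drag_coefficient * s$area / s$mass
  deriv <- function(t, y, parms) {
    rel <- u_f(t) - y[2]
    list(c(y[2], k * rho_f(t) * abs(rel) * rel))
  }
  times <- flow$time[flow$time <= t_end + 1e-12]
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(y = c(x = 0, v = 0), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  v <- sol[, "v"]
  tr <- track_record(sol[, "time"], sol[, "x"])
  attr(tr, "velocity") <- v
  attr(tr, "force") <- s$mass * k * rho_f(sol[, "time"]) *
    abs(u_f(sol[, "time"]) - v) * (u_f(sol[, "time"]) - v)
  tr
}

#' Kinematic analysis of a free-flight track
#'
#' Velocity by central finite differences (second-order one-sided at the
#' ends, so uniformly accelerated tracks are differentiated exactly);
#' velocity change, imparted impulse (mass x delta v), mean acceleration
#' over the loading interval (motion onset to final velocity), and
#' displacement over the first millisecond. When the track carries
#' measurement noise (detected as residual scatter about a quadratic
#' fit), the endpoint velocities entering `delta_v` come from quadratic
#' fits over the first/last third of the samples, since raw finite
#' differences amplify camera pixel noise.
#'
#' @param t A [track_record()] (at least 3 samples).
#' @param s A [sphere_spec()].
#' @param onset_frac Fraction of |delta v| used to detect motion onset.
#' @return List with `delta_v` (m/s), `impulse` (N s), `mean_accel`
#'   (m/s^2), `peak_accel` (m/s^2), `early_displacement` (m over the
#'   first 1 ms) and the `velocity` series.
#' @export
analyze_track <- function(t, s, onset_frac = 0.02) {
  stopifnot(inherits(t, "track_record"), inherits(s, "sphere_spec"))
  n <- length(t$times)
  if (n < 3) stop("need at least 3 track samples")
  tt <- t$times
  x <- t$positions
  v <- numeric(n)
  # second-order finite differences (nonuniform-safe via local quadratics)
  for (i in seq_len(n)) {
    j <- if (i == 1) 1:3 else if (i == n) (n - 2):n else (i - 1):(i + 1)
    h1 <- tt[j[2]] - tt[j[1]]
    h2 <- tt[j[3]] - tt[j[2]]
    # derivative of the interpolating quadratic at tt[i]
    d <- tt[i]
    l1 <- ((d - tt[j[2]]) + (d - tt[j[3]])) /
      ((tt[j[1]] - tt[j[2]]) * (tt[j[1]] - tt[j[3]]))
    l2 <- ((d - tt[j[1]]) + (d - tt[j[3]])) /
      ((tt[j[2]] - tt[j[1]]) * (tt[j[2]] - tt[j[3]]))
    l3 <- ((d - tt[j[1]]) + (d - tt[j[2]])) /
      ((tt[j[3]] - tt[j[1]]) * (tt[j[3]] - tt[j[2]]))
    v[i] <- x[j[1]] * l1 + x[j[2]] * l2 + x[j[3]] * l3
  }
  # endpoint velocities: finite differences are exact for smooth
  # (noise-free) motion but amplify camera pixel noise, so when the
  # track carries measurement noise the endpoint slopes come from a
  # cross-validated smoothing spline instead
  v1 <- v[1]
  vn <- v[n]
  if (n >= 10 && diff(range(x)) > 0) {
    sp <- stats::smooth.spline(tt, x)
    noisy <- stats::sd(x - stats::predict(sp, tt)$y) >
      1e-4 * diff(range(x))
    if (noisy) {
      end_slope <- function(idx, at) {
        f <- stats::lm(x[idx] ~ stats::poly(tt[idx], 2, raw = TRUE))
        co <- stats::coef(f)
        unname(co[2] + 2 * co[3] * at)
      }
      K <- max(10L, n %/% 3)
      v1 <- end_slope(seq_len(K), tt[1])
      vn <- end_slope(seq(n - K + 1L, n), tt[n])
    }
  }
  delta_v <- vn - v1
  impulse <- s$mass * delta_v
  a <- c(diff(v) / diff(tt), NA)
  if (abs(delta_v) > 0) {
    onset <- which(abs(v - v1) > onset_frac * abs(delta_v))[1]
    if (is.na(onset)) onset <- 1L
    dt_load <- tt[n] - tt[onset]
    mean_accel <- if (dt_load > 0) delta_v / dt_load else 0
  } else {
    mean_accel <- 0
  }
  t1 <- tt[1] + 1e-3
  early <- if (max(tt) >= t1)
    abs(stats::approx(tt, x, t1)$y - x[1]) else NA_real_
  list(delta_v = delta_v, impulse = impulse, mean_accel = mean_accel,
       peak_accel = max(abs(a), na.rm = TRUE),
       early_displacement = early, velocity = v)
}
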