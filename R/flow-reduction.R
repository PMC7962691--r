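#' Dynamic pressure from a stagnation/static pair (Bernoulli partition)
#'
#' Low-Mach partition of the total pressure: the stagnation pressure is the
#' sum of static and dynamic pressure, so q = p_stag - p_static.
#'
#' @param p_stag Stagnation (total) pressure, Pa. Vectorized.
#' @param p_static Static pressure, Pa (same length or length 1).
#' @return Dynamic pressure, Pa.
#' @export
dynamic_pressure_bernoulli <- function(p_stag, p_static) {
  if (any(p_stag < p_static))
    stop("stagnation channel reads below static channel: ",
         "check channel assignment (p_stag < p_static)")
  p_stag - p_static
}

#' Isentropic / Rayleigh-Pitot pressure ratio at a given Mach number
#'
#' Forward relation p_stag / p_static measured by a Pitot probe in a flow
#' of Mach `M`: the isentropic total-pressure ratio for M <= 1, and the
#' Rayleigh-Pitot formula (stagnation behind the probe's detached normal
#' shock over upstream static) for M > 1. The two branches agree at M = 1.
#'
#' @param M Mach number (>= 0). Vectorized.
#' @param gamma Ratio of specific heats.
#' @param branch `"auto"` selects by Mach number; `"subsonic"` or
#'   `"supersonic"` force one closed form (the two agree at M = 1).
#' @return Pressure ratio (>= 1).
#' @export
pitot_ratio <- function(M, gamma = 1.4,
                        branch = c("auto", "subsonic", "supersonic")) {
  branch <- match.arg(branch)
  if (any(M < 0)) stop("Mach number must be non-negative")
  g <- gamma
  sub <- (1 + (g - 1) / 2 * M^2)^(g / (g - 1))
  sup <- ((g + 1)^2 * M^2 / (4 * g * M^2 - 2 * (g - 1)))^(g / (g - 1)) *
    ((1 - g + 2 * g * M^2) / (g + 1))
  switch(branch,
         auto = ifelse(M <= 1, sub, sup),
         subsonic = sub,
         supersonic = sup)
}

#' Stagnation pressure recorded by a Pitot port in a known flow state
#'
#' @param p Static pressure, Pa.
#' @param rho Density, kg/m^3.
#' @param u Flow velocity, m/s.
#' @param c A [gas_constants()] object.
#' @return Absolute stagnation pressure, Pa. Vectorized.
#' @export
pitot_pressure <- function(p, rho, u, c = gas_constants()) {
  M <- abs(u) / sqrt(c$gamma * p / rho)
  p * pitot_ratio(M, c$gamma)
}

#' Mach number and flow state from a Pitot-static pressure pair
#'
#' Inverts the subsonic isentropic total-pressure ratio
#' p_stag/p_static = (1 + ((gamma-1)/2) M^2)^(gamma/(gamma-1));
#' if the implied Mach number exceeds 1 the Rayleigh-Pitot
#' (normal-shock-corrected) formula is inverted instead and the point is
#' flagged supersonic. Velocity is recovered from the total temperature
#' `T_ref` via the adiabatic relation T = T_ref / (1 + ((gamma-1)/2) M^2).
#'
#' @param p_stag Absolute stagnation pressure, Pa.
#' @param p_static Absolute static pressure, Pa (> 0).
#' @param c A [gas_constants()] object.
#' @param T_ref Total temperature, K (default ambient; the chamber gas
#'   starts at rest at ambient so total temperature is conserved along
#'   the jet in the adiabatic approximation).
#' @return An object of class `flow_point`: list with `p_static`,
#'   `p_stag`, `T_ref`, `mach`, `velocity`, `q_dyn` (true compressible
#'   dynamic pressure (gamma/2) p M^2), and `regime`
#'   ("incompressible" M < 0.3, "subsonic", or "supersonic" M > 1).
#' @examples
#' mach_from_pitot(1.8929 * 101325, 101325)$mach # ~1
#' @export
mach_from_pitot <- function(p_stag, p_static, c = gas_constants(),
                            T_ref = c$T_amb) {
  if (p_static <= 0) stop("static pressure must be positive")
  if (p_stag < p_static)
    stop("stagnation channel reads below static channel: ",
         "check channel assignment (p_stag < p_static)")
  g <- c$gamma
  ratio <- p_stag / p_static
  M <- sqrt(2 / (g - 1) * (ratio^((g - 1) / g) - 1))
  if (M > 1) {
    f <- function(m) pitot_ratio(m, g) - ratio
    sol <- tryCatch(
      stats::uniroot(f, c(1, 50), tol = 1e-13, maxiter = 200L),
      error = function(e)
        stop("Rayleigh-Pitot inversion failed for ratio ", ratio,
             ": ", conditionMessage(e)))
    if (abs(sol$f.root) > 1e-6 * ratio)
      stop("Rayleigh-Pitot inversion did not converge: residual ",
           sol$f.root)
    M <- sol$root
  }
  T_static <- T_ref / (1 + (g - 1) / 2 * M^2)
  vel <- M * sound_speed(T_static, c)
  regime <- if (M > 1) "supersonic" else if (M < 0.3) "incompressible"
            else "subsonic"
  structure(list(p_static = p_static, p_stag = p_stag, T_ref = T_ref,
                 mach = M, velocity = vel,
                 q_dyn = g / 2 * p_static * M^2,
                 regime = regime),
            class = "flow_point")
}

#' Reduce a stagnation/static trace pair to flow conditions
#'
#' Per-sample Pitot-static reduction of two simultaneously recorded gauge
#' traces. Samples where the stagnation channel reads below the static
#' channel (sensor noise; negative dynamic pressure is unphysical) are
#' clamped to q = 0 and flagged, never dropped.
#'
#' @param stag,stat [pressure_trace()] objects (gauge Pa) with equal
#'   sampling rates and overlapping time windows.
#' @param c A [gas_constants()] object.
#' @param T_ref Total temperature for velocity recovery, K.
#' @return Data frame with columns `time`, `p_static`, `p_stag` (absolute
#'   Pa), `q_bernoulli` (simple difference), `mach`, `velocity`, `q_dyn`,
#'   `regime`, `clamped`.
#' @export
reduce_trace_pair <- function(stag, stat, c = gas_constants(),
                              T_ref = c$T_amb) {
  stopifnot(inherits(stag, "pressure_trace"),
            inherits(stat, "pressure_trace"))
  if (abs(stag$sample_rate - stat$sample_rate) >
      1e-9 * stag$sample_rate)
    stop("mismatched sampling rates: ", stag$sample_rate, " vs ",
         stat$sample_rate)
  t1 <- trace_times(stag)
  t2 <- trace_times(stat)
  lo <- max(min(t1), min(t2))
  hi <- min(max(t1), max(t2))
  if (hi <= lo) stop("trace time windows do not overlap")
  i1 <- which(t1 >= lo - 1e-12 & t1 <= hi + 1e-12)
  # align the static channel on the stagnation channel's sample times
  ps <- stag$samples[i1] + c$p_amb
  pt <- stats::approx(t2, stat$samples, t1[i1])$y + c$p_amb
  n <- length(i1)
  mach <- velocity <- qd <- numeric(n)
  regime <- character(n)
  clamped <- ps < pt
  g <- c$gamma
  sub <- !clamped
  ratio <- pmax(ps[sub] / pt[sub], 1)
  Msub <- sqrt(2 / (g - 1) * (ratio^((g - 1) / g) - 1))
  mach[sub] <- Msub
  sup <- sub
  sup[sub] <- Msub > 1
  if (any(sup)) {
    mach[sup] <- vapply(which(sup), function(i)
      mach_from_pitot(ps[i], pt[i], c, T_ref)$mach, numeric(1))
  }
  mach[clamped] <- 0
  Tst <- T_ref / (1 + (g - 1) / 2 * mach^2)
  velocity <- mach * sound_speed(Tst, c)
  qd <- g / 2 * pt * mach^2
  qd[clamped] <- 0
  regime <- ifelse(mach > 1, "supersonic",
                   ifelse(mach < 0.3, "incompressible", "subsonic"))
  data.frame(time = t1[i1],
             p_static = pt,
             p_stag = ps,
             q_bernoulli = pmax(ps - pt, 0),
             mach = mach, velocity = velocity, q_dyn = qd,
             regime = regime, clamped = clamped)
}
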