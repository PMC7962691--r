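#' Gas constants for the working fluid
#'
#' Bundles the thermodynamic constants used throughout the package: ratio of
#' specific heats, specific gas constant of air, ambient reference state and
#' the specific energy of TNT used for explosive-equivalence estimates.
#'
#' @param gamma Ratio of specific heats (dimensionless, > 1).
#' @param R_air Specific gas constant of air, J/(kg K).
#' @param p_amb Ambient absolute pressure, Pa.
#' @param T_amb Ambient temperature, K.
#' @param e_TNT TNT specific energy, J/kg.
#'
#' @return An object of class `gas_constants`.
#' @examples
#' gc <- gas_constants()
#' sound_speed(gc$T_amb, gc)
#' @export
gas_constants <- function(gamma = 1.4, R_air = 287.05,
                          p_amb = 101325, T_amb = 293.15,
                          e_TNT = 4.184e6) {
  stopifnot(gamma > 1, R_air > 0, p_amb > 0, T_amb > 0, e_TNT > 0)
  structure(list(gamma = gamma, R_air = R_air, p_amb = p_amb,
                 T_amb = T_amb, e_TNT = e_TNT),
            class = "gas_constants")
}

#' Local thermodynamic and kinematic state of air
#'
#' A `gas_state` records absolute static pressure, density, temperature and
#' flow velocity at a point. Any two of (p, rho, T) determine the third via
#' the ideal-gas closure p = rho R T; the constructor fills in the missing
#' one and checks consistency when all three are supplied.
#'
#' @param p Absolute static pressure, Pa.
#' @param rho Density, kg/m^3 (optional if `T` given).
#' @param T Temperature, K (optional if `rho` given).
#' @param u Flow velocity, m/s.
#' @param c A [gas_constants()] object.
#'
#' @return An object of class `gas_state` with fields `p`, `rho`, `T`, `u`.
#' @export
gas_state <- function(p, rho = NULL, T = NULL, u = 0, c = gas_constants()) {
  if (any(p <= 0)) stop("static pressure must be positive")
  if (is.null(rho) && is.null(T))
    stop("supply at least one of `rho`, `T`")
  if (is.null(rho)) rho <- p / (c$R_air * T)
  if (is.null(T)) T <- p / (c$R_air * rho)
  if (any(rho <= 0) || any(T <= 0))
    stop("density and temperature must be positive")
  rel <- abs(p - rho * c$R_air * T) / p
  if (any(rel > 1e-9))
    stop("ideal-gas closure p = rho R T violated (relative error ",
         format(max(rel)), ")")
  structure(list(p = p, rho = rho, T = T, u = u), class = "gas_state")
}

#' Speed of sound in a perfect gas
#'
#' @param T Temperature, K.
#' @param c A [gas_constants()] object.
#' @return Sound speed sqrt(gamma R T), m/s.
#' @examples
#' sound_speed(293.15) # ~343 m/s
#' @export
sound_speed <- function(T, c = gas_constants()) {
  if (any(T <= 0)) stop("temperature must be positive")
  sqrt(c$gamma * c$R_air * T)
}

#' Peak dynamic pressure behind a blast front
#'
#' Partition of blast energy between static ("crushing") and dynamic
#' ("blast wind") pressure. For an ideal gas with gamma = 1.4 the
#' Rankine-Hugoniot jump conditions give, for a front of peak static
#' overpressure dp_s over ambient p_amb,
#'
#'   q = (5/2) dp_s^2 / (7 p_amb + dp_s).
#'
#' Weak blasts carry negligible dynamic pressure; near 480 kPa static
#' overpressure the two components become about equal.
#'
#' @param dp_s Peak static overpressure (gauge), Pa. Vectorized.
#' @param c A [gas_constants()] object (only `p_amb` is used; the closed
#'   form assumes gamma = 1.4).
#' @return Peak dynamic pressure, Pa.
#' @examples
#' peak_dynamic_pressure(103e3) / 1e3 # ~33 kPa
#' @export
peak_dynamic_pressure <- function(dp_s, c = gas_constants()) {
  if (any(dp_s < 0)) stop("overpressure must be non-negative")
  (5 / 2) * dp_s^2 / (7 * c$p_amb + dp_s)
}

#' Friedlander blast waveform
#'
#' Canonical free-field blast profile: instantaneous rise to `dp_peak`,
#' decay through zero at `t_pos`, and (for `b > 0`) an under-pressure phase
#' returning toward ambient:
#'
#'   p(t) = dp_peak (1 - t/t_pos) exp(-b t / t_pos).
#'
#' @param dp_peak Peak static overpressure, Pa.
#' @param t_pos Positive-phase duration, s.
#' @param b Dimensionless decay shape parameter (>= 0; 0 gives a triangle).
#' @return An object of class `friedlander_wave`.
#' @export
friedlander_wave <- function(dp_peak, t_pos, b = 1) {
  stopifnot(dp_peak > 0, t_pos > 0, b >= 0)
  structure(list(dp_peak = dp_peak, t_pos = t_pos, b = b),
            class = "friedlander_wave")
}

#' Evaluate a Friedlander waveform
#'
#' @param t Time after shock arrival, s (>= 0). Vectorized.
#' @param w A [friedlander_wave()].
#' @return Overpressure at `t`, Pa.
#' @export
friedlander_pressure <- function(t, w) {
  if (any(t < 0)) stop("time must be non-negative")
  w$dp_peak * (1 - t / w$t_pos) * exp(-w$b * t / w$t_pos)
}

#' Positive-phase impulse of a Friedlander waveform
#'
#' Closed-form integral of the overpressure over the positive phase,
#' int_0^{t_pos} p dt = dp_peak t_pos (1/b - (1 - e^{-b})/b^2) for b > 0,
#' reducing to the triangle area dp_peak t_pos / 2 at b = 0.
#'
#' @param w A [friedlander_wave()].
#' @return Impulse, Pa s.
#' @export
friedlander_impulse <- function(w) {
  if (w$b == 0) return(w$dp_peak * w$t_pos / 2)
  w$dp_peak * w$t_pos * (1 / w$b - (1 - exp(-w$b)) / w$b^2)
}

#' Shock Mach number from peak static overpressure
#'
#' Rankine-Hugoniot relation for the propagation Mach number of a normal
#' shock into still ambient air:
#'   Ms = sqrt(1 + ((gamma+1)/(2 gamma)) dp_s / p_amb).
#'
#' @param dp_s Peak static overpressure, Pa (>= 0). Vectorized.
#' @param c A [gas_constants()] object.
#' @return Shock Mach number (>= 1; equals 1 in the acoustic limit).
#' @export
shock_mach_from_overpressure <- function(dp_s, c = gas_constants()) {
  if (any(dp_s < 0)) stop("overpressure must be non-negative")
  sqrt(1 + ((c$gamma + 1) / (2 * c$gamma)) * dp_s / c$p_amb)
}

#' Post-shock state from the shock Mach number
#'
#' Full Rankine-Hugoniot jump conditions for a normal shock of Mach `Ms`
#' propagating into still ambient gas: post-shock pressure, density,
#' temperature and particle velocity (lab frame).
#'
#' @param Ms Shock Mach number (>= 1).
#' @param c A [gas_constants()] object.
#' @return A [gas_state()] of the shocked gas.
#' @export
post_shock_state <- function(Ms, c = gas_constants()) {
  stopifnot(Ms >= 1)
  g <- c$gamma
  p1 <- c$p_amb
  T1 <- c$T_amb
  rho1 <- p1 / (c$R_air * T1)
  p2 <- p1 * (1 + 2 * g / (g + 1) * (Ms^2 - 1))
  rho2 <- rho1 * ((g + 1) * Ms^2) / ((g - 1) * Ms^2 + 2)
  a1 <- sound_speed(T1, c)
  u2 <- (2 * a1 / (g + 1)) * (Ms - 1 / Ms)
  gas_state(p = p2, rho = rho2, u = u2, c = c)
}

#' Temperature change under isentropic pressure change
#'
#' T2 = T1 (p2/p1)^((gamma-1)/gamma). Used for the strong cooling of the
#' vented driver gas as it expands into the test section (the jet core
#' reaches about -60 degC under partial-vacuum excursions).
#'
#' @param p2 Final absolute pressure, Pa.
#' @param p1 Initial absolute pressure, Pa.
#' @param T1 Initial temperature, K.
#' @param c A [gas_constants()] object.
#' @return Final temperature, K.
#' @examples
#' isentropic_temperature(101.325e3, 239.325e3, 293) # ~229 K
#' @export
isentropic_temperature <- function(p2, p1, T1, c = gas_constants()) {
  if (any(p1 <= 0) || any(p2 <= 0) || any(T1 <= 0))
    stop("pressures and temperature must be positive")
  T1 * (p2 / p1)^((c$gamma - 1) / c$gamma)
}

#' TNT-equivalent mass of a pressurized volume
#'
#' Ideal explosive equivalence of the stored compression energy of a gas
#' volume: E = dp V / (gamma - 1), converted to mass by the TNT specific
#' energy. Compressed-gas bursts under-perform ideal point-source
#' equivalence, so a dimensionless `yield_factor` (default 1, i.e. the
#' ideal upper estimate) is exposed.
#'
#' @param dp_gauge Gauge pressure of the stored gas, Pa (>= 0).
#' @param V Volume, m^3.
#' @param c A [gas_constants()] object.
#' @param yield_factor Dimensionless efficiency in (0, 1].
#' @return Equivalent explosive mass, kg.
#' @examples
#' # hemispherical diaphragm bulge of 7 cm radius at 138 kPa gauge
#' tnt_equivalent_mass(138e3, 2 / 3 * pi * 0.07^3) * 1e6 # ~59 mg
#' @export
tnt_equivalent_mass <- function(dp_gauge, V, c = gas_constants(),
                                yield_factor = 1) {
  if (any(dp_gauge < 0)) stop("gauge pressure must be non-negative")
  stopifnot(V > 0, yield_factor > 0)
  yield_factor * dp_gauge * V / ((c$gamma - 1) * c$e_TNT)
}

#' Convert between psi and kPa
#'
#' The apparatus literature mixes units (20 psi vs 138 kPa); the conversion
#' is fixed at 6.894757 kPa per psi.
#'
#' @param x Pressure value(s).
#' @return Converted value(s).
#' @rdname unit-conversion
#' @export
psi_to_kpa <- function(x) x * 6.894757

#' @rdname unit-conversion
#' @export
kpa_to_psi <- function(x) x / 6.894757
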