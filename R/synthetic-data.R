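#' Specification of a synthetic OPC sensor record
#'
#' Parameterizes the temporal structure of the apparatus's sensor suite:
#' an on-axis stagnation trace with a ~0.2 ms precursor wavelet followed
#' by an ~18 ms jet decay carrying ~1.3 kHz ripple, a static trace
#' fluctuating below 20 kPa with partial-vacuum dips, a monotone driver
#' decay, staged convergence of all channels to a ~15 kPa quasi-static
#' level with an ~8.5 ms reverberation period, sensor noise, and an
#' optional thermal-drift artifact.
#'
#' @param precursor Length-2: precursor wavelet amplitude (Pa) and
#'   duration (s).
#' @param jet_peak Initial jet stagnation amplitude, Pa (the driver burst
#'   level).
#' @param jet_decay_tau Exponential decay constant of the jet, s (6 ms:
#'   decay completes over ~18 ms, i.e. three time constants).
#' @param ripple Length-2: ripple frequency (Hz) and relative amplitude.
#' @param quasi_static Final quasi-static gauge level, Pa.
#' @param reverberation_period Longitudinal reverberation period, s.
#' @param static_fluctuation_bound Bound on the static-channel
#'   fluctuation, Pa.
#' @param vacuum_dip_depth Depth of the sub-ambient static dip, Pa.
#' @param noise_sd Gaussian sensor noise standard deviation, Pa.
#' @param drift_rate Linear thermal-drift artifact, Pa/s.
#' @param shock_fraction Probability of a clean (step-onset) rupture.
#' @param seed Integer RNG seed; same seed gives bit-identical records.
#' @return An object of class `record_spec`.
#' @export
record_spec <- function(precursor = c(20e3, 2e-4),
                        jet_peak = 138e3,
                        jet_decay_tau = 6e-3,
                        ripple = c(1300, 0.03),
                        quasi_static = 15e3,
                        reverberation_period = 8.5e-3,
                        static_fluctuation_bound = 20e3,
                        vacuum_dip_depth = 5e3,
                        noise_sd = 200,
                        drift_rate = 0,
                        shock_fraction = 0.10,
                        seed = 1L) {
  stopifnot(precursor[1] >= 0, precursor[2] > 0, jet_peak >= 0,
            jet_decay_tau > 0, ripple[1] > 0, ripple[2] >= 0,
            quasi_static >= 0, reverberation_period > 0,
            static_fluctuation_bound >= 0, vacuum_dip_depth >= 0,
            noise_sd >= 0,
            shock_fraction >= 0, shock_fraction <= 1)
  structure(list(precursor = precursor, jet_peak = jet_peak,
                 jet_decay_tau = jet_decay_tau, ripple = ripple,
                 quasi_static = quasi_static,
                 reverberation_period = reverberation_period,
                 static_fluctuation_bound = static_fluctuation_bound,
                 vacuum_dip_depth = vacuum_dip_depth,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 shock_fraction = shock_fraction,
                 seed = as.integer(seed)),
            class = "record_spec")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a multichannel synthetic OPC sensor record
#'
#' Deterministic skeleton plus seeded Gaussian noise. The stagnation
#' channel is a precursor wavelet followed by an exponential jet decay
#' with sinusoidal ripple, converging to the quasi-static level with a
#' smoothed step train at the reverberation period (the staged
#' convergence driven by the longitudinal compression wave). The static
#' channel fluctuates below its bound with at least one partial-vacuum
#' dip; the driver channel decays monotonically to the quasi-static
#' level. With probability `shock_fraction` the onset is a one-sample
#' step (clean rupture); otherwise a 1.5 ms linear ramp (petaling
#' rupture).
#'
#' @param spec A [record_spec()].
#' @param duration Record length after burst, s (>= 30 ms for the full
#'   structure).
#' @param sample_rate Sampling rate, Hz.
#' @param pre_trigger Quiet pre-trigger interval before the burst, s.
#' @return Named list of three [pressure_trace()] objects
#'   (`stagnation`, `static`, `driver`) with attribute `shock_branch`.
#' @export
gen_opc_record <- function(spec, duration = 0.06, sample_rate = 8e5,
                           pre_trigger = 1e-3) {
  if (duration < 0.03)
    stop("duration must be at least 30 ms for the full record structure")
  .with_seed(spec$seed, {
    shock <- stats::runif(1) < spec$shock_fraction
    t <- seq(-pre_trigger, duration, by = 1 / sample_rate)
    n <- length(t)
    tp <- pmax(t, 0)
    Trev <- spec$reverberation_period

    # precursor wavelet arrives first (triangular pulse from t = 0);
    # the jet impingement follows half a millisecond later, with a
    # one-sample step onset for a clean rupture or a 1.5 ms ramp for
    # the usual petaling rupture
    t_jet <- 5e-4
    onset <- if (shock) as.numeric(t >= t_jet)
             else pmin(1, pmax(0, (t - t_jet) / 1.5e-3))
    prec <- spec$precursor[1] *
      pmax(0, 1 - abs(tp - spec$precursor[2] / 2) /
             (spec$precursor[2] / 2)) * (t >= 0)
    # staged convergence: smoothed step train at the reverberation period
    stages <- 4
    stair <- rowMeans(vapply(seq_len(stages), function(k)
      stats::plogis((tp - k * Trev) / (0.06 * Trev)),
      numeric(n))) * (t >= 0)
    # decaying reverberation ripple keeps the tail periodicity visible
    rev_ripple <- 0.05 * spec$quasi_static *
      cos(2 * pi * tp / Trev) * exp(-tp / 0.04) * (t >= 0)

    jet <- (spec$jet_peak - spec$quasi_static) *
      exp(-tp / spec$jet_decay_tau) *
      (1 + spec$ripple[2] * sin(2 * pi * spec$ripple[1] * tp))
    stag <- prec + onset * jet + spec$quasi_static * stair + rev_ripple

    stat_fluct <- 0.35 * spec$static_fluctuation_bound *
      exp(-tp / spec$jet_decay_tau) *
      sin(2 * pi * 800 * tp + pi / 3) * (t >= 0)
    dip <- -spec$vacuum_dip_depth *
      exp(-((tp - 2e-3) / 4e-4)^2) * (t >= 0)
    stat <- spec$quasi_static * stair + stat_fluct + dip -
      spec$quasi_static * 0.2 * exp(-tp / 1e-3) * (t >= 0)

    drv <- ifelse(t >= 0,
                  spec$quasi_static +
                    (spec$jet_peak - spec$quasi_static) *
                      exp(-tp / spec$jet_decay_tau),
                  spec$jet_peak)

    mk <- function(x, id, role) {
      x <- x + spec$drift_rate * (t - t[1]) +
        stats::rnorm(n, 0, spec$noise_sd)
      pressure_trace(x, sample_rate = sample_rate, t0 = -pre_trigger,
                     channel_id = id, role = role)
    }
    out <- list(stagnation = mk(stag, "probe1_stagnation", "stagnation"),
                static = mk(stat, "probe1_static", "static"),
                driver = mk(drv, "driver", "driver"))
    attr(out, "shock_branch") <- shock
    out
  })
}

#' Generate paired static/dynamic blast-wave records
#'
#' The static channel is a Friedlander waveform; the dynamic channel is
#' scaled to the Rankine-Hugoniot peak dynamic pressure and given a
#' faster decay exponent and a longer positive tail (dynamic pressure
#' decays more abruptly yet lasts longer than the static overpressure),
#' clamped at zero since q = (1/2) rho u^2 cannot be negative.
#'
#' @param w A [friedlander_wave()].
#' @param sample_rate Sampling rate, Hz (>= 10 / t_pos).
#' @param c A [gas_constants()] object.
#' @param dyn_duration_factor Positive-phase duration of the dynamic
#'   channel relative to the static channel (> 1).
#' @param dyn_decay_factor Decay-shape exponent of the dynamic channel
#'   relative to the static channel (> 1).
#' @param duration Record length, s.
#' @return Named list of [pressure_trace()] objects `static`, `dynamic`.
#' @export
gen_blast_record <- function(w, sample_rate = 8e5, c = gas_constants(),
                             dyn_duration_factor = 1.5,
                             dyn_decay_factor = 2,
                             duration = 4 * w$t_pos) {
  if (sample_rate < 10 / w$t_pos)
    stop("sample_rate too low to resolve the positive phase")
  stopifnot(dyn_duration_factor > 1, dyn_decay_factor > 1)
  t <- seq(0, duration, by = 1 / sample_rate)
  stat <- friedlander_pressure(t, w)
  q_peak <- peak_dynamic_pressure(w$dp_peak, c)
  t_pos_q <- dyn_duration_factor * w$t_pos
  b_q <- dyn_decay_factor * max(w$b, 1)
  dyn <- pmax(0, q_peak * (1 - t / t_pos_q) * exp(-b_q * t / t_pos_q))
  list(static = pressure_trace(stat, sample_rate = sample_rate,
                               channel_id = "blast_static",
                               role = "static"),
       dynamic = pressure_trace(dyn, sample_rate = sample_rate,
                                channel_id = "blast_dynamic",
                                role = "dynamic"))
}

#' Degrade a true motion track to a camera-frame observation
#'
#' Resamples a track at the camera frame rate (8-9 kfps in the apparatus
#' imaging) and adds i.i.d. Gaussian position noise emulating pixel
#' quantization; deterministic given the seed.
#'
#' @param true_motion A [track_record()] (the native, finely sampled
#'   motion).
#' @param frame_rate Camera frame rate, Hz (must not exceed the native
#'   sampling rate).
#' @param pixel_noise Position noise standard deviation, m.
#' @param seed Integer RNG seed.
#' @return A [track_record()] at the camera frame rate.
#' @export
gen_track <- function(true_motion, frame_rate = 8500, pixel_noise = 2e-4,
                      seed = 1L) {
  stopifnot(inherits(true_motion, "track_record"))
  native <- 1 / stats::median(diff(true_motion$times))
  if (frame_rate > native + 1e-9)
    stop("frame_rate exceeds native track sampling (", round(native),
         " Hz)")
  .with_seed(seed, {
    tt <- seq(min(true_motion$times), max(true_motion$times),
              by = 1 / frame_rate)
    x <- stats::approx(true_motion$times, true_motion$positions, tt)$y
    x <- x + stats::rnorm(length(x), 0, pixel_noise)
    track_record(tt, x, frame_rate = frame_rate)
  })
}
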