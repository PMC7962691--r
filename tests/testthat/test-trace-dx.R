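make_friedlander_trace <- function(dp = 20e3, t_pos = 0.2e-3, b = 1,
                                   sr = 8e5, pre = 1e-3, dur = 5e-3,
                                   ramp = 0, baseline = 0) {
  t <- seq(-pre, dur, by = 1 / sr)
  w <- friedlander_wave(dp, t_pos, b)
  p <- ifelse(t >= 0, friedlander_pressure(pmax(t, 0), w), 0)
  if (ramp > 0) {
    onset <- pmin(1, pmax(0, t / ramp))
    p <- ifelse(t >= 0 & t < ramp, onset * dp, p)
    p[t >= ramp] <- friedlander_pressure(pmax(t[t >= ramp] - ramp, 0), w)
  }
  pressure_trace(p + baseline, sample_rate = sr, t0 = -pre)
}

test_that("step-onset blast record is diagnosed as a shock front", {
  tr <- make_friedlander_trace()
  d <- diagnose(tr)
  expect_equal(d$peak_overpressure, 20e3, tolerance = 1e-6)
  expect_lt(d$rise_time, 10e-6)
  expect_true(d$is_shock_front)
  expect_equal(d$positive_phase_duration, 0.2e-3, tolerance = 0.05)
})

test_that("1.5 ms ramp onset is jet-type, not a shock", {
  tr <- make_friedlander_trace(t_pos = 10e-3, dur = 30e-3, ramp = 1.5e-3)
  d <- diagnose(tr)
  expect_false(d$is_shock_front)
  expect_gt(d$rise_time, 0.5e-3)
  expect_true(classify_shock(make_friedlander_trace()))
  expect_false(classify_shock(tr))
})

test_that("an all-constant trace yields an empty report, not an error", {
  d <- diagnose(pressure_trace(rep(500, 2000), 8e5, 0))
  expect_equal(d$peak_overpressure, 0)
  expect_false(d$is_shock_front)
  expect_error(diagnose(pressure_trace(rep(0, 100), 8e5, 0)), "short")
})

test_that("diagnosis is invariant to a constant pre-trigger baseline", {
  t1 <- make_friedlander_trace(t_pos = 2e-3, dur = 20e-3)
  t2 <- make_friedlander_trace(t_pos = 2e-3, dur = 20e-3, baseline = 5e3)
  d1 <- diagnose(t1)
  d2 <- diagnose(t2)
  expect_equal(d2$peak_overpressure, d1$peak_overpressure,
               tolerance = 1e-9)
  expect_equal(d2$impulse, d1$impulse, tolerance = 1e-9)
  expect_equal(d2$quasi_static_level, d1$quasi_static_level,
               tolerance = 1e-9)
  expect_equal(d2$baseline - d1$baseline, 5e3, tolerance = 1e-9)
})

test_that("dominant decay-ripple frequency is recovered within a bin", {
  sr <- 8e5
  tt <- seq(0, 0.05, by = 1 / sr)
  for (f in c(500, 1300, 5000)) {
    p <- 30e3 * exp(-tt / 6e-3) + 2e3 * sin(2 * pi * f * tt) + 15e3
    d <- diagnose(pressure_trace(p, sr, 0))
    bin <- sr / length(tt)
    expect_lt(abs(d$dominant_frequency - f), 2 * bin + 1)
  }
})

test_that("impulse integral handles canonical shapes", {
  sr <- 1e5
  # constant 10 kPa for 10 ms -> 100 Pa s
  tr <- pressure_trace(rep(10e3, 0.01 * sr + 1), sr, 0)
  expect_equal(impulse_integral(tr, c(0, 0.01)), 100, tolerance = 1e-6)
  # triangular decay, 20 kPa over 5 ms -> 50 Pa s
  t <- seq(0, 5e-3, by = 1 / sr)
  tri <- pressure_trace(20e3 * (1 - t / 5e-3), sr, 0)
  expect_equal(impulse_integral(tri, c(0, 5e-3)), 50, tolerance = 1e-4)
  # antisymmetric wave integrates to zero
  t2 <- seq(0, 1e-2, by = 1 / sr)
  anti <- pressure_trace(5e3 * sin(2 * pi * 200 * t2), sr, 0)
  expect_equal(impulse_integral(anti, c(0, 1e-2)), 0, tolerance = 1e-6)
  expect_error(impulse_integral(tr, c(5e-3, 1e-3)), "empty")
  expect_error(impulse_integral(tr, c(0, 1)), "outside")
})

test_that("downsampling 800 kHz to 100 kHz barely changes jet-record
           peak and impulse", {
  spec <- record_spec(noise_sd = 0, shock_fraction = 0, seed = 7)
  rec <- gen_opc_record(spec, duration = 0.04)
  tr <- rec$stagnation
  keep <- seq(1, length(tr$samples), by = 8)
  tr_lo <- pressure_trace(tr$samples[keep], tr$sample_rate / 8, tr$t0,
                          role = tr$role)
  d_hi <- diagnose(tr)
  d_lo <- diagnose(tr_lo)
  expect_equal(d_lo$peak_overpressure, d_hi$peak_overpressure,
               tolerance = 0.01)
  win <- c(0, 0.03)
  expect_equal(impulse_integral(tr_lo, win), impulse_integral(tr, win),
               tolerance = 0.01)
})

test_that("classifier recovers the configured shock incidence over a
           seeded batch", {
  frac <- shock_batch_fraction(200)
  # binomial: p = 0.10, n = 200, sd ~ 0.021; allow three sigma
  expect_gt(frac, 0.10 - 3 * sqrt(0.1 * 0.9 / 200))
  expect_lt(frac, 0.10 + 3 * sqrt(0.1 * 0.9 / 200))
})
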