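test_that("sound speed follows the perfect-gas closed form", {
  expect_equal(sound_speed(293.15), sqrt(1.4 * 287.05 * 293.15))
  expect_equal(sound_speed(293.15), 343.2, tolerance = 1e-3)
  # at the coldest jet temperature (-60 degC)
  expect_equal(sound_speed(213.15), 292.7, tolerance = 1e-3)
  # square-root homogeneity is exact
  expect_equal(sound_speed(4 * 300), 2 * sound_speed(300))
  expect_error(sound_speed(-1), "positive")
})

test_that("gas_state enforces the ideal-gas closure", {
  c0 <- gas_constants()
  st <- gas_state(p = 101325, T = 293.15)
  expect_equal(st$rho * c0$R_air * st$T, st$p, tolerance = 1e-12)
  st2 <- gas_state(p = 101325, rho = st$rho)
  expect_equal(st2$T, 293.15, tolerance = 1e-12)
  expect_error(gas_state(p = 101325, rho = 1.2, T = 400), "closure")
  expect_error(gas_state(p = -1, T = 293), "positive")
})

test_that("blast static/dynamic pressure partition matches the closed form", {
  c0 <- gas_constants()
  q <- function(dp) (5 / 2) * dp^2 / (7 * c0$p_amb + dp)
  expect_equal(peak_dynamic_pressure(103e3), q(103e3))
  # moderate blast: ~33 kPa of dynamic pressure rides on 103 kPa static
  expect_equal(peak_dynamic_pressure(103e3) / 1e3, 33, tolerance = 0.02)
  # strong blast: the two components are about equal
  expect_equal(peak_dynamic_pressure(480e3) / 480e3, 1, tolerance = 0.05)
  expect_identical(peak_dynamic_pressure(0), 0)
  expect_error(peak_dynamic_pressure(-5), "non-negative")
})

test_that("dynamic pressure partition is convex-increasing with weak limit", {
  dp <- seq(0, 500e3, by = 10e3)
  q <- peak_dynamic_pressure(dp)
  expect_true(all(diff(q) > 0))
  expect_true(all(diff(diff(q)) > 0))
  # weak limit q / dp^2 -> 5 / (14 p_amb)
  c0 <- gas_constants()
  expect_equal(peak_dynamic_pressure(1e3) / 1e3^2, 5 / (14 * c0$p_amb),
               tolerance = 2e-3)
  # in the acoustic regime (10 kPa) the blast wind is negligible
  expect_lt(peak_dynamic_pressure(10e3), 0.5e3)
})

test_that("shock Mach number relation has correct limits and is consistent
           with the full jump conditions", {
  c0 <- gas_constants()
  expect_equal(shock_mach_from_overpressure(0), 1)
  expect_equal(shock_mach_from_overpressure(101325), sqrt(1 + 6 / 7),
               tolerance = 1e-12)
  expect_gt(shock_mach_from_overpressure(480e3),
            shock_mach_from_overpressure(103e3))
  # post-shock kinetic pressure equals the partition relation
  for (dp in c(10e3, 103e3, 480e3)) {
    Ms <- shock_mach_from_overpressure(dp, c0)
    st <- post_shock_state(Ms, c0)
    expect_equal(0.5 * st$rho * st$u^2, peak_dynamic_pressure(dp, c0),
                 tolerance = 1e-6)
    expect_equal(st$p - c0$p_amb, dp, tolerance = 1e-9)
  }
})

test_that("Friedlander waveform has the defining endpoint values", {
  w <- friedlander_wave(20e3, 5e-3, b = 1.2)
  expect_equal(friedlander_pressure(0, w), 20e3)
  expect_equal(friedlander_pressure(w$t_pos, w), 0)
  # under-pressure phase beyond t_pos, returning toward zero
  late <- friedlander_pressure(c(1.5, 3, 6) * w$t_pos, w)
  expect_true(all(late < 0))
  expect_true(abs(late[3]) < abs(late[2]))
  expect_error(friedlander_pressure(-1e-3, w), "non-negative")
})

test_that("Friedlander impulse matches adaptive quadrature", {
  # triangle limit
  w0 <- friedlander_wave(20e3, 5e-3, b = 0)
  quad0 <- stats::integrate(friedlander_pressure, 0, w0$t_pos, w = w0,
                            rel.tol = 1e-10)$value
  expect_equal(friedlander_impulse(w0), 20e3 * 5e-3 / 2)
  expect_equal(friedlander_impulse(w0), quad0, tolerance = 1e-8)
  for (b in c(0.35, 1, 2.7)) {
    w <- friedlander_wave(50e3, 2e-3, b = b)
    quad <- stats::integrate(friedlander_pressure, 0, w$t_pos, w = w,
                             rel.tol = 1e-12)$value
    expect_equal(friedlander_impulse(w), quad, tolerance = 1e-8)
  }
})

test_that("isentropic temperature drop reproduces the cold vented jet", {
  expect_equal(isentropic_temperature(2e5, 2e5, 300), 300)
  # driver gas expanding from burst pressure to ambient cools strongly
  expect_equal(isentropic_temperature(101.325e3, 239.325e3, 293), 229,
               tolerance = 2e-3)
  # under partial vacuum (80 kPa) it reaches about -59 degC
  expect_equal(isentropic_temperature(80e3, 239.325e3, 293), 214,
               tolerance = 2e-3)
  expect_error(isentropic_temperature(-1, 2e5, 300), "positive")
})

test_that("TNT equivalence of the pressurized diaphragm bulge", {
  expect_identical(tnt_equivalent_mass(0, 1), 0)
  # hemispherical bulge of aperture radius at burst pressure: ~59 mg as
  # an ideal upper estimate
  V <- 2 / 3 * pi * 0.07^3
  m <- tnt_equivalent_mass(138e3, V)
  expect_equal(m * 1e6, 59, tolerance = 0.01)
  expect_equal(tnt_equivalent_mass(138e3, 2 * V), 2 * m)
  expect_equal(tnt_equivalent_mass(138e3, V, yield_factor = 0.5), m / 2)
})

test_that("psi/kPa conversion is fixed and invertible", {
  expect_equal(psi_to_kpa(20), 137.89514)
  expect_equal(kpa_to_psi(psi_to_kpa(13.7)), 13.7)
})
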