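test_that("finite-volume kernel reproduces the exact Sod solution", {
  s <- sod_run(1000)
  L1 <- sum(abs(s$num$rho - s$exact$rho)) / sum(abs(s$exact$rho))
  expect_lt(L1, 0.01)
  L1u <- sum(abs(s$num$u - s$exact$u)) / sum(abs(s$exact$u) + 1e-12)
  expect_lt(L1u, 0.02)
})

test_that("solver flags non-physical states with a located diagnostic", {
  n <- 100
  x_face <- seq(0, 1, length.out = n + 1)
  # a corrupted state (NaN velocity) is caught with cell/time location
  init <- function(xc)
    data.frame(rho = 1, u = ifelse(xc > 0.5, NaN, 0), p = 1e5, s = 0)
  expect_error(
    solve_euler1d(x_face, rep(1, n + 1), init, t_end = 1e-3),
    "solver failure")
  bad <- function(xc)
    data.frame(rho = rep(-1, length(xc)), u = 0, p = 1e5, s = 0)
  expect_error(
    solve_euler1d(x_face, rep(1, n + 1), bad, t_end = 1e-3),
    "positive")
  expect_error(
    solve_euler1d(x_face, rep(1, n + 1), bad, t_end = 1e-3, cfl = 2),
    "cfl")
})

test_that("lumped blowdown converges to the two-volume equilibrium", {
  burst <- burst_model()
  # equal driver/test volumes halve the burst overpressure exactly
  f <- function(d) {
    g <- chamber_geometry(driver_length = d)
    v <- section_volumes(g)
    v$V_driver - v$V_test
  }
  d_eq <- stats::uniroot(f, c(0.5, 1.3), tol = 1e-10)$root
  lb <- lumped_blowdown(chamber_geometry(driver_length = d_eq), burst,
                        t_end = 0.4)
  expect_equal(lb$quasi_static, 69e3, tolerance = 1e-6)
  tail_p <- utils::tail(lb$trace$samples, 5)
  expect_equal(mean(tail_p), 69e3, tolerance = 0.01)

  # default calibrated geometry equilibrates near the observed 15 kPa
  lb0 <- opc_lumped_default()
  expect_equal(lb0$quasi_static / 1e3, 15, tolerance = 0.10)
  # driver pressure decays monotonically toward equilibrium (up to
  # integrator noise around the settled level)
  expect_true(all(diff(lb0$trace$samples) <= 1))
  # discharge timescale: overpressure e-folds in a few ms, so the jet
  # envelope (about three time constants) dies over ~15-20 ms
  expect_gt(lb0$efold_time, 2e-3)
  expect_lt(lb0$efold_time, 10e-3)
  expect_error(
    lumped_blowdown(chamber_geometry(), burst, discharge_coeff = 0),
    "degenerate aperture")
})

test_that("chamber simulation conserves mass and energy once open", {
  h <- opc_default_run()
  open <- h$times > h$burst$petal_duration
  m <- h$mass[open]
  e <- h$energy[open]
  expect_lt(max(abs(m / m[1] - 1)), 1e-6)
  expect_lt(max(abs(e / e[1] - 1)), 1e-6)
})

test_that("PDE late-time level matches the lumped two-volume oracle", {
  h <- opc_default_run()
  lb <- opc_lumped_default()
  tr <- h$probes$specimen_static
  tt <- trace_times(tr)
  qs <- stats::median(tr$samples[tt >= 0.05])
  expect_equal(qs, lb$quasi_static, tolerance = 0.02)
})

test_that("halving the cell size leaves the solution converged", {
  h1 <- opc_default_run()                       # 720 cells
  h2 <- memo("run_1440",
             solve_quasi1d(chamber_geometry(), burst_model(),
                           t_end = 0.06, n_cells = 1440))
  qs <- function(h) {
    tr <- h$probes$specimen_static
    stats::median(tr$samples[trace_times(tr) >= 0.05])
  }
  expect_equal(qs(h2), qs(h1), tolerance = 0.01)
  p1 <- diagnose(h1$probes$end_wall)$reverberation_period
  p2 <- diagnose(h2$probes$end_wall)$reverberation_period
  expect_equal(p2, p1, tolerance = 0.03)
})

test_that("specimen-station static pressure is jet-like, not shock-like", {
  h <- opc_default_run()
  tr <- h$probes$specimen_static
  tt <- trace_times(tr)
  decay <- tt >= 2e-3 & tt <= 18e-3   # jet-decay phase, past startup
  # fluctuates at a low level below 20 kPa ...
  expect_lt(max(tr$samples[decay]), 20e3)
  # ... with partial-vacuum excursions
  expect_lt(min(tr$samples[decay]), 0)
})

test_that("vented-gas front tracking behaves physically", {
  h <- opc_default_run()
  v <- jet_front_speed(h)
  expect_gt(v, 50)
  expect_lt(v, 450)
  # front speed rises with burst pressure
  quick <- function(p_burst)
    solve_quasi1d(chamber_geometry(), burst_model(p_burst),
                  t_end = 4e-3, n_cells = 360)
  v_hi <- jet_front_speed(memo("front_hi", quick(138e3)))
  v_lo <- jet_front_speed(memo("front_lo", quick(69e3)))
  expect_gt(v_hi, v_lo)
  # window validation
  expect_error(jet_front_speed(h, c(0.05, 0.1)), "downstream")
  expect_error(jet_front_speed(h, c(1.7, 1.79)), "never reached")
})

test_that("spherical wavelet peak decays with range, at least as 1/r", {
  b <- burst_model()
  peaks <- vapply(c(0.127, 0.25, 0.5), function(r)
    attr(memo(paste0("wav_", r),
              solve_spherical_burst(b, r, n_cells = 700)), "peak"),
    numeric(1))
  expect_true(all(diff(peaks) < 0))
  # far-field decay steeper than or equal to 1/r
  expect_lte(peaks[3] / peaks[2], 0.25 / 0.5 * 1.05)
  expect_error(solve_spherical_burst(b, 0.05), "inside")
})
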