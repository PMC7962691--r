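test_that("same seed gives bit-identical records; noise differs across
           seeds on an identical skeleton", {
  a <- gen_opc_record(record_spec(seed = 11), duration = 0.03)
  b <- gen_opc_record(record_spec(seed = 11), duration = 0.03)
  expect_identical(a$stagnation$samples, b$stagnation$samples)
  expect_identical(a$static$samples, b$static$samples)
  # skeleton (noise-free) is seed-independent once the rupture branch is
  # pinned
  s1 <- gen_opc_record(record_spec(seed = 1, noise_sd = 0,
                                   shock_fraction = 0), duration = 0.03)
  s2 <- gen_opc_record(record_spec(seed = 2, noise_sd = 0,
                                   shock_fraction = 0), duration = 0.03)
  expect_identical(s1$stagnation$samples, s2$stagnation$samples)
  n1 <- gen_opc_record(record_spec(seed = 1, shock_fraction = 0),
                       duration = 0.03)
  n2 <- gen_opc_record(record_spec(seed = 2, shock_fraction = 0),
                       duration = 0.03)
  expect_false(identical(n1$stagnation$samples, n2$stagnation$samples))
  expect_equal(n1$stagnation$samples - s1$stagnation$samples,
               n1$stagnation$samples - s1$stagnation$samples)
  expect_error(gen_opc_record(record_spec(), duration = 0.01), "30 ms")
})

test_that("record generation does not disturb the caller's RNG stream", {
  set.seed(99)
  r1 <- stats::runif(1)
  set.seed(99)
  invisible(gen_opc_record(record_spec(seed = 5), duration = 0.03))
  r2 <- stats::runif(1)
  expect_identical(r1, r2)
})

test_that("analyzer recovers the generator's own parameters", {
  spec <- record_spec(seed = 1)
  rec <- gen_opc_record(spec, duration = 0.06)
  d <- diagnose(rec$stagnation)
  expect_equal(d$quasi_static_level, spec$quasi_static,
               tolerance = 0.5e3 / spec$quasi_static)
  expect_equal(d$reverberation_period, spec$reverberation_period,
               tolerance = 0.5e-3 / spec$reverberation_period)
  expect_lt(abs(d$dominant_frequency - spec$ripple[1]), 25)
  # static channel: bounded fluctuation with a partial-vacuum dip
  tt <- trace_times(rec$static)
  lo <- tt >= 0 & tt <= 0.018
  expect_lt(max(rec$static$samples[lo]), spec$static_fluctuation_bound)
  expect_lt(min(rec$static$samples[lo]), 0)
  # driver skeleton decays monotonically
  drv <- gen_opc_record(record_spec(seed = 3, noise_sd = 0),
                        duration = 0.03)$driver
  expect_true(all(diff(drv$samples[trace_times(drv) >= 0]) <= 1e-9))
})

test_that("noise-free clean rupture gives a one-sample rise", {
  rec <- gen_opc_record(record_spec(seed = 4, noise_sd = 0,
                                    shock_fraction = 1), duration = 0.03)
  expect_true(attr(rec, "shock_branch"))
  d <- diagnose(rec$stagnation)
  expect_lt(d$rise_time, 2.5e-6)   # within two samples at 800 kHz
  expect_true(d$is_shock_front)
})

test_that("blast-record pair has the prescribed partition and shape", {
  w <- friedlander_wave(103e3, 5e-3, b = 1)
  rec <- gen_blast_record(w, sample_rate = 2e5)
  expect_equal(max(rec$dynamic$samples) / 1e3, 33, tolerance = 0.02)
  expect_equal(max(rec$static$samples), 103e3, tolerance = 1e-6)
  # dynamic channel: decays faster early yet keeps a longer positive tail
  t <- trace_times(rec$static)
  i_late <- which(t > 1.2 * w$t_pos & t < 1.4 * w$t_pos)
  expect_true(all(rec$static$samples[i_late] <= 0))
  expect_true(all(rec$dynamic$samples[i_late] > 0))
  expect_true(all(rec$dynamic$samples >= 0))
  # vanishing blast -> vanishing channels
  w0 <- friedlander_wave(1e-3, 5e-3, b = 1)
  rec0 <- gen_blast_record(w0, sample_rate = 2e5)
  expect_lt(max(abs(rec0$dynamic$samples)), 1e-6)
  expect_error(gen_blast_record(w, sample_rate = 100), "sample_rate")
})

test_that("camera-track degradation round-trips the velocity change", {
  # uniformly accelerated reference motion sampled at 100 kHz
  tt <- seq(0, 5e-3, by = 1e-5)
  truth <- track_record(tt, 0.5 * 3000 * tt^2)
  s <- sphere_spec()
  # noise-free resampling is an exact subsample
  clean <- gen_track(truth, frame_rate = 1e4, pixel_noise = 0, seed = 1)
  expect_equal(clean$positions,
               stats::approx(tt, truth$positions, clean$times)$y)
  # 8.5 kfps with 0.2 mm pixel noise still recovers delta-v within 5%
  noisy <- gen_track(truth, frame_rate = 8500, pixel_noise = 2e-4,
                     seed = 2)
  kin <- analyze_track(noisy, s)
  expect_equal(kin$delta_v, 3000 * max(noisy$times), tolerance = 0.05)
  # stationary input stays stationary up to noise
  still <- gen_track(track_record(tt, rep(0, length(tt))),
                     frame_rate = 8500, pixel_noise = 2e-4, seed = 3)
  kin0 <- analyze_track(still, s)
  expect_lt(abs(kin0$impulse), 0.05)
  expect_error(gen_track(truth, frame_rate = 2e5), "native")
})
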