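# The coupled-oscillator generator, sensor projection and SNR-calibrated
# noise.

test_that("zero jitter yields a pure sinusoid at the base frequency", {
  spec <- oscillator_spec(jitter_scale = 0)
  s <- generate_jittered_oscillation(spec, 1)
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(s^2)), 1, tolerance = 1e-9)
  ps <- welch_cross_spectrum(s, s)
  freqs <- attr(ps, "freqs")
  expect_equal(freqs[which.max(Re(ps))], 12)
})

test_that("oscillations are deterministic given the seed", {
  spec <- oscillator_spec()
  expect_identical(generate_jittered_oscillation(spec, 99),
                   generate_jittered_oscillation(spec, 99))
  expect_false(identical(generate_jittered_oscillation(spec, 99),
                         generate_jittered_oscillation(spec, 100)))
})

test_that("jittered oscillations stay inside the alpha band", {
  spec <- oscillator_spec(jitter_scale = 0.5)
  for (seed in 1:3) {
    s <- generate_jittered_oscillation(spec, seed)
    ps <- Re(welch_cross_spectrum(s, s))
    freqs <- attr(ps, "freqs")
    in_band <- sum(ps[freqs >= 9 & freqs <= 14]) / sum(ps)
    expect_gte(in_band, 0.95)
  }
  expect_error(oscillator_spec(jitter_scale = -1), "nonnegative")
})

test_that("the coupling loop reaches its target coherence", {
  spec <- oscillator_spec()
  p1 <- generate_coupled_pair(spec, 1, tolerance = 0, rng_seed = 5)
  expect_identical(p1$series_1, p1$series_2)
  expect_equal(p1$achieved_coherence, 1)
  expect_equal(p1$iterations_used, 0L)

  p4 <- generate_coupled_pair(spec, 0.4, rng_seed = 5)
  expect_gte(p4$achieved_coherence, 0.38)
  expect_lte(p4$achieved_coherence, 0.42)
  expect_equal(ms_coherence(p4$series_1, p4$series_2),
               p4$achieved_coherence)

  expect_error(generate_coupled_pair(spec, 0.1, max_iterations = 0,
                                     rng_seed = 5),
               "did not converge")
})

test_that("generator calibration: mean achieved coherence hits each target", {
  spec <- oscillator_spec()
  for (target in c(0.1, 0.2, 0.4)) {
    ach <- vapply(1:20, function(k)
      generate_coupled_pair(spec, target,
                            rng_seed = 80000 + k)$achieved_coherence,
      numeric(1))
    expect_lte(abs(mean(ach) - target), 0.02)
  }
})

test_that("source activity carries identical series on patch members", {
  spec <- short_spec()
  pair <- generate_coupled_pair(spec, 0.4, rng_seed = 3)
  p1 <- structure(list(seed_vertex = 2, member_vertices = c(2, 4, 6, 8),
                       target_area = 2, achieved_area = 2), class = "patch")
  p2 <- structure(list(seed_vertex = 11, member_vertices = 11,
                       target_area = 0, achieved_area = 0.5),
                  class = "patch")
  S <- build_source_activity(pair, p1, p2, 20)
  expect_equal(dim(S), c(20, spec$n_samples))
  expect_true(all(S[setdiff(1:20, c(p1$member_vertices, 11)), ] == 0))
  for (v in c(4, 6, 8)) expect_identical(S[2, ], S[v, ])
  expect_equal(S[11, ], pair$series_2, ignore_attr = TRUE)

  pt <- build_source_activity(pair, p2,
                              structure(list(seed_vertex = 1,
                                             member_vertices = 1,
                                             target_area = 0,
                                             achieved_area = 0.5),
                                        class = "patch"), 20)
  expect_equal(sum(rowSums(pt != 0) > 0), 2)
  expect_true(all(build_source_activity(pair, p1, p2, 20,
                                        amplitude = 0) == 0))

  p_overlap <- structure(list(seed_vertex = 4, member_vertices = c(4, 5),
                              target_area = 2, achieved_area = 1),
                         class = "patch")
  expect_error(build_source_activity(pair, p1, p_overlap, 20),
               "overlap")
})

test_that("sensor projection is the linear image of the activity", {
  gain <- matrix(stats::rnorm(5 * 8), 5, 8)
  expect_true(all(project_to_sensors(gain, matrix(0, 8, 10)) == 0))
  S1 <- matrix(0, 8, 10); S1[3, ] <- stats::rnorm(10)
  M1 <- project_to_sensors(gain, S1)
  expect_equal(M1, outer(gain[, 3], S1[3, ]))
  S2 <- matrix(0, 8, 10); S2[7, ] <- stats::rnorm(10)
  expect_equal(project_to_sensors(gain, S1 + S2),
               project_to_sensors(gain, S1) + project_to_sensors(gain, S2))
  expect_error(project_to_sensors(gain, matrix(0, 7, 10)), "shape error")
})

test_that("noise is calibrated exactly to the requested Frobenius SNR", {
  clean <- matrix(stats::rnorm(40 * 500), 40)
  for (snr in c(0, -20, -13.7, 6)) {
    nz <- add_noise_at_snr(clean, snr, rng_seed = 21)
    realized <- 20 * log10(sqrt(sum(clean^2)) / sqrt(sum(nz$noise^2)))
    expect_equal(realized, snr, tolerance = 1e-6)
    expect_identical(nz$noisy, clean + nz$noise)
  }
  nz0 <- add_noise_at_snr(clean, 0, rng_seed = 21)
  expect_equal(sqrt(sum(nz0$noise^2)), sqrt(sum(clean^2)),
               tolerance = 1e-9 * sqrt(sum(clean^2)))
  nzm20 <- add_noise_at_snr(clean, -20, rng_seed = 21)
  expect_equal(sqrt(sum(nzm20$noise^2)), 10 * sqrt(sum(clean^2)),
               tolerance = 1e-8 * sqrt(sum(clean^2)))
  expect_error(add_noise_at_snr(matrix(0, 4, 5), 0, 1), "undefined SNR")
})

test_that("realized noise covariance is symmetric PSD and near-diagonal", {
  clean <- matrix(stats::rnorm(30 * 4000), 30)
  nz <- add_noise_at_snr(clean, 0, rng_seed = 8)
  q <- nz$noise_cov$q
  expect_equal(q, t(q), tolerance = 1e-12)
  ev <- eigen(q, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
  # white noise: off-diagonal correlations are sampling noise ~ 1/sqrt(n)
  r <- stats::cov2cor(q)
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 3 / sqrt(nz$noise_cov$n_samples_used))
})

test_that("a realization is bit-reproducible and self-consistent", {
  geom <- tiny_geometry()
  spec <- short_spec()
  sim1 <- simulate_realization(geom$lf, seed_1 = 10, seed_2 = 100,
                               patch_area = 2, coupling = 0.4, snr_db = 0,
                               rng_seed = 77, spec = spec)
  sim2 <- simulate_realization(geom$lf, seed_1 = 10, seed_2 = 100,
                               patch_area = 2, coupling = 0.4, snr_db = 0,
                               rng_seed = 77, spec = spec)
  expect_identical(sim1$noisy, sim2$noisy)
  expect_identical(sim1$source_activity, sim2$source_activity)

  expect_identical(sim1$noisy, sim1$clean + sim1$noise)
  active <- c(sim1$patch_1$member_vertices, sim1$patch_2$member_vertices)
  expect_true(all(sim1$source_activity[-active, ] == 0))
  realized <- 20 * log10(sqrt(sum(sim1$clean^2)) / sqrt(sum(sim1$noise^2)))
  expect_equal(realized, 0, tolerance = 1e-6)
})
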