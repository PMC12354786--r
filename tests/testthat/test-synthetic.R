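test_that("same seed reproduces the generated curve bit for bit", {
  g1 <- generate_monotonic(generator_profile(seed = 123))
  g2 <- generate_monotonic(generator_profile(seed = 123))
  expect_identical(g1$curve, g2$curve)
  g3 <- generate_monotonic(generator_profile(seed = 124))
  expect_false(identical(g1$curve$force_per_width, g3$curve$force_per_width))
})

test_that("a flat Poisson profile yields nu2 equal to nu1", {
  prof <- generator_profile(nu2_gen = 0.3, nu1_gen = 0.3,
                            noise_sd_force = 0, noise_sd_stretch = 0)
  g <- generate_monotonic(prof)
  s <- extract_summary(derive_curves(g$curve))
  expect_equal(s$nu2, s$nu1, tolerance = 0.02)
})

test_that("generated ground truth is self-consistent", {
  prof <- generator_profile(noise_sd_force = 0, noise_sd_stretch = 0)
  g <- generate_monotonic(prof)
  # force is the integral of the stiffness profile
  lam <- g$truth$lambda
  f_int <- cumtrapz_local(lam, g$truth$tangent_stiffness)
  expect_equal(g$truth$force_per_width, f_int, tolerance = 1e-5)
  # transverse stretch integrates the Poisson profile
  nu_back <- -diff(log(g$truth$lambda_tr)) / diff(log(lam))
  nu_mid <- (g$truth$nu_inc[-1] + g$truth$nu_inc[-length(lam)]) / 2
  expect_equal(nu_back, nu_mid, tolerance = 1e-3)
})

test_that("cyclic generation hits the scheduled residuals exactly and rejoins the envelope", {
  prof <- generator_profile(noise_sd_force = 0, noise_sd_stretch = 0)
  peaks <- c(1.08, 1.14, 1.2, 1.26, 1.32, 1.4)
  g <- generate_cyclic(prof, peaks)
  rec <- recovery_analysis(g$curve)
  expect_equal(rec$recovery_percent, g$truth_cycles$recovery_percent,
               tolerance = 1e-6)
  # reloading beyond the previous peak rejoins the monotonic envelope
  for (ci in 2:length(peaks)) {
    seg <- g$curve[g$curve$cycle == ci & g$curve$phase == "loading", ]
    beyond <- seg[seg$lambda_ax > peaks[ci - 1] + 1e-9, ]
    f_env <- wallmech:::gen_force(prof, beyond$lambda_ax)
    expect_equal(beyond$force_per_width, f_env, tolerance = 1e-9)
  }
})

test_that("recovery schedule of 100% leaves no residual stretch", {
  prof <- generator_profile(recovery_initial = 100, recovery_floor = 100,
                            noise_sd_force = 0, noise_sd_stretch = 0)
  g <- generate_cyclic(prof, c(1.1, 1.25, 1.4))
  expect_equal(g$truth_cycles$residual_stretch, rep(1, 3))
  rec <- recovery_analysis(g$curve)
  expect_equal(rec$recovery_percent, rep(100, 3), tolerance = 1e-6)
})

test_that("model-driven fixtures resample the five-beam output faithfully", {
  p <- five_beam_params()
  raw0 <- generate_from_model(p, loading = list(type = "monotonic",
                                                lambda_max = 1.4, n = 101),
                              noise = list(force = 0, stretch = 0))
  truth <- attr(raw0, "truth")
  expect_equal(raw0$force_per_width, truth$force_per_width)
  expect_equal(raw0$lambda_tr, truth$lambda_tr)
  # seeded noise perturbs the samples but not the underlying summary much
  raw1 <- generate_from_model(p, loading = list(type = "monotonic",
                                                lambda_max = 1.5, n = 301),
                              noise = list(force = 0.02, stretch = 5e-4),
                              seed = 99)
  s0 <- extract_summary(as_derived_curves(
    simulate_monotonic(p, seq(1, 1.5, length.out = 301))))
  s1 <- extract_summary(derive_curves(raw1))
  expect_equal(s1$E1, s0$E1, tolerance = 0.05 * s0$E1)
  expect_equal(s1$E2, s0$E2, tolerance = 0.05 * s0$E2)
})

test_that("profile invariants are enforced", {
  expect_error(generator_profile(ramp_start = 0.9),
               class = "wallmech_invalid_input")
  expect_error(generator_profile(E1_gen = 80, E2_gen = 70),
               class = "wallmech_invalid_input")
  expect_error(generator_profile(recovery_floor = 90, recovery_initial = 50),
               class = "wallmech_invalid_input")
})
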