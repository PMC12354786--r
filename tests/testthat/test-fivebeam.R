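test_that("initial geometry places the diamond by the node angle", {
  s90 <- build_geometry(90, 1)
  expect_equal(s90$h0, 1, tolerance = 1e-12)
  expect_equal(s90$L0, sqrt(2), tolerance = 1e-12)
  s60 <- build_geometry(60, 1)
  expect_equal(s60$h0, tan(pi / 6), tolerance = 1e-12)
  # all four diagonal beams share one reference length for any angle
  for (th in c(30, 75, 120)) {
    s <- build_geometry(th, 2)
    expect_equal(s$L0, sqrt(s$x0^2 + s$h0^2))
  }
  expect_error(build_geometry(180), class = "wallmech_invalid_input")
})

test_that("connector return map: elastic, perfectly plastic, and hardening branches", {
  p <- five_beam_params(k_c = 10, f_slip = 4, H = 0)
  el <- connector_return_map(2, 0, p)
  expect_equal(el$f, 2)
  expect_equal(el$slip, 0)
  pl <- connector_return_map(8, 0, p)
  expect_equal(pl$f, 4)
  expect_equal(pl$slip, 4 / 10)
  ph <- five_beam_params(k_c = 10, f_slip = 4, H = 5)
  hd <- connector_return_map(8, 0, ph)
  expect_equal(hd$slip, (8 - 4) / 15)
  expect_equal(hd$f, 4 + 5 * hd$slip)
  # infinite threshold never slips
  pinf <- five_beam_params(f_slip = Inf)
  expect_equal(connector_return_map(1e6, 0, pinf)$slip, 0)
})

test_that("return mapping is rate independent on random displacement paths", {
  set.seed(7)
  p <- five_beam_params(k_c = 20, f_slip = 3, H = 8)
  for (rep in 1:3) {
    u_knots <- cumsum(rnorm(50, sd = 0.2))
    drive <- function(n_sub) {
      u_path <- c(0, u_knots)
      slip <- 0; acc <- 0; f <- 0
      for (i in seq_len(length(u_path) - 1)) {
        for (u in seq(u_path[i], u_path[i + 1], length.out = n_sub + 1)[-1]) {
          rm <- connector_return_map(p$k_c * (u - slip), slip, p,
                                     slip_acc = acc)
          slip <- rm$slip; acc <- rm$slip_acc; f <- rm$f
        }
      }
      c(f, slip)
    }
    expect_equal(drive(1), drive(10), tolerance = 1e-8)
  }
})

test_that("bending law starts at zero, is monotone, and plateaus without hardening", {
  p <- five_beam_params(bend_harden = 0, bend_harden_lin = 0, bend_knee = 4)
  L <- 2
  expect_equal(as.numeric(bending_force(0, p, L)), 0)
  d <- seq(0, 1.2, length.out = 100)
  P <- as.numeric(bending_force(d, p, L))
  expect_true(all(diff(P) >= -1e-12))
  # far beyond the knee the force sits at the critical load
  expect_equal(as.numeric(bending_force(1.4, p, L)), p$bend_Pcr,
               tolerance = 0.01 * p$bend_Pcr)
  # negative shortening = straight-beam extension, flagged
  Pneg <- bending_force(-0.1, p, L)
  expect_lt(as.numeric(Pneg), 0)
  expect_true(attr(Pneg, "extension"))
})

test_that("equilibrium at stretch 1 is the stress-free state", {
  p <- five_beam_params()
  st <- solve_equilibrium(p, build_geometry(p$theta, p$scale), 1)
  expect_equal(st$force_per_width, 0, tolerance = 1e-10)
  expect_equal(st$lambda_tr, 1, tolerance = 1e-8)
  expect_equal(st$slip, rep(0, 4))
})

test_that("with slip disabled, load-unload returns to the initial state", {
  p <- five_beam_params(f_slip = Inf)
  st <- build_geometry(p$theta, p$scale)
  for (l in seq(1, 1.2, by = 0.005)[-1]) st <- solve_equilibrium(p, st, l)
  f_peak <- st$force_per_width
  expect_gt(f_peak, 0)
  for (l in rev(seq(1, 1.2, by = 0.005))[-1]) st <- solve_equilibrium(p, st, l)
  expect_equal(st$force_per_width, 0, tolerance = 1e-8 * p$k_s)
  expect_equal(st$lambda_tr, 1, tolerance = 1e-8)
  expect_equal(st$dissipation, 0)
})

test_that("discrete energy bookkeeping: work = stored + nonnegative dissipation", {
  cur <- simulate_monotonic(five_beam_params(),
                            seq(1, 1.5, length.out = 101))
  e <- attr(cur, "energy")
  gap <- diff(e$work) - diff(e$stored)
  # dissipation per increment is the work-storage gap and never negative
  expect_true(all(gap > -1e-8))
  expect_lt(max(abs(diff(e$dissipation) - gap)), 1e-4)
  expect_true(all(diff(e$dissipation) >= 0))
  # elastic unit dissipates nothing
  cure <- simulate_monotonic(five_beam_params(f_slip = Inf),
                             seq(1, 1.4, length.out = 41))
  expect_equal(max(attr(cure, "energy")$dissipation), 0)
})

test_that("response is invariant to halving the increment size", {
  p <- five_beam_params()
  g <- seq(1, 1.5, length.out = 26)
  c1 <- simulate_monotonic(p, g, dmax = 0.01)
  c2 <- simulate_monotonic(p, g, dmax = 0.0025)
  expect_equal(c1$force_per_width, c2$force_per_width,
               tolerance = 1e-6)
  expect_equal(c1$lambda_tr, c2$lambda_tr, tolerance = 1e-6)
})

test_that("mirror symmetry: transverse span stays positive and closes the diamond", {
  p <- five_beam_params()
  st <- build_geometry(p$theta, p$scale)
  for (l in seq(1, 1.4, by = 0.01)[-1]) st <- solve_equilibrium(p, st, l)
  expect_gt(st$y, 0)
  # the diagonal length equals the beam + connector elongation budget
  L <- sqrt(st$x^2 + st$y^2)
  comp <- st$L0 / p$k_s + 1 / p$k_c
  expect_equal(L - st$L0, st$f_diag * comp + st$slip[1], tolerance = 1e-9)
  expect_equal(length(unique(st$slip)), 1)  # four identical connectors
})

test_that("force scale invariance: scaling all force-like parameters rescales forces only", {
  g <- seq(1, 1.4, length.out = 41)
  p1 <- five_beam_params()
  c1 <- simulate_monotonic(p1, g)
  p2 <- five_beam_params(k_s = p1$k_s * 3, bend_Pcr = p1$bend_Pcr * 3,
                         k_c = p1$k_c * 3, f_slip = p1$f_slip * 3,
                         H = p1$H * 3)
  c2 <- simulate_monotonic(p2, g)
  expect_equal(c2$force_per_width, 3 * c1$force_per_width, tolerance = 1e-7)
  expect_equal(c2$lambda_tr, c1$lambda_tr, tolerance = 1e-9)
})

test_that("a rigid transverse beam suppresses the Poisson peak", {
  g <- seq(1, 1.5, length.out = 101)
  soft <- simulate_monotonic(five_beam_params(), g)
  rigid <- simulate_monotonic(five_beam_params(bend_Pcr = 1e6, f_slip = Inf), g)
  expect_lt(max(rigid$nu_inc), 0.7 * max(soft$nu_inc))
})

test_that("cyclic loading with slip accumulates residual stretch monotonically", {
  p <- five_beam_params()
  cy <- simulate_cyclic(p, c(1.15, 1.3, 1.45))
  rec <- cy$recovery
  expect_true(all(diff(rec$residual_stretch) >= -1e-9))
  tab <- residual_vs_force(rec)
  expect_true(all(diff(tab$residual_stretch) >= -1e-9))
  # elastic unit recovers fully in every cycle
  rec0 <- simulate_cyclic(five_beam_params(f_slip = Inf), c(1.1, 1.2))$recovery
  expect_equal(rec0$recovery_percent, c(100, 100), tolerance = 1e-3)
})

test_that("invalid parameters are rejected", {
  expect_error(five_beam_params(k_s = -1), class = "wallmech_invalid_input")
  expect_error(five_beam_params(theta = 0), class = "wallmech_invalid_input")
  expect_error(five_beam_params(f_slip = 0), class = "wallmech_invalid_input")
  expect_error(five_beam_params(H = -2), class = "wallmech_invalid_input")
})
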