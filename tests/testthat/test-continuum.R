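test_that("plane-stress uniaxial solution at unit stretch is stress free", {
  m <- hyperelastic_material("neo-hookean", mu = 5 / 13, K = 5 / 6)
  s <- plane_stress_uniaxial(m, 1)
  expect_equal(s$lambda_tr, 1)
  expect_equal(s$force_per_width, 0)
})

test_that("normalized neo-Hookean plate has nu = 0.3 and unit initial modulus", {
  m <- hyperelastic_material("neo-hookean", mu = 5 / 13, K = 5 / 6)
  expect_equal(m$E0, 1, tolerance = 1e-12)
  expect_equal(m$nu0, 0.3, tolerance = 1e-12)
  s <- plane_stress_uniaxial(m, 1.001)
  expect_equal(-log(s$lambda_tr) / log(1.001), 0.3, tolerance = 1e-3)
  s2 <- plane_stress_uniaxial(m, c(1.0005, 1.0015))
  slope <- diff(s2$force_per_width) / 0.001
  expect_equal(slope, 1, tolerance = 1e-2)
})

test_that("incompressible limit matches the closed-form neo-Hookean bar", {
  m <- hyperelastic_material("neo-hookean", mu = 1, K = 1e4)
  s <- plane_stress_uniaxial(m, 1.3)
  expect_equal(s$force_per_width, 1 * (1.3 - 1.3^-2), tolerance = 0.005)
  expect_equal(s$lambda_tr, 1.3^-0.5, tolerance = 0.005)
})

test_that("small-strain moduli of implemented materials match their (E, nu)", {
  for (nu in c(0.2, 0.3, 0.45)) {
    E <- 1
    mu <- E / (2 * (1 + nu)); K <- E / (3 * (1 - 2 * nu))
    m <- hyperelastic_material("neo-hookean", mu = mu, K = K)
    eps <- 5e-4
    s <- plane_stress_uniaxial(m, 1 + eps)
    expect_equal(-log(s$lambda_tr) / log(1 + eps), nu, tolerance = 1e-3)
    expect_equal(s$force_per_width / eps, E, tolerance = 2e-3)
  }
})

test_that("Yeoh stiffening raises the late tangent stiffness", {
  m <- hyperelastic_material("yeoh", C10 = 0.2, C20 = 0.3, C30 = 0.4,
                             D1 = 0.5)
  cur <- uniaxial_curve(m, seq(1, 1.5, length.out = 101))
  k <- function(x) stats::approx(cur$lambda, cur$tangent_stiffness, x)$y
  expect_gt(k(1.4), k(1.05))
  expect_equal(cur$force_per_width[1], 0)
})

test_that("plate energy balances the work of the force-stretch curve", {
  m <- hyperelastic_material("neo-hookean", mu = 5 / 13, K = 5 / 6)
  g <- seq(1, 1.4, length.out = 201)
  cur <- plane_stress_uniaxial(m, g)
  work <- sum(diff(g) * (cur$force_per_width[-1] + cur$force_per_width[-201]) / 2)
  # strain energy density * reference volume per unit area (thickness 1)
  W <- function(l1, l2, l3) {
    J <- l1 * l2 * l3; I1 <- l1^2 + l2^2 + l3^2
    m$C10 * (I1 * J^(-2 / 3) - 3) + (1 / m$D1) * (J - 1)^2
  }
  n <- length(g)
  stored <- W(g[n], cur$lambda_tr[n], cur$lambda_th[n])
  expect_equal(work, stored, tolerance = 1e-3)
})

test_that("neo-Hookean plate has no three-regime structure over the tested range", {
  m <- hyperelastic_material("neo-hookean", mu = 5 / 13, K = 5 / 6)
  cur <- uniaxial_curve(m, seq(1, 1.5, length.out = 101))
  k <- cur$tangent_stiffness
  # smooth, no interior extrema of the tangent stiffness
  expect_true(all(diff(sign(diff(k))) == 0))
  expect_error(extract_summary(as_derived_curves(cur)),
               class = "wallmech_no_plateau")
})

test_that("inflation of a linear-elastic sphere meets its closed-form limit point", {
  sp <- shell_spec("sphere", radius = 1e-3, wall_thickness = 1e-6,
                   material = list(E = 1e6, nu = 0.3))
  inf <- inflate_shell(sp, c(0, 100, 200))
  expect_equal(inf$lambda[1], 1)
  lim <- attr(inf, "limit_point")
  # p ~ (lambda-1)/lambda^3 peaks at lambda = 3/2
  expect_equal(lim$lambda, 1.5, tolerance = 1e-3)
  p_max_closed <- 2 * 1e6 * 1e-6 * 0.5 / ((1 - 0.3) * 1e-3 * 1.5^3)
  expect_equal(lim$pressure, p_max_closed, tolerance = 1e-3)
  # beyond the limit pressure the curve is truncated and flagged
  inf2 <- inflate_shell(sp, c(0, lim$pressure * 0.9, lim$pressure * 1.1))
  expect_true(attr(inf2, "truncated"))
  expect_equal(nrow(inf2), 2)
})

test_that("a strain-stiffening wall resists inflation more than a soft linear wall", {
  kp_stiff <- function(l) 12 + 58 * wallmech:::smoothstep((l - 1.1) / 0.15)
  kp_soft <- function(l) rep(12, length(l))
  s_st <- shell_spec("sphere", 1e-3, 1e-6, material = list(k_profile = kp_stiff))
  s_so <- shell_spec("sphere", 1e-3, 1e-6, material = list(k_profile = kp_soft))
  pg <- seq(0, 1.5e4, length.out = 40)
  i_st <- inflate_shell(s_st, pg)
  i_so <- inflate_shell(s_so, pg)
  d_st <- diff(utils::tail(i_st$lambda, 2)) / diff(utils::tail(i_st$pressure, 2))
  d_so <- diff(utils::tail(i_so$lambda, 2)) / diff(utils::tail(i_so$pressure, 2))
  expect_lt(d_st, d_so)
})

test_that("pressurized cylinder: bar limit, Poisson stiffening, thickness scaling", {
  mk <- function(nu, p, t = 1e-6) {
    shell_spec("cylinder", 1e-3, t, material = list(E = 1e6, nu = nu),
               pressure = p)
  }
  Fg <- c(0, 1e-4, 2e-4)
  k0 <- attr(cylinder_axial_response(mk(0.3, 0), Fg), "tangent_stiffness")[1]
  expect_equal(k0, 2 * pi * 1e-3 * 1e-6 * 1e6, tolerance = 1e-3)
  k_hi <- attr(cylinder_axial_response(mk(0.45, 20), Fg), "tangent_stiffness")[2]
  k_lo <- attr(cylinder_axial_response(mk(0.0, 20), Fg), "tangent_stiffness")[2]
  expect_gt(k_hi, k_lo)
  k2t <- attr(cylinder_axial_response(mk(0.3, 0, t = 2e-6), Fg),
              "tangent_stiffness")[1]
  expect_equal(k2t / k0, 2, tolerance = 1e-3)
})

test_that("material and shell constructors validate their inputs", {
  expect_error(hyperelastic_material("neo-hookean"),
               class = "wallmech_invalid_input")
  expect_error(hyperelastic_material("neo-hookean", mu = 1, K = 1,
                                     C10 = 1, D1 = 1),
               class = "wallmech_invalid_input")
  m <- hyperelastic_material("neo-hookean", C10 = 0.5, D1 = 2)
  expect_equal(m$mu, 1); expect_equal(m$K, 1)
  expect_warning(shell_spec("sphere", 1e-3, 2e-4,
                            material = list(E = 1, nu = 0.3)),
                 "thin-wall")
})
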