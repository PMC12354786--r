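#' Hyperelastic wall material (neo-Hookean or Yeoh)
#'
#' Compressible isotropic hyperelastic material in the deviatoric /
#' volumetric split convention: the strain energy is
#' \deqn{W = \sum_i C_{i0} (\bar I_1 - 3)^i + (1/D_1)(J - 1)^2}
#' with \eqn{\bar I_1 = J^{-2/3} I_1}. For the neo-Hookean case only
#' \eqn{C_{10} = \mu/2} and \eqn{D_1 = 2/K} are active, so published
#' constants in that convention carry over unchanged. Either
#' (`mu`, `K`) or (`C10`, `D1`) may be given for neo-Hookean; the other
#' pair is derived. The small-strain Young's modulus and Poisson's ratio
#' follow the classical isotropic relations
#' \eqn{E = 9K\mu/(3K+\mu)}, \eqn{\nu = (3K-2\mu)/(2(3K+\mu))}.
#'
#' @param model `"neo-hookean"` or `"yeoh"`.
#' @param mu,K shear and bulk modulus (normalized units).
#' @param C10,C20,C30 Yeoh deviatoric constants.
#' @param D1 volumetric constant.
#' @param thickness_ref reference plate thickness (meters).
#' @return An object of class `hyperelastic_material`.
#' @export
hyperelastic_material <- function(model = c("neo-hookean", "yeoh"),
                                  mu = NULL, K = NULL,
                                  C10 = NULL, C20 = 0, C30 = 0, D1 = NULL,
                                  thickness_ref = 1) {
  model <- match.arg(model)
  if (model == "neo-hookean") {
    if (!is.null(mu) && !is.null(K)) {
      if (!is.null(C10) || !is.null(D1)) {
        stop_wallmech("wallmech_invalid_input",
                      "give either (mu, K) or (C10, D1), not both")
      }
      C10 <- mu / 2; D1 <- 2 / K
    } else if (!is.null(C10) && !is.null(D1)) {
      mu <- 2 * C10; K <- 2 / D1
    } else {
      stop_wallmech("wallmech_invalid_input",
                    "neo-Hookean needs (mu, K) or (C10, D1)")
    }
    C20 <- 0; C30 <- 0
  } else {
    if (is.null(C10) || is.null(D1)) {
      stop_wallmech("wallmech_invalid_input", "Yeoh needs C10 and D1")
    }
    mu <- 2 * C10; K <- 2 / D1
  }
  if (mu <= 0 || K <= 0 || thickness_ref <= 0) {
    stop_wallmech("wallmech_invalid_input",
                  "moduli and thickness must be positive")
  }
  structure(list(model = model, mu = mu, K = K,
                 C10 = C10, C20 = C20, C30 = C30, D1 = D1,
                 thickness_ref = thickness_ref,
                 E0 = 9 * K * mu / (3 * K + mu),
                 nu0 = (3 * K - 2 * mu) / (2 * (3 * K + mu))),
            class = "hyperelastic_material")
}

# Principal nominal (first Piola) stresses dW/dlambda_i at principal
# stretches (l1, l2, l3).
principal_nominal_stress <- function(mat, l1, l2, l3) {
  J <- l1 * l2 * l3
  I1 <- l1^2 + l2^2 + l3^2
  Ib <- I1 * J^(-2 / 3)
  x <- Ib - 3
  dW_dIb <- mat$C10 + 2 * mat$C20 * x + 3 * mat$C30 * x^2
  dW_dJ <- (2 / mat$D1) * (J - 1)
  l <- c(l1, l2, l3)
  dIb_dl <- 2 * l * J^(-2 / 3) - (2 / 3) * I1 * J^(-2 / 3) / l
  dJ_dl <- J / l
  dW_dIb * dIb_dl + dW_dJ * dJ_dl
}

#' Plane-stress uniaxial solution of a hyperelastic plate
#'
#' Solves for the transverse and through-thickness stretches such that
#' the corresponding stresses vanish (for an isotropic material under
#' uniaxial tension the two coincide), and returns the transverse
#' stretch and the nominal membrane force: axial first Piola stress
#' times reference thickness.
#'
#' @param mat a `hyperelastic_material`.
#' @param lambda_ax axial stretch(es), positive.
#' @return Data frame with `lambda_ax`, `lambda_tr`, `lambda_th`,
#'   `force_per_width`.
#' @export
plane_stress_uniaxial <- function(mat, lambda_ax) {
  one <- function(la) {
    if (la <= 0) stop_wallmech("wallmech_invalid_input", "stretch must be > 0")
    if (abs(la - 1) < 1e-14) {
      return(c(lt = 1, f = 0))
    }
    g <- function(lt) principal_nominal_stress(mat, la, lt, lt)[2]
    lo <- 0.05; hi <- max(2, la)
    if (g(lo) * g(hi) > 0) {
      stop_wallmech("wallmech_solver",
                    sprintf("transverse stress not bracketed at lambda = %g", la))
    }
    r <- stats::uniroot(g, c(lo, hi), tol = 1e-14)
    P <- principal_nominal_stress(mat, la, r$root, r$root)
    c(lt = r$root, f = P[1] * mat$thickness_ref)
  }
  res <- vapply(lambda_ax, one, c(lt = 0, f = 0))
  data.frame(lambda_ax = lambda_ax, lambda_tr = res["lt", ],
             lambda_th = res["lt", ], force_per_width = res["f", ])
}

#' Uniaxial model curve of a hyperelastic plate
#'
#' Maps [plane_stress_uniaxial()] over a stretch grid and derives the
#' tangent stiffness and incremental Poisson's ratio, so the homogeneous
#' plate reference can be compared with experimental and network-model
#' curves. The neo-Hookean plate is smooth and convex-then-affine over
#' the tested range: it has no three-regime structure, which is the point
#' of the comparison.
#'
#' @param mat a `hyperelastic_material`.
#' @param lambda_grid stretch grid starting at 1.
#' @return A `model_curve` data frame.
#' @export
uniaxial_curve <- function(mat, lambda_grid = seq(1, 1.5, length.out = 201)) {
  if (abs(lambda_grid[1] - 1) > 1e-12 || any(diff(lambda_grid) <= 0)) {
    stop_wallmech("wallmech_invalid_input",
                  "lambda_grid must start at 1 and be strictly increasing")
  }
  sol <- plane_stress_uniaxial(mat, lambda_grid)
  k <- central_diff(lambda_grid, sol$force_per_width)
  nu <- -central_diff(lambda_grid, log(sol$lambda_tr)) * lambda_grid
  structure(
    data.frame(lambda = lambda_grid, force_per_width = sol$force_per_width,
               lambda_tr = sol$lambda_tr, tangent_stiffness = k, nu_inc = nu),
    class = c("model_curve", "data.frame"), material = mat
  )
}

#' Thin pressurized shell specification
#'
#' @param geometry `"sphere"` or `"cylinder"`.
#' @param radius reference radius (meters).
#' @param wall_thickness wall thickness (meters); a thin-wall ratio above
#'   0.1 triggers a warning.
#' @param material wall material: a `hyperelastic_material`, a linear
#'   wall `list(E =, nu =)` (Pa), or a tangent-stiffness profile
#'   `list(k_profile = function(lambda))` in N/m.
#' @param pressure internal pressure (Pa), used by the cylinder response.
#' @return An object of class `shell_spec`.
#' @export
shell_spec <- function(geometry = c("sphere", "cylinder"), radius,
                       wall_thickness, material, pressure = 0) {
  geometry <- match.arg(geometry)
  if (radius <= 0 || wall_thickness <= 0) {
    stop_wallmech("wallmech_invalid_input", "radius and thickness must be > 0")
  }
  if (wall_thickness / radius >= 0.1) {
    warning("thin-wall assumption questionable: t/r = ",
            signif(wall_thickness / radius, 3), call. = FALSE)
  }
  structure(list(geometry = geometry, radius = radius,
                 wall_thickness = wall_thickness, material = material,
                 pressure = pressure),
            class = "shell_spec")
}

# Pressure sustained by the shell at hoop stretch lambda (current
# geometry Laplace relation). c_geo = 2 for sphere, 1 for cylinder hoop.
shell_pressure_of_stretch <- function(spec, lambda) {
  c_geo <- if (spec$geometry == "sphere") 2 else 1
  m <- spec$material
  r0 <- spec$radius; t0 <- spec$wall_thickness
  if (inherits(m, "hyperelastic_material")) {
    # equibiaxial plane stress: lambda1 = lambda2 = lambda, solve lambda3
    sapply(lambda, function(l) {
      if (abs(l - 1) < 1e-14) return(0)
      g <- function(l3) principal_nominal_stress(m, l, l, l3)[3]
      r <- stats::uniroot(g, c(0.02, 2), tol = 1e-14)
      P1 <- principal_nominal_stress(m, l, r$root, r$root)[1]
      # Cauchy membrane tension: sigma1 * current thickness = P1 * t0 / l
      c_geo * P1 * t0 / (l^2 * r0)
    })
  } else if (!is.null(m$k_profile)) {
    # membrane-tension wall: T(lambda) = integral of the stiffness profile
    sapply(lambda, function(l) {
      if (abs(l - 1) < 1e-14) return(0)
      Tm <- stats::integrate(m$k_profile, 1, l, rel.tol = 1e-10)$value
      c_geo * Tm / (l * r0)
    })
  } else {
    # linear wall stress with incompressible thinning t = t0 / lambda^2
    c_geo * m$E * t0 * (lambda - 1) / ((1 - m$nu) * r0 * lambda^3)
  }
}

#' Quasi-static inflation of a thin shell
#'
#' Solves the membrane equilibrium (Laplace relation with current
#' geometry) for the hoop stretch at each pressure. A linear-elastic wall
#' admits a limit point -- the pressure maximum beyond which no nearby
#' equilibrium exists and slight pressure increases produce runaway
#' stretch; a wall whose tangent stiffness ramps up with stretch pushes
#' that instability away, which is the mechanical argument for why
#' strain-stiffening protects turgid cells. If the grid exceeds the limit
#' pressure, the curve is returned up to the limit point and flagged.
#'
#' @param spec a `shell_spec`.
#' @param pressure_grid nondecreasing pressures starting at >= 0.
#' @param lambda_hi upper bound of the stretch search range.
#' @return Data frame `pressure`, `lambda`; attributes `limit_point`
#'   (list with `pressure`, `lambda`, or `NULL`) and `truncated`.
#' @export
inflate_shell <- function(spec, pressure_grid, lambda_hi = 3) {
  if (any(pressure_grid < 0) || any(diff(pressure_grid) < 0)) {
    stop_wallmech("wallmech_invalid_input",
                  "pressures must be nonnegative and nondecreasing")
  }
  lam_dense <- seq(1, lambda_hi, length.out = 2000)
  p_dense <- shell_pressure_of_stretch(spec, lam_dense)
  i_max <- which.max(p_dense)
  limit <- NULL
  if (i_max < length(lam_dense)) {
    limit <- list(pressure = p_dense[i_max], lambda = lam_dense[i_max])
  }
  p_cap <- p_dense[i_max]
  ok <- pressure_grid <= p_cap + 1e-12 * max(1, p_cap)
  lam <- sapply(pressure_grid[ok], function(p) {
    if (p <= 0) return(1)
    g <- function(l) shell_pressure_of_stretch(spec, l) - p
    stats::uniroot(g, c(1, lam_dense[i_max]), tol = 1e-12,
                   extendInt = "no")$root
  })
  structure(data.frame(pressure = pressure_grid[ok], lambda = lam),
            limit_point = limit, truncated = any(!ok))
}

#' Axial response of a closed pressurized thin cylinder
#'
#' Superposes an axial force on a closed thin-walled cylinder held at
#' constant internal pressure. The wall is linear elastic with
#' first-order kinematics (wall stresses evaluated on the reference
#' geometry), while the pressure cap force acts on the current radius
#' \eqn{p \pi r^2} -- the geometric coupling through which the Poisson
#' effect enters. Axial stretching contracts the radius, so the cap
#' force drops as the cylinder extends and a larger wall Poisson's ratio
#' makes the pressurized cell stiffer axially (effective stiffness
#' \eqn{\approx 2\pi r_0 t E (1 + \nu\, p r_0/(tE))}); at zero pressure
#' the response reduces to the standard bar stiffness
#' \eqn{2\pi r_0 t E}. The formulation is deliberately minimal: it fixes
#' the monotone-in-\eqn{\nu} trend, not a particular finite-deformation
#' theory.
#'
#' @param spec a `shell_spec` with `geometry = "cylinder"` and a linear
#'   wall material `list(E =, nu =)`.
#' @param axial_force_grid axial forces (N).
#' @return Data frame `force`, `lambda_ax`, `lambda_hoop`, plus the
#'   effective axial tangent stiffness as attribute
#'   `tangent_stiffness` (dF/dlambda at the grid, central differences).
#' @export
cylinder_axial_response <- function(spec, axial_force_grid) {
  stopifnot(spec$geometry == "cylinder")
  m <- spec$material
  if (inherits(m, "hyperelastic_material") || is.null(m$E)) {
    stop_wallmech("wallmech_invalid_input",
                  "cylinder response expects a linear wall list(E, nu)")
  }
  r0 <- spec$radius; t <- spec$wall_thickness; p <- spec$pressure
  sth <- p * r0 / t  # hoop stress, reference Laplace relation
  one <- function(F) {
    ez <- 0; eth <- 0
    for (i in 1:200) {
      r <- r0 * (1 + eth)  # current radius for the cap force only
      sz <- (p * pi * r^2 + F) / (2 * pi * r0 * t)
      ez_new <- (sz - m$nu * sth) / m$E
      eth_new <- (sth - m$nu * sz) / m$E
      if (max(abs(ez_new - ez), abs(eth_new - eth)) < 1e-14) {
        ez <- ez_new; eth <- eth_new
        break
      }
      ez <- ez_new; eth <- eth_new
    }
    c(ez = ez, eth = eth)
  }
  res <- vapply(axial_force_grid, one, c(ez = 0, eth = 0))
  lam_z <- 1 + res["ez", ]
  out <- data.frame(force = axial_force_grid, lambda_ax = lam_z,
                    lambda_hoop = 1 + res["eth", ])
  if (length(axial_force_grid) >= 3) {
    attr(out, "tangent_stiffness") <- 1 / central_diff(axial_force_grid, lam_z)
  } else if (length(axial_force_grid) == 2) {
    attr(out, "tangent_stiffness") <-
      rep(diff(axial_force_grid) / diff(lam_z), 2)
  }
  out
}
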