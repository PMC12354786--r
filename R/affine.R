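#' Parameters of the affine isotropic fiber network
#'
#' In the affine network model every fiber stretches and rotates exactly
#' with the macroscopic deformation gradient. Fibers are distributed
#' uniformly in orientation over \eqn{[0, \pi)} and carry a nominal
#' force set by `fiber_law`: Green-strain (St. Venant-Kirchhoff) fibers,
#' \eqn{t_f = \kappa_f \lambda_f (\lambda_f^2 - 1)/2} (default), or
#' fibers linear in stretch, \eqn{t_f = \kappa_f (\lambda_f - 1)}. Both
#' have tangent \eqn{\kappa_f} at \eqn{\lambda_f = 1}, so the
#' small-strain network response (Poisson's ratio 1/3) is the same. The
#' uniaxial membrane response follows by orientation averaging and by
#' enforcing zero transverse membrane force. This is the null mechanism
#' against which the five-beam unit is contrasted: it produces only
#' two-regime stiffening and a monotonically increasing incremental
#' Poisson's ratio.
#'
#' @param kappa_f fiber stiffness density (N/m per unit fiber stretch).
#' @param n_orient number of orientation quadrature nodes (midpoint rule
#'   on \eqn{[0, \pi)}); at least 8 and even.
#' @param tension_only if `TRUE`, fibers with stretch below 1 carry no
#'   force.
#' @param matrix_k optional isotropic linear background stiffness (N/m).
#' @param fiber_law `"green"` or `"linear"` fiber force law.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(kappa_f = 30, n_orient = 360,
                          tension_only = FALSE, matrix_k = 0,
                          fiber_law = c("green", "linear")) {
  fiber_law <- match.arg(fiber_law)
  if (kappa_f <= 0) stop_wallmech("wallmech_invalid_input", "kappa_f must be > 0")
  if (n_orient < 8 || n_orient %% 2 != 0) {
    stop_wallmech("wallmech_invalid_input", "n_orient must be >= 8 and even")
  }
  structure(list(kappa_f = kappa_f, n_orient = n_orient,
                 tension_only = tension_only, matrix_k = matrix_k,
                 fiber_law = fiber_law),
            class = "affine_params")
}

#' Stretch of an affinely convected fiber
#'
#' Under the principal in-plane deformation
#' \eqn{F = diag(\lambda_{ax}, \lambda_{tr})}, a fiber at initial
#' orientation \eqn{\theta_0} to the loading axis attains stretch
#' \eqn{\lambda_f = \sqrt{\lambda_{ax}^2\cos^2\theta_0 +
#' \lambda_{tr}^2\sin^2\theta_0}}.
#'
#' @param theta0 initial orientation angle in radians.
#' @param lambda_ax,lambda_tr principal stretches, positive.
#' @return Fiber stretch (vectorized over any argument).
#' @export
fiber_stretch <- function(theta0, lambda_ax, lambda_tr) {
  if (any(lambda_ax <= 0) || any(lambda_tr <= 0)) {
    stop_wallmech("wallmech_invalid_input", "stretches must be positive")
  }
  sqrt(lambda_ax^2 * cos(theta0)^2 + lambda_tr^2 * sin(theta0)^2)
}

#' Membrane forces of the affine network at a given deformation
#'
#' Orientation-averages the fiber nominal forces projected onto the two
#' in-plane axes (midpoint quadrature over the uniform orientation
#' distribution), optionally zeroing compressed fibers and adding a
#' linear isotropic matrix term.
#'
#' @param params an `affine_params`.
#' @param lambda_ax,lambda_tr principal stretches.
#' @return Named numeric vector `c(f_ax, f_tr)` of nominal membrane
#'   forces (N/m).
#' @export
membrane_force <- function(params, lambda_ax, lambda_tr) {
  th <- (seq_len(params$n_orient) - 0.5) * pi / params$n_orient
  c2 <- cos(th)^2
  s2 <- sin(th)^2
  lf <- sqrt(lambda_ax^2 * c2 + lambda_tr^2 * s2)
  tf <- if ((params$fiber_law %||% "linear") == "green") {
    params$kappa_f * lf * (lf^2 - 1) / 2
  } else {
    params$kappa_f * (lf - 1)
  }
  if (params$tension_only) tf[lf < 1] <- 0
  f_ax <- mean(tf * lambda_ax * c2 / lf) + params$matrix_k * (lambda_ax - 1)
  f_tr <- mean(tf * lambda_tr * s2 / lf) + params$matrix_k * (lambda_tr - 1)
  c(f_ax = f_ax, f_tr = f_tr)
}

#' Uniaxial response of the affine isotropic network
#'
#' For each axial stretch on the grid, the transverse stretch is solved
#' from the zero transverse membrane force condition by bracketed root
#' finding, and the force, tangent stiffness (central differences of the
#' model curve) and incremental Poisson's ratio are tabulated.
#'
#' @param params an `affine_params`.
#' @param lambda_grid axial stretch grid starting at 1, strictly
#'   increasing.
#' @return A data frame of class `model_curve` with columns `lambda`,
#'   `force_per_width`, `lambda_tr`, `tangent_stiffness`, `nu_inc`.
#' @export
uniaxial_response <- function(params, lambda_grid) {
  if (abs(lambda_grid[1] - 1) > 1e-12 || any(diff(lambda_grid) <= 0)) {
    stop_wallmech("wallmech_invalid_input",
                  "lambda_grid must start at 1 and be strictly increasing")
  }
  n <- length(lambda_grid)
  lam_tr <- numeric(n)
  f_ax <- numeric(n)
  lam_tr[1] <- 1
  f_ax[1] <- 0
  for (i in seq_len(n)[-1]) {
    la <- lambda_grid[i]
    g <- function(lt) membrane_force(params, la, lt)[["f_tr"]]
    lo <- 0.05
    hi <- 1
    if (g(lo) * g(hi) > 0) {
      stop_wallmech("wallmech_solver",
                    sprintf(paste0("transverse equilibrium not bracketed at ",
                                   "lambda_ax = %.4f (f_tr(%.2f) = %.4g, ",
                                   "f_tr(1) = %.4g)"), la, lo, g(lo), g(hi)))
    }
    r <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
    lam_tr[i] <- r$root
    f_ax[i] <- membrane_force(params, la, lam_tr[i])[["f_ax"]]
  }
  k <- central_diff(lambda_grid, f_ax)
  nu <- -central_diff(lambda_grid, log(lam_tr)) * lambda_grid
  # nu_inc = -dln(tr)/dln(ax) = -(dln(tr)/dlambda) * lambda
  structure(
    data.frame(lambda = lambda_grid, force_per_width = f_ax,
               lambda_tr = lam_tr, tangent_stiffness = k, nu_inc = nu),
    class = c("model_curve", "data.frame"), params = params
  )
}
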