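#' Construct a tensile test curve
#'
#' A tensile test is recorded as a sampled time series of the axial
#' stretch (deformed length over initial length), the transverse stretch
#' (deformed width over initial width) and the force per unit reference
#' width (membrane force, N/m). Stretches are dimensionless; force is
#' normalized by the undeformed sample width.
#'
#' @param time_s sample times in seconds, monotone nondecreasing.
#' @param lambda_ax axial stretch, positive.
#' @param lambda_tr transverse stretch, positive.
#' @param force_per_width membrane force in N/m.
#' @param cycle,phase optional per-sample cycle index and
#'   `"loading"`/`"unloading"` label; supplying both yields a
#'   `cyclic_curve`.
#' @param width_ref optional reference width in meters (metadata).
#' @param label free-text label.
#' @param zeroed if `TRUE`, the first sample is checked to start within
#'   `1e-6` of stretch 1 (freshly zeroed test).
#' @return A data frame of class `tensile_curve` (and `cyclic_curve` when
#'   segment labels are supplied).
#' @export
tensile_curve <- function(time_s, lambda_ax, lambda_tr, force_per_width,
                          cycle = NULL, phase = NULL,
                          width_ref = NA_real_, label = "", zeroed = FALSE) {
  n <- length(time_s)
  if (!all(lengths(list(lambda_ax, lambda_tr, force_per_width)) == n) || n < 4) {
    stop_wallmech("wallmech_invalid_input",
                  "all series must have equal length >= 4")
  }
  if (any(diff(time_s) < 0)) {
    stop_wallmech("wallmech_invalid_input", "time must be nondecreasing")
  }
  if (any(lambda_ax <= 0) || any(lambda_tr <= 0)) {
    stop_wallmech("wallmech_invalid_input", "stretches must be positive")
  }
  if (zeroed && abs(lambda_ax[1] - 1) > 1e-6) {
    stop_wallmech("wallmech_invalid_input",
                  "zeroed test must start at axial stretch 1 (within 1e-6)")
  }
  out <- data.frame(time_s = time_s, lambda_ax = lambda_ax,
                    lambda_tr = lambda_tr, force_per_width = force_per_width)
  cls <- c("tensile_curve", "data.frame")
  if (!is.null(cycle) && !is.null(phase)) {
    phase <- match.arg(phase, c("loading", "unloading"), several.ok = TRUE)
    if (any(diff(cycle) < 0)) {
      stop_wallmech("wallmech_invalid_input",
                    "cycle indices must be nondecreasing")
    }
    out$cycle <- cycle
    out$phase <- phase
    cls <- c("cyclic_curve", cls)
  }
  structure(out, class = cls, width_ref = width_ref, label = label)
}

#' Summary metrics of a three-regime tensile curve
#'
#' Extracts the regime-level scalar metrics from derived tangent curves:
#' the initial stiffness E1 and initial incremental Poisson's ratio nu1
#' as averages over the stretch window 1.02-1.05; the final stiffness E2
#' as the average tangent stiffness from the stretch at which the
#' derivative of the stiffness first approaches zero (after the
#' strain-stiffening rise) up to the maximum stretch minus 0.05; and the
#' peak Poisson's ratio nu2 as the average of the incremental Poisson's
#' ratio in a window of plus/minus 0.05 stretch around its maximum.
#'
#' "Approaches zero" is made operational as
#' \eqn{|dk/d\lambda| <} `plateau_frac` \eqn{\times k_{range}/\lambda_{range}}
#' (a scale-free relative criterion) or a sign change of
#' \eqn{dk/d\lambda} (a local stiffness extremum, where the derivative
#' passes through zero between grid points); the search starts at the end
#' of regime I, reported as the first stretch at or beyond 1.05 where the
#' stiffness exceeds `regime1_factor` times E1 (curves may dip slightly
#' below E1 inside regime I, so the initial window is excluded). For flat
#' stiffness profiles (no stiffening) the plateau search degenerates and
#' the E2 window spans the whole grid.
#'
#' @param derived a `derived_curves` data frame (or any data frame with
#'   columns `lambda`, `tangent_stiffness`, `nu_inc`).
#' @param lambda_max maximum stretch of the test (default: top of the
#'   grid); must exceed 1.1.
#' @param plateau_frac relative threshold for the stiffness-derivative
#'   plateau criterion (default 0.05).
#' @param regime1_factor stiffness multiple of E1 marking the end of
#'   regime I (default 1.2).
#' @return An object of class `mech_summary`: list with `E1`, `E2`,
#'   `nu1`, `nu2`, `regime_bounds` (end of regime I, start of the final
#'   plateau), `lambda_max`, and the peak location `lambda_peak_nu`.
#' @export
extract_summary <- function(derived, lambda_max = NULL,
                            plateau_frac = 0.05, regime1_factor = 1.2) {
  lam <- derived$lambda
  k <- derived$tangent_stiffness
  nu <- derived$nu_inc
  if (is.null(lambda_max)) lambda_max <- max(lam)
  if (lambda_max <= 1.1) {
    stop_wallmech("wallmech_range_too_short",
                  "lambda_max must exceed 1.1 for regime extraction")
  }
  if (min(lam) > 1.02) {
    stop_wallmech("wallmech_invalid_input",
                  "derived curves must cover the initial window from 1.02")
  }

  E1 <- trapz_mean(lam, k, 1.02, 1.05)
  nu1 <- trapz_mean(lam, nu, 1.02, 1.05)

  k_range <- diff(range(k))
  lam_range <- diff(range(lam))
  dk <- central_diff(lam, k)

  flat <- k_range <= 1e-9 * max(abs(k), 1)
  if (flat) {
    lambda_star <- lam[1]
    regime1_end <- lam[1]
  } else {
    thresh <- plateau_frac * k_range / lam_range
    i_rise <- which(k > regime1_factor * E1 & lam >= 1.05)
    regime1_end <- if (length(i_rise)) lam[min(i_rise)] else lam[1]
    sign_flip <- c(FALSE, diff(sign(dk)) != 0)
    cand <- which(lam >= regime1_end & (abs(dk) < thresh | sign_flip))
    if (!length(cand)) {
      stop_wallmech(
        "wallmech_no_plateau",
        sprintf(paste0("stiffness derivative never approaches zero after the",
                       " rise; min |dk/dlambda| = %.4g against threshold %.4g"),
                min(abs(dk[lam >= regime1_end])), thresh),
        min_abs_dk = min(abs(dk[lam >= regime1_end]))
      )
    }
    lambda_star <- lam[min(cand)]
  }
  if (lambda_star >= lambda_max - 0.05) {
    stop_wallmech("wallmech_no_plateau",
                  "final plateau starts inside the excluded end window")
  }
  E2 <- trapz_mean(lam, k, lambda_star, lambda_max - 0.05)

  ip <- which.max(nu)
  lambda_p <- lam[ip]
  nu2 <- trapz_mean(lam, nu,
                    max(min(lam), lambda_p - 0.05),
                    min(max(lam), lambda_p + 0.05))

  structure(
    list(E1 = E1, E2 = E2, nu1 = nu1, nu2 = nu2,
         regime_bounds = c(regime1_end, lambda_star),
         lambda_max = lambda_max, lambda_peak_nu = lambda_p),
    class = "mech_summary"
  )
}

#' @export
print.mech_summary <- function(x, ...) {
  cat("Tensile summary (three-regime extraction)\n")
  cat(sprintf("  E1  = %8.3f N/m   (initial stiffness, stretch 1.02-1.05)\n", x$E1))
  cat(sprintf("  E2  = %8.3f N/m   (final stiffness plateau)\n", x$E2))
  cat(sprintf("  nu1 = %8.3f       (initial incremental Poisson's ratio)\n", x$nu1))
  cat(sprintf("  nu2 = %8.3f       (peak incremental Poisson's ratio at %.3f)\n",
              x$nu2, x$lambda_peak_nu))
  cat(sprintf("  regimes: I ends %.3f, III starts %.3f, max stretch %.3f\n",
              x$regime_bounds[1], x$regime_bounds[2], x$lambda_max))
  invisible(x)
}

#' Treat a model curve as derived curves
#'
#' Model responses already carry their tangent stiffness and incremental
#' Poisson's ratio; this adapter lets [extract_summary()] consume them.
#'
#' @param model_curve data frame with `lambda`, `tangent_stiffness`,
#'   `nu_inc` columns.
#' @return The same data, classed as `derived_curves`.
#' @export
as_derived_curves <- function(model_curve) {
  structure(
    data.frame(lambda = model_curve$lambda,
               force_per_width = model_curve$force_per_width,
               tangent_stiffness = model_curve$tangent_stiffness,
               nu_inc = model_curve$nu_inc),
    class = c("derived_curves", "data.frame")
  )
}
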