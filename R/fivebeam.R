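#' Parameters of the five-beam diamond unit
#'
#' The five-beam unit conceptualizes the cellulose microfibril network of
#' the primary cell wall as a diamond of four stretching beams (AC, AD,
#' BC, BD: the majority of microfibrils, which rotate towards the loading
#' direction and elongate elastically) plus one transverse beam AB (the
#' microfibrils near the transverse direction, which bend under the
#' end-compression imposed by the contracting diamond). Each stretching
#' beam acts in series with a connector: the effective fiber-fiber link
#' (matrix-mediated or direct cellulose-cellulose contact) that deforms
#' elastically and, above a force threshold, slips plastically -- the
#' source of residual stretch after unloading.
#'
#' Model units are arbitrary but consistent: forces are reported per unit
#' out-of-plane width so model curves are dimensionally comparable with
#' experimental membrane forces; absolute magnitudes are deliberately not
#' calibrated to tissue values.
#'
#' @param k_s stretching-beam axial stiffness (model force per unit beam
#'   stretch).
#' @param bend_Pcr critical end-compression force of the transverse beam
#'   (model force); the bending law rises to this level with initial
#'   stiffness `bend_Pcr / (bend_rise_frac * L_AB)` and then hardens.
#' @param bend_harden dimensionless post-critical hardening coefficient
#'   of the bending law.
#' @param bend_harden_lin dimensionless linear hardening coefficient of
#'   the bending law (early, gentle growth of bending resistance).
#' @param bend_wall fraction of the transverse beam length at which the
#'   compacting beam's resistance diverges (arrest of transverse
#'   collapse); 1 means the chord must fully close.
#' @param bend_rise_frac fraction of the transverse beam length over
#'   which the pre-critical branch rises to `bend_Pcr` (sets the initial
#'   bending stiffness).
#' @param bend_knee sharpness exponent of the pre-critical knee; larger
#'   values keep the tangent at its initial value longer before the
#'   post-buckling plateau.
#' @param k_c connector elastic stiffness (model force per unit slip
#'   displacement).
#' @param f_slip connector slip threshold (model force); `Inf` disables
#'   slip (fully elastic unit).
#' @param H connector hardening modulus (model force per unit accumulated
#'   slip).
#' @param theta full angle in degrees between the two stretching beams
#'   meeting at a loading node (0 < theta < 180); 90 is the isotropic
#'   baseline diamond.
#' @param scale reference half-span of the unit (model length).
#' @return An object of class `five_beam_params`.
#' @export
five_beam_params <- function(k_s = 35, bend_Pcr = 1, bend_harden = 13,
                             k_c = 300, f_slip = 2.5, H = 60,
                             theta = 90, scale = 1, bend_harden_lin = 0,
                             bend_wall = 1, bend_rise_frac = 0.15,
                             bend_knee = 2) {
  if (k_s <= 0 || k_c <= 0 || bend_Pcr <= 0 || scale <= 0) {
    stop_wallmech("wallmech_invalid_input", "stiffnesses and scale must be > 0")
  }
  if (!(theta > 0 && theta < 180)) {
    stop_wallmech("wallmech_invalid_input", "theta must lie in (0, 180) degrees")
  }
  if (f_slip <= 0) stop_wallmech("wallmech_invalid_input", "f_slip must be > 0")
  if (H < 0 || bend_harden < 0 || bend_harden_lin < 0) {
    stop_wallmech("wallmech_invalid_input", "hardening moduli must be >= 0")
  }
  if (bend_rise_frac <= 0 || bend_knee < 1) {
    stop_wallmech("wallmech_invalid_input",
                  "bend_rise_frac must be > 0 and bend_knee >= 1")
  }
  if (bend_wall <= 0 || bend_wall > 1) {
    stop_wallmech("wallmech_invalid_input", "bend_wall must lie in (0, 1]")
  }
  structure(list(k_s = k_s, bend_Pcr = bend_Pcr, bend_harden = bend_harden,
                 k_c = k_c, f_slip = f_slip, H = H,
                 theta = theta, scale = scale,
                 bend_harden_lin = bend_harden_lin, bend_wall = bend_wall,
                 bend_rise_frac = bend_rise_frac, bend_knee = bend_knee),
            class = "five_beam_params")
}

#' Initial geometry of the five-beam unit
#'
#' Loading nodes C, D sit on the axial axis at \eqn{\pm}`scale`;
#' transverse nodes A, B sit on the transverse axis at
#' \eqn{\pm scale \tan(\theta/2)}, so the angle ACB between the two
#' stretching beams meeting at C equals `theta`. All four diagonal beams
#' have equal length; the unit starts undeformed.
#'
#' @param theta full angle at a loading node, degrees.
#' @param scale reference half-span.
#' @return A `five_beam_state`: node geometry, stretches, per-connector
#'   slip, internal forces and energy bookkeeping, all zeroed.
#' @export
build_geometry <- function(theta, scale = 1) {
  if (!(theta > 0 && theta < 180)) {
    stop_wallmech("wallmech_invalid_input", "theta must lie in (0, 180) degrees")
  }
  h0 <- scale * tan(theta * pi / 360)
  structure(
    list(x = scale, y = h0, x0 = scale, h0 = h0,
         L0 = sqrt(scale^2 + h0^2),
         lambda_ax = 1, lambda_tr = 1,
         slip = rep(0, 4), slip_acc = 0,
         f_diag = 0, P_bend = 0, force_per_width = 0,
         stored_energy = 0, external_work = 0, dissipation = 0,
         bend_extension_flag = FALSE),
    class = "five_beam_state"
  )
}

#' Rate-independent return map of a connector
#'
#' One-dimensional elastoplastic return mapping for the fiber-fiber
#' connector. Given a trial force (elastic predictor) and the previously
#' accumulated slip, the force is either accepted (elastic step, below
#' the current yield level `f_slip + H * slip_acc`) or returned to the
#' hardening yield surface, with the excess absorbed by plastic slip
#' \eqn{\Delta s = (|f_{trial}| - f_y)/(k + H)}.
#'
#' @param f_trial trial connector force.
#' @param slip_prev previously accumulated signed slip.
#' @param params a `five_beam_params` (uses `f_slip`, `H`).
#' @param k_elastic elastic stiffness of the predictor; defaults to the
#'   connector stiffness `k_c`, while the diamond solver passes the
#'   series beam-connector stiffness.
#' @param slip_acc accumulated slip magnitude; defaults to
#'   `abs(slip_prev)` (exact under unidirectional slip).
#' @return List with `f` (mapped force), `slip` (updated signed slip) and
#'   `slip_acc` (updated accumulated slip).
#' @export
connector_return_map <- function(f_trial, slip_prev, params,
                                 k_elastic = params$k_c,
                                 slip_acc = abs(slip_prev)) {
  fy <- params$f_slip + params$H * slip_acc
  if (!is.finite(fy) || abs(f_trial) <= fy) {
    return(list(f = f_trial, slip = slip_prev, slip_acc = slip_acc))
  }
  ds <- (abs(f_trial) - fy) / (k_elastic + params$H)
  slip_new <- slip_prev + ds * sign(f_trial)
  acc_new <- slip_acc + ds
  f <- sign(f_trial) * (params$f_slip + params$H * acc_new)
  list(f = f, slip = slip_new, slip_acc = acc_new)
}

#' Bending law of the transverse beam
#'
#' Compressive end force carried by beam AB as a function of its end
#' shortening: a compliant pre-critical branch
#' \eqn{P = P_{cr} u (1+u^m)^{-1/m}} with \eqn{u = \delta k_0/P_{cr}}
#' (tangent \eqn{k_0 = } `bend_Pcr / (bend_rise_frac * L_AB)` up to a
#' knee of sharpness `m = bend_knee`, then the post-buckling plateau at
#' `bend_Pcr`), plus a convex hardening term
#' `bend_Pcr * (bend_harden_lin * w + bend_harden * w^2 / (1 - w/bend_wall))`
#' with `w = delta/L_AB`, capturing the growing resistance to further
#' bending as the bent beam compacts (the force diverges as the
#' shortening approaches the `bend_wall` fraction of the beam length, so
#' the transverse collapse is always arrested). The law is continuous, differentiable
#' and monotone nondecreasing, with P(0) = 0. Negative shortening
#' (extension of AB) is treated as straight-beam axial loading with
#' stiffness `k_s` and flagged via attribute.
#'
#' @param shortening end shortening of beam AB (model length).
#' @param params a `five_beam_params`.
#' @param L_AB reference length of beam AB.
#' @return Compressive force (model force), with attribute `extension`
#'   set when the shortening was negative.
#' @export
bending_force <- function(shortening, params, L_AB) {
  Pcr <- params$bend_Pcr
  k0 <- Pcr / (params$bend_rise_frac * L_AB)
  m <- params$bend_knee
  a <- params$bend_wall
  u <- k0 * pmax(shortening, 0) / Pcr
  w <- pmin(pmax(shortening, 0) / L_AB, a * (1 - 1e-12))
  P <- ifelse(
    shortening >= 0,
    Pcr * u * (1 + u^m)^(-1 / m) + Pcr * params$bend_harden_lin * w +
      Pcr * params$bend_harden * w^2 / (1 - w / a),
    params$k_s * shortening / L_AB
  )
  attr(P, "extension") <- any(shortening < 0)
  P
}

# Stored elastic energy of the bending beam at shortening delta
# (pre-critical branch integrated numerically, hardening in closed form).
bending_energy <- function(delta, params, L_AB) {
  Pcr <- params$bend_Pcr
  k0 <- Pcr / (params$bend_rise_frac * L_AB)
  m <- params$bend_knee
  if (delta >= 0) {
    a <- params$bend_wall
    w <- min(delta / L_AB, a * (1 - 1e-12))
    v <- w / a
    knee <- stats::integrate(function(s) {
      u <- k0 * s / Pcr
      Pcr * u * (1 + u^m)^(-1 / m)
    }, 0, delta, rel.tol = 1e-10)$value
    knee + Pcr * params$bend_harden_lin * L_AB * w^2 / 2 +
      Pcr * params$bend_harden * L_AB * a^3 * (-v^2 / 2 - v - log(1 - v))
  } else {
    0.5 * params$k_s * delta^2 / L_AB
  }
}

#' Quasi-static equilibrium of the five-beam unit at a prescribed stretch
#'
#' With the C-D span prescribed by the target axial stretch, solves for
#' the transverse half-span such that the net transverse force on node A
#' vanishes (mirror symmetry makes this the single geometric unknown),
#' with connector forces satisfying the elastoplastic return map from the
#' previous converged state (operator split per increment). Energy
#' bookkeeping (stored energy, external work, dissipation) is updated at
#' the converged step.
#'
#' @param params a `five_beam_params`.
#' @param state_prev previous converged `five_beam_state`.
#' @param lambda_ax_target target axial stretch; should be within a small
#'   increment of the previous stretch (incremental loading).
#' @return The converged `five_beam_state` at the target stretch.
#' @export
solve_equilibrium <- function(params, state_prev, lambda_ax_target) {
  x0 <- state_prev$x0
  h0 <- state_prev$h0
  L0 <- state_prev$L0
  L_AB <- 2 * h0
  comp <- L0 / params$k_s + 1 / params$k_c  # series beam+connector compliance
  k_eff <- 1 / comp
  slip_prev <- state_prev$slip[1]
  acc_prev <- state_prev$slip_acc

  x <- lambda_ax_target * x0

  trial <- function(y) {
    L <- sqrt(x^2 + y^2)
    f_trial <- (L - L0 - slip_prev) * k_eff
    rm <- connector_return_map(f_trial, slip_prev, params,
                               k_elastic = k_eff, slip_acc = acc_prev)
    P <- bending_force(2 * (h0 - y), params, L_AB)
    list(L = L, rm = rm, P = as.numeric(P),
         resid = as.numeric(P) - 2 * rm$f * y / L)
  }

  lo <- 1e-9 * h0
  hi <- 1.5 * h0 + 0.5 * abs(state_prev$y)
  r_lo <- trial(lo)$resid
  r_hi <- trial(hi)$resid
  cuts <- 0
  while (r_lo * r_hi > 0 && cuts < 10) {
    hi <- hi * 2
    r_hi <- trial(hi)$resid
    cuts <- cuts + 1
  }
  if (r_lo * r_hi > 0) {
    stop_wallmech("wallmech_solver",
                  sprintf("transverse equilibrium not bracketed at lambda = %.4f (residuals %.4g, %.4g)",
                          lambda_ax_target, r_lo, r_hi))
  }
  root <- stats::uniroot(function(y) trial(y)$resid, c(lo, hi),
                         tol = 1e-13 * max(1, h0))
  y <- root$root
  sol <- trial(y)
  if (abs(sol$resid) > 1e-10 * params$k_s) {
    # polish with a few bisection refinements if uniroot's tol left residue
    lo2 <- y - 1e-10; hi2 <- y + 1e-10
    root <- stats::uniroot(function(z) trial(z)$resid,
                           lower = max(lo, lo2), upper = min(hi, hi2),
                           tol = .Machine$double.eps^0.9, extendInt = "yes")
    y <- root$root
    sol <- trial(y)
  }

  f <- sol$rm$f
  delta_bend <- 2 * (h0 - y)
  F_ax <- 2 * f * x / sol$L

  stored <- 2 * f^2 * comp + bending_energy(delta_bend, params, L_AB)
  dacc <- sol$rm$slip_acc - acc_prev
  d_inc <- if (dacc > 0) {
    4 * (params$f_slip + params$H * (acc_prev + sol$rm$slip_acc) / 2) * dacc
  } else 0
  w_inc <- (state_prev$force_per_width + F_ax) / 2 *
    (2 * x - 2 * state_prev$x)

  structure(
    list(x = x, y = y, x0 = x0, h0 = h0, L0 = L0,
         lambda_ax = x / x0, lambda_tr = y / h0,
         slip = rep(sol$rm$slip, 4), slip_acc = sol$rm$slip_acc,
         f_diag = f, P_bend = sol$P, force_per_width = F_ax,
         stored_energy = stored,
         external_work = state_prev$external_work + w_inc,
         dissipation = state_prev$dissipation + d_inc,
         bend_extension_flag = delta_bend < 0),
    class = "five_beam_state"
  )
}

# Advance a state to lambda_target using increments no larger than dmax.
fb_advance <- function(params, state, lambda_target, dmax = 0.0025) {
  lam <- state$lambda_ax
  n <- max(1L, ceiling(abs(lambda_target - lam) / dmax))
  for (l in seq(lam, lambda_target, length.out = n + 1)[-1]) {
    state <- solve_equilibrium(params, state, l)
  }
  state
}

#' Monotonic uniaxial response of the five-beam unit
#'
#' Runs the incremental quasi-static simulation over a stretch grid and
#' tabulates force per width, transverse stretch (A-B chord ratio),
#' tangent stiffness and incremental Poisson's ratio. With default
#' parameters the response exhibits the three-regime phenomenology:
#' a soft bending-dominated plateau, a strain-stiffening rise as the
#' stretching beams align and take load, and a stiff final plateau where
#' beam stretch plus connector slip dominate; the incremental Poisson's
#' ratio rises to an interior maximum and then falls.
#'
#' @param params a `five_beam_params`.
#' @param lambda_grid stretch grid starting at 1, strictly increasing.
#' @param dmax maximum internal stretch increment.
#' @return A `model_curve` data frame (`lambda`, `force_per_width`,
#'   `lambda_tr`, `tangent_stiffness`, `nu_inc`), with the per-step
#'   energy audit (`work`, `stored`, `dissipation`) and final state
#'   attached as attributes.
#' @export
simulate_monotonic <- function(params, lambda_grid = seq(1, 1.5, length.out = 201),
                               dmax = 0.0025) {
  if (abs(lambda_grid[1] - 1) > 1e-12 || any(diff(lambda_grid) <= 0)) {
    stop_wallmech("wallmech_invalid_input",
                  "lambda_grid must start at 1 and be strictly increasing")
  }
  state <- build_geometry(params$theta, params$scale)
  n <- length(lambda_grid)
  f <- numeric(n); ltr <- numeric(n)
  work <- numeric(n); stored <- numeric(n); diss <- numeric(n)
  f[1] <- 0; ltr[1] <- 1
  for (i in seq_len(n)[-1]) {
    state <- fb_advance(params, state, lambda_grid[i], dmax = dmax)
    f[i] <- state$force_per_width
    ltr[i] <- state$lambda_tr
    work[i] <- state$external_work
    stored[i] <- state$stored_energy
    diss[i] <- state$dissipation
  }
  k <- central_diff(lambda_grid, f)
  nu <- -central_diff(lambda_grid, log(ltr)) * lambda_grid
  structure(
    data.frame(lambda = lambda_grid, force_per_width = f, lambda_tr = ltr,
               tangent_stiffness = k, nu_inc = nu),
    class = c("model_curve", "data.frame"),
    params = params, final_state = state,
    energy = data.frame(lambda = lambda_grid, work = work,
                        stored = stored, dissipation = diss)
  )
}

#' Incremental cyclic loading of the five-beam unit
#'
#' Loads to each stretch peak in turn and unloads until the axial force
#' crosses zero (located by bisection), mimicking the incremental cyclic
#' tensile protocol. Because connector slip is the only inelastic
#' mechanism, reloading beyond a previous peak rejoins the monotonic
#' envelope; residual stretch at zero force accumulates with the peaks.
#'
#' @param params a `five_beam_params`.
#' @param peak_list increasing stretch peaks, first > 1.
#' @param dlambda recording increment along loading/unloading branches.
#' @return List with `curve` (a labeled `cyclic_curve`; time is the
#'   cumulative stretch path length) and `recovery` (the
#'   [recovery_analysis()] of that curve).
#' @export
simulate_cyclic <- function(params, peak_list, dlambda = 0.0025) {
  if (any(diff(peak_list) <= 0) || peak_list[1] <= 1) {
    stop_wallmech("wallmech_invalid_input",
                  "peaks must be increasing and exceed 1")
  }
  state <- build_geometry(params$theta, params$scale)
  rows <- list(list(t = 0, lam = 1, ltr = 1, f = 0, cycle = 1L,
                    phase = "loading"))
  tcur <- 0

  push <- function(state, cycle, phase) {
    tcur <<- tcur + abs(state$lambda_ax - rows[[length(rows)]]$lam)
    rows[[length(rows) + 1]] <<- list(t = tcur, lam = state$lambda_ax,
                                      ltr = state$lambda_tr,
                                      f = state$force_per_width,
                                      cycle = cycle, phase = phase)
  }

  for (ci in seq_along(peak_list)) {
    peak <- peak_list[ci]
    # loading branch
    lams <- seq(state$lambda_ax, peak,
                by = min(dlambda, peak - state$lambda_ax))
    if (lams[length(lams)] < peak) lams <- c(lams, peak)
    for (l in lams[-1]) {
      state <- solve_equilibrium(params, state, l)
      push(state, ci, "loading")
    }
    # unloading branch: step down until the force changes sign, then bisect
    ftol <- 1e-10 * params$k_s
    repeat {
      l_next <- state$lambda_ax - dlambda
      if (l_next <= 1 - 1e-9) l_next <- 1
      state_hi <- state
      state <- solve_equilibrium(params, state, l_next)
      if (state$force_per_width <= ftol || l_next <= 1) {
        if (state$force_per_width < -ftol) {
          g <- function(l) solve_equilibrium(params, state_hi, l)$force_per_width
          r <- stats::uniroot(g, c(l_next, state_hi$lambda_ax),
                              tol = 1e-12)
          state <- solve_equilibrium(params, state_hi, r$root)
        }
        push(state, ci, "unloading")
        break
      }
      push(state, ci, "unloading")
    }
  }

  df <- do.call(rbind, lapply(rows, as.data.frame))
  curve <- tensile_curve(df$t, df$lam, df$ltr, df$f,
                         cycle = df$cycle, phase = df$phase,
                         label = "five-beam cyclic")
  list(curve = curve, recovery = recovery_analysis(curve),
       final_state = state)
}

#' Parameter sweep of the five-beam unit
#'
#' Re-simulates the monotonic response while varying one parameter and
#' extracts the three-regime summary metrics per value; optionally also
#' runs the cyclic protocol and attaches per-value recovery tables. This
#' is the numerical experiment used to probe how connector resistance
#' (development) and beam angle (microfibril alignment anisotropy) tune
#' the macroscopic stiffnesses and Poisson's ratios.
#'
#' @param base a `five_beam_params` baseline.
#' @param vary name of the field to vary (e.g. `"k_c"`, `"theta"`,
#'   `"f_slip"`, `"bend_Pcr"`).
#' @param values values to assign to that field.
#' @param lambda_grid stretch grid for the monotonic runs.
#' @param peaks optional cyclic peaks; when given, recovery tables are
#'   attached as attribute `recovery` (a list, one per value).
#' @return Data frame with one row per value: `value`, `E1`, `E2`,
#'   `nu1`, `nu2`, `lambda_peak_nu`.
#' @export
parameter_sweep <- function(base, vary, values,
                            lambda_grid = seq(1, 1.5, length.out = 201),
                            peaks = NULL) {
  stopifnot(vary %in% names(base))
  rows <- list(); recs <- list()
  for (i in seq_along(values)) {
    p <- base
    p[[vary]] <- values[i]
    p <- do.call(five_beam_params, unclass(p))
    cur <- simulate_monotonic(p, lambda_grid)
    s <- extract_summary(as_derived_curves(cur))
    rows[[i]] <- data.frame(value = values[i], E1 = s$E1, E2 = s$E2,
                            nu1 = s$nu1, nu2 = s$nu2,
                            lambda_peak_nu = s$lambda_peak_nu)
    if (!is.null(peaks)) recs[[i]] <- simulate_cyclic(p, peaks)$recovery
  }
  out <- do.call(rbind, rows)
  if (!is.null(peaks)) attr(out, "recovery") <- recs
  out
}
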