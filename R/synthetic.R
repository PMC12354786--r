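#' Profile of the synthetic tensile-curve generator
#'
#' The generator emulates the measured phenomenology of stretched leaf
#' epidermal peels so the whole analysis pipeline can be exercised
#' without experimental data: a three-regime tangent stiffness (soft
#' plateau at `E1_gen`, cubic-smoothstep ramp across regime II, stiff
#' plateau at `E2_gen`), a nonmonotonic incremental Poisson's ratio
#' (quartic bump from `nu1_gen` to a peak `nu2_gen` at `nu_peak_at`,
#' compactly supported so the initial window is untouched), a recovery
#' schedule dropping from `recovery_initial` to `recovery_floor` across
#' the ramp, and additive Gaussian measurement noise on force and
#' transverse stretch (axial stretch is the controlled variable). The
#' plateau stiffnesses default to the measured tissue values of about
#' 12 and 70 N/m; the regime boundaries are generator conventions.
#'
#' @param E1_gen,E2_gen initial and final tangent stiffness (N/m).
#' @param ramp_start,ramp_end stretch bounds of regime II.
#' @param nu1_gen,nu2_gen initial and peak incremental Poisson's ratio.
#' @param nu_peak_at stretch at the Poisson-ratio peak.
#' @param nu_width half-width of the compact Poisson-ratio bump.
#' @param recovery_initial,recovery_floor recovery percentages early in
#'   loading and at the late-cycle plateau.
#' @param noise_sd_force force noise s.d. (N/m).
#' @param noise_sd_stretch transverse-stretch noise s.d.
#' @param n_points samples per generated curve.
#' @param lambda_max final stretch of the monotonic ramp.
#' @param seed integer seed; `NULL` leaves the RNG stream alone.
#' @return An object of class `generator_profile`.
#' @export
generator_profile <- function(E1_gen = 12, E2_gen = 70,
                              ramp_start = 1.10, ramp_end = 1.25,
                              nu1_gen = 0.3, nu2_gen = 1.1,
                              nu_peak_at = 1.20, nu_width = 0.12,
                              recovery_initial = 85, recovery_floor = 40,
                              noise_sd_force = 0.05,
                              noise_sd_stretch = 0.001,
                              n_points = 500, lambda_max = 1.5,
                              seed = NULL) {
  if (!(1 < ramp_start && ramp_start < ramp_end)) {
    stop_wallmech("wallmech_invalid_input", "need 1 < ramp_start < ramp_end")
  }
  if (!(E2_gen >= E1_gen && E1_gen > 0)) {
    stop_wallmech("wallmech_invalid_input", "need E2_gen >= E1_gen > 0")
  }
  if (!(0 <= recovery_floor && recovery_floor <= recovery_initial &&
        recovery_initial <= 100)) {
    stop_wallmech("wallmech_invalid_input",
                  "need 0 <= recovery_floor <= recovery_initial <= 100")
  }
  structure(
    list(E1_gen = E1_gen, E2_gen = E2_gen,
         ramp_start = ramp_start, ramp_end = ramp_end,
         nu1_gen = nu1_gen, nu2_gen = nu2_gen,
         nu_peak_at = nu_peak_at, nu_width = nu_width,
         recovery_initial = recovery_initial,
         recovery_floor = recovery_floor,
         noise_sd_force = noise_sd_force,
         noise_sd_stretch = noise_sd_stretch,
         n_points = n_points, lambda_max = lambda_max, seed = seed),
    class = "generator_profile"
  )
}

# True tangent stiffness profile k(lambda).
gen_stiffness <- function(profile, lambda) {
  u <- (lambda - profile$ramp_start) / (profile$ramp_end - profile$ramp_start)
  profile$E1_gen + (profile$E2_gen - profile$E1_gen) * smoothstep(u)
}

# Closed-form force envelope F(lambda) = integral of k from 1.
gen_force <- function(profile, lambda) {
  rs <- profile$ramp_start; re <- profile$ramp_end
  u <- (lambda - rs) / (re - rs)
  profile$E1_gen * (lambda - 1) +
    (profile$E2_gen - profile$E1_gen) * (re - rs) * smoothstep_integral(u)
}

# True incremental Poisson's ratio profile: compact quartic bump.
gen_nu <- function(profile, lambda) {
  t <- (lambda - profile$nu_peak_at) / profile$nu_width
  bump <- ifelse(abs(t) < 1, (1 - t^2)^2, 0)
  profile$nu1_gen + (profile$nu2_gen - profile$nu1_gen) * bump
}

# True transverse stretch: lambda_tr = exp(-integral nu dln lambda),
# evaluated by fine cumulative quadrature and interpolation.
gen_lambda_tr <- function(profile, lambda) {
  grid <- seq(1, max(profile$lambda_max, max(lambda)), length.out = 4000)
  lt <- exp(-cumtrapz(log(grid), gen_nu(profile, grid)))
  stats::approx(grid, lt, xout = lambda)$y
}

# Recovery schedule r(lambda_peak) in percent.
gen_recovery_schedule <- function(profile, lambda_peak) {
  u <- (lambda_peak - profile$ramp_start) /
    (profile$ramp_end - profile$ramp_start)
  profile$recovery_initial -
    (profile$recovery_initial - profile$recovery_floor) * smoothstep(u)
}

# Expected summary metrics under the extraction conventions (window
# averages of the true profiles).
gen_expected_summary <- function(profile) {
  grid <- seq(1, profile$lambda_max, length.out = 2000)
  k <- gen_stiffness(profile, grid)
  nu <- gen_nu(profile, grid)
  lp <- grid[which.max(nu)]
  list(E1 = trapz_mean(grid, k, 1.02, 1.05),
       E2 = trapz_mean(grid, k, profile$ramp_end, profile$lambda_max - 0.05),
       nu1 = trapz_mean(grid, nu, 1.02, 1.05),
       nu2 = trapz_mean(grid, nu, lp - 0.05, lp + 0.05))
}

#' Generate a monotonic synthetic tensile curve
#'
#' Draws a displacement-controlled monotonic test from the profile:
#' axial stretch ramps linearly in time, the force envelope is the exact
#' integral of the stiffness profile, the transverse stretch integrates
#' the Poisson-ratio profile, and seeded Gaussian noise is added to the
#' measured (force, transverse) channels. Machine-readable ground truth
#' is returned alongside the curve.
#'
#' @param profile a `generator_profile`.
#' @return List with `curve` (a `tensile_curve`), `truth` (data frame of
#'   the noise-free profiles on the sample grid) and `expected_summary`
#'   (window-averaged E1, E2, nu1, nu2 of the true profiles).
#' @export
generate_monotonic <- function(profile) {
  if (!is.null(profile$seed)) set.seed(profile$seed)
  n <- profile$n_points
  lam <- seq(1, profile$lambda_max, length.out = n)
  force <- gen_force(profile, lam)
  ltr <- gen_lambda_tr(profile, lam)
  truth <- data.frame(lambda = lam, force_per_width = force,
                      lambda_tr = ltr,
                      tangent_stiffness = gen_stiffness(profile, lam),
                      nu_inc = gen_nu(profile, lam))
  f_obs <- force + stats::rnorm(n, 0, profile$noise_sd_force)
  ltr_obs <- ltr + stats::rnorm(n, 0, profile$noise_sd_stretch)
  curve <- tensile_curve(seq(0, 1, length.out = n) * 200, lam,
                         pmax(ltr_obs, 1e-6), f_obs,
                         label = "synthetic monotonic")
  list(curve = curve, truth = truth,
       expected_summary = gen_expected_summary(profile))
}

#' Generate an incremental cyclic synthetic curve
#'
#' Loading follows the monotonic envelope (reloading from a residual
#' point rises along a straight chord back to the envelope at the prior
#' peak, then continues on the envelope); unloading descends a straight
#' chord in the force-stretch plane to the residual stretch set by the
#' recovery schedule. Transverse stretch follows its envelope on loading
#' and a chord to its own residual on unloading. Segment labels and the
#' per-cycle ground truth are attached.
#'
#' @param profile a `generator_profile`.
#' @param peak_list increasing stretch peaks, first > 1.
#' @return List with `curve` (a labeled `cyclic_curve`), `truth_cycles`
#'   (per-cycle peaks, scheduled recovery and residuals) and
#'   `expected_summary` as in [generate_monotonic()].
#' @export
generate_cyclic <- function(profile, peak_list) {
  if (any(diff(peak_list) <= 0) || peak_list[1] <= 1) {
    stop_wallmech("wallmech_invalid_input",
                  "peaks must be increasing and exceed 1")
  }
  if (!is.null(profile$seed)) set.seed(profile$seed)
  n_seg <- max(25L, ceiling(profile$n_points / (2 * length(peak_list))))

  truth <- data.frame(cycle = seq_along(peak_list),
                      peak_stretch = peak_list)
  truth$recovery_percent <- gen_recovery_schedule(profile, peak_list)
  truth$residual_stretch <- peak_list -
    truth$recovery_percent / 100 * (peak_list - 1)
  tr_peak <- gen_lambda_tr(profile, peak_list)
  truth$residual_stretch_tr <- 1 -
    truth$recovery_percent / 100 * (1 - tr_peak)
  truth$peak_force_per_width <- gen_force(profile, peak_list)

  lam_res_prev <- 1; ltr_res_prev <- 1; prev_peak <- 1
  rows <- list()
  for (ci in seq_along(peak_list)) {
    pk <- peak_list[ci]
    # loading: chord from residual to the envelope at the prior peak,
    # then along the envelope to the new peak
    lam_chord <- if (prev_peak > lam_res_prev + 1e-12) {
      seq(lam_res_prev, prev_peak, length.out = n_seg)
    } else numeric(0)
    f_chord <- if (length(lam_chord)) {
      seq(0, gen_force(profile, prev_peak), length.out = n_seg)
    } else numeric(0)
    ltr_chord <- if (length(lam_chord)) {
      seq(ltr_res_prev, gen_lambda_tr(profile, prev_peak),
          length.out = n_seg)
    } else numeric(0)
    lam_env <- seq(max(prev_peak, lam_res_prev), pk, length.out = n_seg)
    load <- data.frame(
      lambda_ax = c(lam_chord, lam_env),
      lambda_tr = c(ltr_chord, gen_lambda_tr(profile, lam_env)),
      force_per_width = c(f_chord, gen_force(profile, lam_env)),
      cycle = ci, phase = "loading")
    # unloading: straight chords to the scheduled residuals
    un <- data.frame(
      lambda_ax = seq(pk, truth$residual_stretch[ci], length.out = n_seg),
      lambda_tr = seq(gen_lambda_tr(profile, pk),
                      truth$residual_stretch_tr[ci], length.out = n_seg),
      force_per_width = seq(gen_force(profile, pk), 0, length.out = n_seg),
      cycle = ci, phase = "unloading")
    rows[[ci]] <- rbind(load, un)
    lam_res_prev <- truth$residual_stretch[ci]
    ltr_res_prev <- truth$residual_stretch_tr[ci]
    prev_peak <- pk
  }
  df <- do.call(rbind, rows)
  # drop zero-length duplicate samples at segment joints
  keep <- c(TRUE, abs(diff(df$lambda_ax)) > 1e-12 |
              abs(diff(df$force_per_width)) > 1e-12)
  df <- df[keep, ]
  n <- nrow(df)
  df$force_per_width <- df$force_per_width +
    stats::rnorm(n, 0, profile$noise_sd_force)
  df$lambda_tr <- pmax(df$lambda_tr +
                         stats::rnorm(n, 0, profile$noise_sd_stretch), 1e-6)
  curve <- tensile_curve(seq_len(n) - 1, df$lambda_ax, df$lambda_tr,
                         df$force_per_width, cycle = df$cycle,
                         phase = df$phase, label = "synthetic cyclic")
  list(curve = curve, truth_cycles = truth,
       expected_summary = gen_expected_summary(profile))
}

#' Generate a noisy curve from a five-beam simulation
#'
#' Runs the five-beam unit under the requested loading, resamples the
#' response onto a uniform time grid and adds seeded Gaussian
#' measurement noise, producing model-driven fixtures for the analysis
#' pipeline.
#'
#' @param params a `five_beam_params`.
#' @param loading `list(type = "monotonic", lambda_max =, n =)` or
#'   `list(type = "cyclic", peaks =)`.
#' @param noise `list(force =, stretch =)` noise standard deviations.
#' @param seed integer seed, or `NULL`.
#' @return A `tensile_curve` (monotonic) or `cyclic_curve` (cyclic),
#'   with the noise-free model output attached as attribute `truth`.
#' @export
generate_from_model <- function(params,
                                loading = list(type = "monotonic",
                                               lambda_max = 1.5, n = 300),
                                noise = list(force = 0, stretch = 0),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (loading$type == "monotonic") {
    grid <- seq(1, loading$lambda_max, length.out = loading$n %||% 300)
    cur <- simulate_monotonic(params, grid)
    n <- nrow(cur)
    out <- tensile_curve(
      seq(0, 1, length.out = n) * 200, cur$lambda,
      pmax(cur$lambda_tr + stats::rnorm(n, 0, noise$stretch), 1e-6),
      cur$force_per_width + stats::rnorm(n, 0, noise$force),
      label = "five-beam synthetic")
    attr(out, "truth") <- cur
    out
  } else if (loading$type == "cyclic") {
    sim <- simulate_cyclic(params, loading$peaks)
    cur <- sim$curve
    n <- nrow(cur)
    out <- cur
    out$force_per_width <- cur$force_per_width +
      stats::rnorm(n, 0, noise$force)
    out$lambda_tr <- pmax(cur$lambda_tr +
                            stats::rnorm(n, 0, noise$stretch), 1e-6)
    attr(out, "truth") <- cur
    out
  } else {
    stop_wallmech("wallmech_invalid_input", "unknown loading type")
  }
}
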