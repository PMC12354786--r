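#' Segment an incremental cyclic test into loading/unloading cycles
#'
#' Reversals are located as sign changes of the time derivative of the
#' smoothed axial-stretch trace, then snapped to the local extremum of
#' the raw series; samples are labeled with a cycle index (numbered from
#' 1 in time order) and a `loading`/`unloading` phase. Peak samples close
#' the loading phase of their cycle.
#'
#' @param raw a `tensile_curve`.
#' @return A `cyclic_curve` with added `cycle` and `phase` columns.
#' @export
split_cycles <- function(raw) {
  t <- raw$time_s
  lam <- raw$lambda_ax
  n <- length(t)

  # derivative sign from a GCV-smoothed trace; fall back to raw diffs when
  # the spline cannot be fit (few points, exact piecewise-linear data)
  v <- tryCatch({
    fit <- stats::smooth.spline(t, lam, cv = FALSE)
    stats::predict(fit, t, deriv = 1)$y
  }, error = function(e) {
    c(diff(lam) / diff(t), NA)[pmin(seq_len(n), n - 1)]
  })
  vmax <- max(abs(v))
  s <- sign(v) * (abs(v) > 0.02 * vmax)
  # forward-fill zeros so dwell samples inherit the current phase
  for (i in seq_len(n)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  if (s[1] == 0) s[1] <- s[match(TRUE, s != 0)]
  if (all(s >= 0) || all(s <= 0)) {
    stop_wallmech("wallmech_not_cyclic",
                  "no loading reversal found in the axial stretch trace")
  }

  # reversal indices: last sample of each sign run, snapped to the raw
  # extremum in a small neighborhood
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  w <- max(2L, ceiling(n / 100))
  rev_idx <- integer(0)
  rev_sign <- integer(0)
  for (j in seq_along(runs$values)[-length(runs$values)]) {
    i0 <- ends[j]
    lo <- max(1L, i0 - w); hi <- min(n, i0 + w)
    i <- if (runs$values[j] > 0) lo - 1L + which.max(lam[lo:hi])
         else lo - 1L + which.min(lam[lo:hi])
    rev_idx <- c(rev_idx, i)
    rev_sign <- c(rev_sign, runs$values[j])
  }

  cycle <- integer(n)
  phase <- character(n)
  cur_cycle <- 1L
  cur_phase <- if (s[1] > 0) "loading" else "unloading"
  start <- 1L
  for (j in seq_along(rev_idx)) {
    idx <- rev_idx[j]
    cycle[start:idx] <- cur_cycle
    phase[start:idx] <- cur_phase
    if (cur_phase == "unloading") cur_cycle <- cur_cycle + 1L
    cur_phase <- if (cur_phase == "loading") "unloading" else "loading"
    start <- idx + 1L
  }
  cycle[start:n] <- cur_cycle
  phase[start:n] <- cur_phase

  out <- raw
  out$cycle <- cycle
  out$phase <- phase
  class(out) <- unique(c("cyclic_curve", class(raw)))
  out
}

#' Per-cycle recovery metrics of a cyclic tensile test
#'
#' For each load-unload cycle, locates the zero-force crossing of the
#' unloading branch (samples with force below `zero_tol_frac` of the
#' cycle's peak force count as zero; detection runs on a short
#' running-mean of the force so measurement noise cannot trigger it
#' early, and the crossing stretch is then solved from a local
#' least-squares line through the raw samples) and reports the residual
#' axial stretch there, the peak stretch and peak force, and the
#' recovery percentage: recovered
#' deformation relative to total deformation,
#' \eqn{100 (\lambda_{peak} - \lambda_{res}) / (\lambda_{peak} - 1)}.
#' Transverse analogues use \eqn{1 - \lambda_{tr}} as the deformation
#' measure, symmetrically to the axial definition. If an unloading branch
#' never reaches zero force, the residual is taken at the segment end and
#' the cycle is flagged.
#'
#' @param cyc a `cyclic_curve` (from [split_cycles()] or a generator).
#' @param zero_tol_frac zero-force band as a fraction of the cycle's peak
#'   force (default 0.005).
#' @return A data frame of class `recovery_result`, one row per cycle:
#'   `cycle`, `peak_stretch`, `peak_force_per_width`, `residual_stretch`,
#'   `recovery_percent`, `residual_stretch_tr`, `recovery_percent_tr`,
#'   `zero_not_reached`.
#' @export
recovery_analysis <- function(cyc, zero_tol_frac = 0.005) {
  stopifnot(inherits(cyc, "cyclic_curve"))
  cycles <- sort(unique(cyc$cycle))
  rows <- lapply(cycles, function(ci) {
    seg <- cyc[cyc$cycle == ci, ]
    peak_stretch <- max(seg$lambda_ax)
    peak_force <- max(seg$force_per_width)
    peak_tr <- min(seg$lambda_tr)
    un <- seg[seg$phase == "unloading", ]
    if (!nrow(un)) return(NULL)
    un <- un[order(un$time_s), ]
    tol <- zero_tol_frac * peak_force
    flagged <- FALSE
    nu_n <- nrow(un)
    w <- max(1L, min(4L, floor(nu_n / 10)))
    # centered running mean (partial windows at the edges)
    csum <- cumsum(c(0, un$force_per_width))
    lo_i <- pmax(seq_len(nu_n) - w, 1L)
    hi_i <- pmin(seq_len(nu_n) + w, nu_n)
    f_s <- (csum[hi_i + 1] - csum[lo_i]) / (hi_i - lo_i + 1)
    # the running mean is biased upward where a branch ends right at zero,
    # so raw samples count within the final window
    hit <- which(f_s <= tol |
                   (un$force_per_width <= tol & seq_len(nu_n) >= nu_n - w))
    if (length(hit)) {
      i <- min(hit)
      j <- max(1L, i - w):min(nu_n, i + w)
      if (length(j) >= 3 &&
          stats::sd(un$lambda_ax[j]) > 0 &&
          stats::cov(un$lambda_ax[j], un$force_per_width[j]) > 0) {
        # local line through the raw samples, solved at zero force
        fit <- stats::lm.fit(cbind(1, un$lambda_ax[j]),
                             un$force_per_width[j])
        residual <- -fit$coefficients[[1]] / fit$coefficients[[2]]
        residual <- min(max(residual, min(un$lambda_ax[j])),
                        max(un$lambda_ax[j]))
        fit_tr <- stats::lm.fit(cbind(1, un$lambda_ax[j]), un$lambda_tr[j])
        residual_tr <- fit_tr$coefficients[[1]] +
          fit_tr$coefficients[[2]] * residual
      } else {
        residual <- un$lambda_ax[i]
        residual_tr <- un$lambda_tr[i]
      }
    } else {
      flagged <- TRUE
      residual <- un$lambda_ax[nu_n]
      residual_tr <- un$lambda_tr[nu_n]
    }
    recovery <- if (peak_stretch > 1) {
      100 * (peak_stretch - residual) / (peak_stretch - 1)
    } else NA_real_
    recovery_tr <- if (peak_tr < 1) {
      100 * (residual_tr - peak_tr) / (1 - peak_tr)
    } else NA_real_
    data.frame(cycle = ci, peak_stretch = peak_stretch,
               peak_force_per_width = peak_force,
               residual_stretch = residual, recovery_percent = recovery,
               residual_stretch_tr = residual_tr,
               recovery_percent_tr = recovery_tr,
               zero_not_reached = flagged)
  })
  out <- do.call(rbind, rows)
  if (any(out$zero_not_reached)) {
    warning("some unloading branches never reached zero force; residuals ",
            "taken at segment end", call. = FALSE)
  }
  structure(out, class = c("recovery_result", "data.frame"))
}

#' Residual stretch versus peak membrane force
#'
#' Orders the cycles of a recovery analysis by their peak force per width
#' and reports the accumulated residual stretch measured at each cycle,
#' the standard presentation of progressive plasticity in incremental
#' cyclic tests.
#'
#' @param rec a `recovery_result`.
#' @return Data frame with `peak_force_per_width` and `residual_stretch`,
#'   ordered by peak force.
#' @export
residual_vs_force <- function(rec) {
  stopifnot(inherits(rec, "recovery_result"))
  ord <- order(rec$peak_force_per_width)
  data.frame(peak_force_per_width = rec$peak_force_per_width[ord],
             residual_stretch = rec$residual_stretch[ord])
}
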