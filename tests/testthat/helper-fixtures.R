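# Shared fixtures: analytic derived-curve profiles and small loading paths.

# Derived curves from analytic stiffness/Poisson profiles (no smoothing).
analytic_derived <- function(k_fun, nu_fun, lambda_max = 1.5, n = 400) {
  lam <- seq(1, lambda_max, length.out = n)
  structure(
    data.frame(lambda = lam,
               force_per_width = cumtrapz_local(lam, k_fun(lam)),
               tangent_stiffness = k_fun(lam),
               nu_inc = nu_fun(lam)),
    class = c("derived_curves", "data.frame")
  )
}

cumtrapz_local <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Piecewise three-regime stiffness: E1 until a, linear ramp to E2 at b.
ramp_k <- function(E1, E2, a, b) {
  function(lam) {
    u <- pmin(pmax((lam - a) / (b - a), 0), 1)
    E1 + (E2 - E1) * u
  }
}

# Triangle-wave cyclic stretch path with given peaks, returning to 1.
triangle_path <- function(peaks, n_seg = 40) {
  lam <- 1
  for (p in peaks) {
    lam <- c(lam, seq(utils::tail(lam, 1), p, length.out = n_seg)[-1],
             seq(p, 1, length.out = n_seg)[-1])
  }
  lam
}

quick_fb <- function(...) five_beam_params(...)
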