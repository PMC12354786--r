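# Small numerical helpers shared across modules.

# Cubic smoothstep on [0, 1], C1 at both ends.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Integral of smoothstep from 0 to u (beyond 1 the integrand is 1).
smoothstep_integral <- function(u) {
  u0 <- pmin(pmax(u, 0), 1)
  ifelse(u >= 1, u - 0.5, u0^3 - u0^4 / 2)
}

# Trapezoidal cumulative integral of y over x, same length as x.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Mean of a sampled profile y(x) over [a, b] by trapezoidal quadrature,
# with linear interpolation at the window edges. Degenerates to point
# evaluation when b <= a.
trapz_mean <- function(x, y, a, b) {
  if (b <= a) {
    return(stats::approx(x, y, xout = a, rule = 2)$y)
  }
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- stats::approx(x, y, xout = xs, rule = 2)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2) / (b - a)
}

# Central differences with one-sided ends; x strictly increasing.
central_diff <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  i <- 2:(n - 1)
  d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  d
}

stop_wallmech <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "wallmech_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
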