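# small numerical helpers shared across modules

# composite trapezoid on a uniform grid with spacing h
trapz <- function(y, h) {
  n <- length(y)
  h * (sum(y) - 0.5 * (y[1] + y[n]))
}

# trapezoid weights on a uniform grid
trapz_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

# causal exponential convolution E(tau_j) = int_0^tau_j Z(s) e^{-(tau_j-s)/tau} ds
# evaluated recursively (stable for tau << grid span, no overflow)
exp_conv <- function(z, h, tau) {
  n <- length(z)
  d <- exp(-h / tau)
  e <- numeric(n)
  for (j in 2:n) e[j] <- e[j - 1] * d + 0.5 * h * (z[j] + z[j - 1] * d)
  e
}

# composite Simpson rule; length(y) must be odd (even number of intervals)
simpson <- function(y, h) {
  n <- length(y)
  stopifnot(n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[c(1, n)] <- 1
  h / 3 * sum(w * y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cfg("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stop_cfg("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}
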