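#' Specify the noise sources
#'
#' The voltage equation is driven by Gaussian white noise of intensity
#' \code{d_white} (\eqn{D}) and by an Ornstein-Uhlenbeck (OU) process with
#' variance \code{sigma2} (\eqn{\sigma^2}) and correlation time
#' \code{tau_eta} (\eqn{\tau_\eta}),
#' \eqn{\langle\eta(t)\eta(t')\rangle = \sigma^2 e^{-|t-t'|/\tau_\eta}}.
#'
#' Modes:
#' \describe{
#'   \item{independent}{white and OU increments are independent.}
#'   \item{green}{the two sources share one increment with opposite signs
#'     (\eqn{\xi_v = -\xi_\eta}), producing network-like "green" noise with
#'     suppressed low-frequency power, spectrum [green_noise_spectrum()].
#'     Requires both \code{d_white > 0} and \code{sigma2 > 0}.}
#'   \item{shared_channel}{adaptation and OU noise model one population of
#'     slow adaptation channels; their time constants must coincide
#'     (\eqn{\tau_c := \tau_a = \tau_\eta}, enforced when a theory context is
#'     built). Increments are independent.}
#' }
#'
#' @param d_white white-noise intensity \eqn{D \ge 0}.
#' @param sigma2 OU variance \eqn{\sigma^2 \ge 0}.
#' @param tau_eta OU correlation time (> 0 whenever \code{sigma2 > 0}).
#' @param mode coupling mode, see Details.
#' @return an object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(d_white = 0, sigma2 = 0, tau_eta = 1,
                       mode = c("independent", "green", "shared_channel")) {
  mode <- match.arg(mode)
  check_scalar(d_white, "d_white", lower = 0)
  check_scalar(sigma2, "sigma2", lower = 0)
  if (sigma2 > 0) check_scalar(tau_eta, "tau_eta", lower = .Machine$double.eps)
  if (mode == "green" && (d_white <= 0 || sigma2 <= 0))
    stop_cfg("green noise requires both d_white > 0 and sigma2 > 0")
  structure(list(d_white = d_white, sigma2 = sigma2, tau_eta = tau_eta,
                 mode = mode),
            class = "noise_spec")
}

# effective variance of the colored component: in green mode the
# anti-correlated white increment contributes a negative exponential
# cross-covariance, folding into sigma^2 - 2 sqrt(D sigma^2 / tau_eta)
sigma2_effective <- function(noise) {
  if (noise$mode == "green")
    noise$sigma2 - 2 * sqrt(noise$d_white * noise$sigma2 / noise$tau_eta)
  else
    noise$sigma2
}

#' Adaptation response parameter
#'
#' \deqn{\nu = 1 - \frac{a^*}{\tau_a}\int_0^{T^*} Z(\tau)
#' e^{-\tau/\tau_a}\,d\tau.}
#' Without adaptation (\eqn{a^* = 0}) \eqn{\nu = 1}; for purely positive PRCs
#' and \eqn{a^* > 0}, \eqn{\nu < 1}. \eqn{\nu < 0} signals strong adaptation
#' (the reset voltage initially recedes from threshold); \eqn{\nu > 1} is
#' possible for partially negative PRCs (resonators).
#'
#' @param prc a \code{"prc_grid"}.
#' @param a_star deterministic peak adaptation value.
#' @param tau_a adaptation time constant.
#' @export
nu_parameter <- function(prc, a_star, tau_a) {
  check_scalar(tau_a, "tau_a", lower = .Machine$double.eps)
  n <- length(prc$tau)
  h <- prc$period / (n - 1)
  1 - a_star / tau_a * trapz(prc$z_v * exp(-prc$tau / tau_a), h)
}

#' Specific SCC of adaptation with white noise
#'
#' The serial correlation coefficient when the only correlation-inducing
#' process is the spike-triggered adaptation (colored noise switched off):
#' \deqn{\rho_{k,a} = -\frac{\alpha(1-\alpha^2\nu)}{1+\alpha^2-2\alpha^2\nu}
#' (1-\nu)\,(\alpha\nu)^{k-1},}
#' a single geometric sequence with ratio \eqn{\alpha\nu} (oscillatory when
#' \eqn{\nu < 0}).
#'
#' @param alpha \eqn{e^{-T^*/\tau_a}}.
#' @param nu adaptation response parameter, see [nu_parameter()].
#' @param k lag(s), \eqn{k \ge 1}.
#' @export
scc_adaptation <- function(alpha, nu, k) {
  if (any(k < 1)) stop_cfg("lag k must be >= 1")
  if (abs(alpha * nu) >= 1)
    stop_cfg("stochastic map unstable: |alpha * nu| = %g >= 1", abs(alpha * nu))
  -alpha * (1 - alpha^2 * nu) / (1 + alpha^2 - 2 * alpha^2 * nu) *
    (1 - nu) * (alpha * nu)^(k - 1)
}

# PRC-weighted covariance functionals of the noise over one period:
#   k_z2 = int Z^2
#   j0   = int int Z(t) Z(t') exp(-|t-t'|/tau_eta)
#   ip   = int Z(t) exp(-(T*-t)/tau_eta),  im = int Z(t) exp(-t/tau_eta)
# h0 = <H^2> + <Xi^2> = sigma_eff^2 j0 + 2 D k_z2 ; h1 = <H_i H_{i+1}> =
# sigma_eff^2 ip im (the lag-1 double integral factorizes because
# T* + t' - t >= 0 on the domain).
noise_functionals <- function(prc, noise) {
  n <- length(prc$tau)
  h <- prc$period / (n - 1)
  z <- prc$z_v
  k_z2 <- trapz(z^2, h)
  s2 <- sigma2_effective(noise)
  if (noise$sigma2 > 0) {
    te <- noise$tau_eta
    ip <- trapz(z * exp(-(prc$period - prc$tau) / te), h)
    im <- trapz(z * exp(-prc$tau / te), h)
    j0 <- 2 * trapz(z * exp_conv(z, h, te), h)
    h1 <- s2 * ip * im
    h0 <- s2 * j0 + 2 * noise$d_white * k_z2
  } else {
    h1 <- 0
    h0 <- 2 * noise$d_white * k_z2
  }
  list(h0 = h0, h1 = h1, k_z2 = k_z2)
}

new_theory_context <- function(prc, period, a_star, tau_a, noise,
                               model = NULL, adaptation = NULL, cycle = NULL) {
  if (noise$mode == "shared_channel" &&
      abs(tau_a - noise$tau_eta) > 1e-12 * max(1, tau_a))
    stop_cfg("shared_channel mode requires tau_a = tau_eta (got %g and %g)",
             tau_a, noise$tau_eta)
  alpha <- exp(-period / tau_a)
  beta <- if (noise$sigma2 > 0) exp(-period / noise$tau_eta) else NA_real_
  nu <- nu_parameter(prc, a_star, tau_a)
  if (abs(alpha * nu) >= 1)
    stop_cfg("stochastic map unstable: |alpha * nu| = %g >= 1", abs(alpha * nu))
  nf <- noise_functionals(prc, noise)
  structure(list(prc = prc, period = period, a_star = a_star, tau_a = tau_a,
                 noise = noise, alpha = alpha, beta = beta, nu = nu,
                 sigma2_eff = sigma2_effective(noise),
                 h0 = nf$h0, h1 = nf$h1, int_z2 = nf$k_z2,
                 model = model, adaptation = adaptation, cycle = cycle),
            class = "theory_context")
}

#' Assemble the weak-noise theory context
#'
#' Chains [find_limit_cycle()], a PRC (analytic closed form by default,
#' adjoint integration on request) and [nu_parameter()], precomputes the
#' PRC-weighted noise covariance functionals, and validates the stability
#' condition \eqn{|\alpha\nu| < 1}.
#'
#' @param model an [model_spec()] object.
#' @param adaptation an [adaptation_spec()] object.
#' @param noise a [noise_spec()] object.
#' @param prc_method \code{"analytic"} or \code{"adjoint"}.
#' @param n_grid trajectory/PRC grid resolution.
#' @param cycle optionally a precomputed [find_limit_cycle()] result.
#' @return an object of class \code{"theory_context"} with fields
#'   \code{period}, \code{a_star}, \code{alpha}, \code{beta}, \code{nu},
#'   \code{prc}, \code{noise} and the internal covariance functionals.
#' @export
build_context <- function(model, adaptation, noise,
                          prc_method = c("analytic", "adjoint"),
                          n_grid = 4096, cycle = NULL) {
  prc_method <- match.arg(prc_method)
  if (is.null(cycle)) cycle <- find_limit_cycle(model, adaptation, n_grid = n_grid)
  prc <- if (prc_method == "adjoint") prc_adjoint(model, adaptation, cycle)
         else switch(model$kind,
                     lif = prc_lif(model, adaptation, cycle),
                     gif = prc_gif(model, adaptation, cycle),
                     qif = prc_qif(model, adaptation, cycle))
  new_theory_context(prc, cycle$period, cycle$a_star, adaptation$tau_a, noise,
                     model = model, adaptation = adaptation, cycle = cycle)
}

#' @export
print.theory_context <- function(x, ...) {
  cat(sprintf(paste0("Theory context: T* = %.5g, a* = %.5g, alpha = %.4g, ",
                     "beta = %.4g, nu = %.4g\n"),
              x$period, x$a_star, x$alpha, x$beta, x$nu))
  invisible(x)
}

# (m^k - b^k)/(m - b) with its limit k m^(k-1) at m = b (vectorized over k)
geom_diff <- function(m, b, k) {
  if (abs(m - b) < 1e-9 * max(1, abs(m), abs(b))) k * m^(k - 1)
  else (m^k - b^k) / (m - b)
}

#' Specific SCC of colored plus white noise (no adaptation)
#'
#' The serial correlation coefficient in the absence of adaptation: a single
#' geometric sequence \eqn{\rho_{k,\eta} = \rho_{1,\eta}\,\beta^{k-1}} with
#' \eqn{\beta = e^{-T^*/\tau_\eta}}. By default it is evaluated in the time
#' domain from the PRC-weighted covariance double integrals
#' \deqn{\rho_{1,\eta} = \frac{\int\!\!\int Z(\tau)Z(\tau')\,
#'   \sigma^2 e^{-(T^*+\tau'-\tau)/\tau_\eta}}
#'   {\int\!\!\int Z(\tau)Z(\tau')\,\sigma^2 e^{-|\tau'-\tau|/\tau_\eta}
#'    + 2D\int Z^2};}
#' \code{method = "frequency"} evaluates the equivalent spectral form
#' through [scc_spectrum()] as an independent cross-check. The coefficient
#' vanishes as \eqn{D/(\tau_\eta\sigma^2) \to \infty} and is non-negative for
#' positive PRCs (in independent mode).
#'
#' @param ctx a [build_context()] result.
#' @param k lag(s), \eqn{k \ge 1}.
#' @param method \code{"time"} (default) or \code{"frequency"}.
#' @param ... further arguments passed to [scc_spectrum()] for the frequency
#'   method.
#' @export
scc_colored <- function(ctx, k, method = c("time", "frequency"), ...) {
  method <- match.arg(method)
  if (any(k < 1)) stop_cfg("lag k must be >= 1")
  noise <- ctx$noise
  if (noise$sigma2 <= 0 && noise$d_white <= 0)
    stop_cfg("undefined statistic: both noise intensities are zero")
  if (noise$sigma2 <= 0) return(rep(0, length(k)))
  if (method == "time") {
    (ctx$h1 / ctx$h0) * ctx$beta^(k - 1)
  } else {
    s_fun <- context_spectrum(ctx)
    vapply(k, function(kk)
      scc_spectrum(ctx$prc, s_fun, ctx$period, kk, ...), numeric(1))
  }
}

# input power spectrum of the total fluctuation in the voltage equation,
# in the 2D-at-high-frequency normalization (only ratios matter)
context_spectrum <- function(ctx) {
  noise <- ctx$noise
  if (noise$mode == "green") {
    function(omega) green_noise_spectrum(omega, noise$d_white, noise$sigma2,
                                         noise$tau_eta)
  } else {
    function(omega) 2 * noise$d_white +
      2 * noise$tau_eta * noise$sigma2 / (1 + noise$tau_eta^2 * omega^2)
  }
}

#' Power spectrum of green (network-like) noise
#'
#' Spectrum of \eqn{\zeta = \eta + \sqrt{2D}\,\xi_v} when the OU and white
#' sources are anti-correlated (\eqn{\xi_v = -\xi_\eta}):
#' \deqn{S_{\zeta\zeta}(\omega) = 2D + \frac{2\tau_\eta\sigma^2 -
#' 4\sqrt{D\tau_\eta\sigma^2}}{1+\tau_\eta^2\omega^2},}
#' with flat high-frequency limit \eqn{2D} and suppressed low-frequency power
#' \eqn{S(0) = (\sqrt{2D} - \sqrt{2\tau_\eta\sigma^2})^2}, vanishing exactly
#' when \eqn{D = \tau_\eta\sigma^2}.
#'
#' @param omega angular frequency (vectorized).
#' @param d_white white-noise intensity \eqn{D}.
#' @param sigma2 OU variance.
#' @param tau_eta OU correlation time.
#' @export
green_noise_spectrum <- function(omega, d_white, sigma2, tau_eta) {
  2 * d_white + (2 * tau_eta * sigma2 - 4 * sqrt(d_white * tau_eta * sigma2)) /
    (1 + tau_eta^2 * omega^2)
}

#' SCC from an arbitrary input power spectrum
#'
#' Generalized specific correlation coefficient
#' \deqn{\rho_{k,\eta} = \frac{\int d\omega\,|\tilde Z(\omega)|^2
#' S_{\zeta\zeta}(\omega)\,e^{-ik\omega T^*}}{\int d\omega\,
#' |\tilde Z(\omega)|^2 S_{\zeta\zeta}(\omega)},}
#' valid when the corresponding autocorrelation decays exponentially (a
#' delta contribution, i.e. a flat spectral floor, is also permitted).
#'
#' The flat component \eqn{S(\infty)} is integrated in closed form (it
#' contributes \eqn{2\pi\int Z^2/T^{*2}} to the denominator and nothing to
#' lags \eqn{k \ge 1}, since the PRC autocorrelation vanishes beyond one
#' period); the remaining decaying part is integrated by composite Simpson
#' quadrature on \eqn{[0, \omega_{max}]} using the even symmetry of the
#' integrand. The imaginary part cancels exactly on the symmetric grid and a
#' zero residual is reported via the \code{"imag_residual"} attribute.
#'
#' @param prc a \code{"prc_grid"} on a uniform grid.
#' @param spectrum function of \eqn{\omega} returning the (two-sided, even)
#'   input power spectrum.
#' @param period the deterministic period \eqn{T^*}.
#' @param k lag (scalar, \eqn{k \ge 0}; \eqn{k = 0} gives 1).
#' @param omega_max truncation of the decaying spectral part (default
#'   \code{400/period}; its tail is \eqn{O(\omega^{-3})} relative).
#' @param points_per_cycle Simpson resolution per oscillation of
#'   \eqn{\cos(k\omega T^*)}.
#' @export
scc_spectrum <- function(prc, spectrum, period, k,
                         omega_max = 400 / period, points_per_cycle = 256) {
  if (length(prc$tau) < 2) stop_cfg("empty PRC grid")
  s_inf <- spectrum(1e12 / period)
  domega <- 2 * pi / (period * points_per_cycle * max(1, k))
  n_om <- ceiling(omega_max / domega)
  if (n_om %% 2 == 1) n_om <- n_om + 1  # even intervals for Simpson
  om <- seq(0, omega_max, length.out = n_om + 1)
  p <- zt_power(prc, om)
  s_dec <- spectrum(om) - s_inf
  h <- om[2] - om[1]
  num_dec <- 2 * simpson(p * s_dec * cos(k * om * period), h)
  den_dec <- 2 * simpson(p * s_dec, h)
  n <- length(prc$tau)
  hz <- period / (n - 1)
  flat <- s_inf * 2 * pi * trapz(prc$z_v^2, hz) / period^2
  num <- num_dec + if (k == 0) flat else 0
  den <- den_dec + flat
  # the imaginary part cancels identically on the symmetric grid
  num / den
}

#' General serial correlation coefficient
#'
#' The weak-noise SCC of the full model with both spike-triggered adaptation
#' and colored noise: a sum of two geometric sequences,
#' \deqn{\rho_k = (A/C)\,\rho_{k,a} + (B/C)\,\rho_{k,\eta},}
#' where the primary evaluation goes through the covariances
#' \eqn{c_k = \langle\delta a_i\,\delta a_{i+k}\rangle} of the peak
#' adaptation values generated by the linearized stochastic map (this route
#' is numerically stable also at the removable singularity
#' \eqn{\alpha\nu = \beta}). The coefficients
#' \deqn{A = 1 - \alpha\nu\beta + \rho_{1,\eta}\,
#'   \frac{1+(\alpha\nu)^2-2\alpha\nu\beta}{\alpha\nu-\beta},\quad
#' B = \frac{(1-(\alpha\nu)^2)(1-\alpha\beta)(\alpha-\beta)}
#'   {(1+\alpha^2-2\alpha^2\nu)(\alpha\nu-\beta)},\quad
#' C = 1 - \alpha\nu\beta + 2\rho_{1,a}\rho_{1,\eta}}
#' are returned alongside. Exact limit cases: \eqn{\sigma = 0} gives
#' \eqn{\rho_k = \rho_{k,a}}; \eqn{\Delta = 0} gives \eqn{\nu = 1} and
#' \eqn{\rho_k = \rho_{k,\eta}}; \eqn{\tau_a = \tau_\eta} gives \eqn{B = 0}
#' (single geometric sequence).
#'
#' @param ctx a [build_context()] result.
#' @param k lags (\eqn{\ge 1}).
#' @return a data frame with columns \code{lag}, \code{rho}, \code{rho_a},
#'   \code{rho_eta}, \code{A}, \code{B}, \code{C} and attribute
#'   \code{"renewal"} when no correlation-inducing process is present.
#' @export
scc_general <- function(ctx, k = 1:10) {
  if (any(k < 1)) stop_cfg("lag k must be >= 1")
  k <- as.integer(k)
  noise <- ctx$noise
  has_adapt <- !is.null(ctx$a_star) && ctx$a_star > 0
  has_col <- noise$sigma2 > 0
  alpha <- ctx$alpha; nu <- ctx$nu; beta <- ctx$beta
  if (!has_adapt && !has_col) {
    out <- data.frame(lag = k, rho = 0, rho_a = 0, rho_eta = 0,
                      A = NA_real_, B = NA_real_, C = NA_real_)
    attr(out, "renewal") <- TRUE
    return(out)
  }
  if (!has_adapt) {
    rho_eta <- scc_colored(ctx, k)
    out <- data.frame(lag = k, rho = rho_eta, rho_a = 0, rho_eta = rho_eta,
                      A = 0, B = 1, C = 1)
    attr(out, "renewal") <- FALSE
    return(out)
  }
  rho_a <- scc_adaptation(alpha, nu, k)
  if (!has_col || ctx$h1 == 0) {
    out <- data.frame(lag = k, rho = rho_a, rho_a = rho_a, rho_eta = 0,
                      A = 1, B = 0, C = 1)
    attr(out, "renewal") <- FALSE
    return(out)
  }

  m <- alpha * nu
  # stationary moments of the linearized map (overall scale of the kick
  # amplitude q cancels in the SCC; set q = 1)
  ch <- ctx$h1 / (1 - m * beta)
  v0 <- (ctx$h0 + 2 * m * ch) / (1 - m^2)
  kk <- 0:(max(k) + 1)
  c_k <- m^kk * v0 + ch * geom_diff(m, beta, kk)  # c_k[i] is the lag-(i-1) covariance
  den <- (1 + alpha^2) * c_k[1] - 2 * alpha * c_k[2]
  rho <- ((1 + alpha^2) * c_k[k + 1] - alpha * (c_k[k] + c_k[k + 2])) / den

  r1e <- ctx$h1 / ctx$h0
  rho_eta <- r1e * beta^(k - 1)
  r1a <- scc_adaptation(alpha, nu, 1)
  A <- 1 - m * beta + r1e * (1 + m^2 - 2 * m * beta) / (m - beta)
  B <- (1 - m^2) * (1 - alpha * beta) * (alpha - beta) /
    ((1 + alpha^2 - 2 * alpha^2 * nu) * (m - beta))
  C <- 1 - m * beta + 2 * r1a * r1e
  out <- data.frame(lag = k, rho = rho, rho_a = rho_a, rho_eta = rho_eta,
                    A = A, B = B, C = C)
  attr(out, "renewal") <- FALSE
  out
}

#' SCC series with analytic tail information
#'
#' Convenience wrapper around [scc_general()] returning an object that also
#' carries the geometric ratios needed to sum the series beyond
#' \code{k_max} in closed form (used by [low_freq_spike_spectrum()]).
#'
#' @inheritParams scc_general
#' @param k_max largest lag to tabulate.
#' @export
scc_series <- function(ctx, k_max = 20) {
  out <- scc_general(ctx, seq_len(k_max))
  attr(out, "ratios") <- c(m = ctx$alpha * ctx$nu, beta = ctx$beta %||% 0)
  class(out) <- c("scc_series", class(out))
  out
}

#' Coefficient of variation of the ISIs (weak-noise theory)
#'
#' \deqn{CV^2 = \frac{1+\alpha^2-2\alpha^2\nu}{T^{*2}(1-(\alpha\nu)^2)}
#' \left[\langle H^2\rangle + \langle\Xi^2\rangle\right]
#' - \frac{2\alpha(1-\alpha^2\nu)(1-\nu)}
#' {T^{*2}(1-\alpha\nu\beta)(1-(\alpha\nu)^2)}\langle H_iH_{i+1}\rangle,}
#' with the PRC-weighted noise functionals
#' \eqn{\langle H^2\rangle+\langle\Xi^2\rangle} and
#' \eqn{\langle H_iH_{i+1}\rangle} evaluated as covariance double integrals
#' over one period. Without adaptation this reduces to
#' \eqn{CV^2 = (\langle H^2\rangle+\langle\Xi^2\rangle)/T^{*2}}, and with
#' purely white noise to \eqn{CV^2 = 2D\int Z^2 d\tau / T^{*2}}.
#'
#' @param ctx a [build_context()] result.
#' @return the theoretical CV (scalar).
#' @export
cv_theory <- function(ctx) {
  alpha <- ctx$alpha; nu <- ctx$nu
  m <- alpha * nu
  if (abs(m) >= 1) stop_cfg("stochastic map unstable: |alpha*nu| >= 1")
  t2 <- ctx$period^2
  first <- (1 + alpha^2 - 2 * alpha^2 * nu) / (t2 * (1 - m^2)) * ctx$h0
  second <- if (ctx$h1 != 0) {
    beta <- ctx$beta
    2 * alpha * (1 - alpha^2 * nu) * (1 - nu) /
      (t2 * (1 - m * beta) * (1 - m^2)) * ctx$h1
  } else 0
  sqrt(first - second)
}

#' Low-frequency limit of the spike-train power spectrum
#'
#' \deqn{\lim_{f\to 0} S(f) = r_0\,CV^2\Big(1 + 2\sum_{j\ge 1}\rho_j\Big),}
#' with the tail of the SCC sum beyond the tabulated lags summed in closed
#' form using the two geometric ratios \eqn{\alpha\nu} and \eqn{\beta}. Also
#' returns the asymptotic Fano factor \eqn{S(0)/r_0}.
#'
#' @param rate firing rate \eqn{r_0 = 1/\langle T\rangle}.
#' @param cv coefficient of variation of the ISIs.
#' @param rho either an [scc_series()] object (tail summed analytically) or a
#'   plain numeric vector of SCC values (summed as given).
#' @return list with \code{s0}, \code{fano} and the correlation sum
#'   \code{rho_sum}.
#' @export
low_freq_spike_spectrum <- function(rate, cv, rho) {
  if (inherits(rho, "scc_series")) {
    ratios <- attr(rho, "ratios")
    m <- ratios[["m"]]; b <- ratios[["beta"]]
    if (abs(m) >= 1 || (is.finite(b) && b >= 1))
      stop_cfg("divergent SCC tail: |alpha*nu| or beta >= 1")
    k_max <- max(rho$lag)
    # rho_k = P_a m^{k-1} + P_eta b^{k-1}; recover the prefactors from the
    # stored components and sum the tail geometrically
    p_a <- if (rho$rho_a[1] != 0) (rho$A[1] / rho$C[1]) * rho$rho_a[1] else 0
    p_e <- if (rho$rho_eta[1] != 0) (rho$B[1] / rho$C[1]) * rho$rho_eta[1] else 0
    tail <- p_a * m^k_max / (1 - m) +
      (if (p_e != 0) p_e * b^k_max / (1 - b) else 0)
    rho_sum <- sum(rho$rho) + tail
  } else {
    rho_sum <- sum(rho)
  }
  s0 <- rate * cv^2 * (1 + 2 * rho_sum)
  list(s0 = unname(s0), fano = unname(cv^2 * (1 + 2 * rho_sum)),
       rho_sum = unname(rho_sum))
}
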