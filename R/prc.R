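#' @title Phase-response curves of the deterministic limit cycle
#' @description The phase-response curve (PRC) \eqn{Z(\tau)} measures the
#' shift of the next spike time caused by a small voltage perturbation applied
#' at phase \eqn{\tau \in [0, T^*]} of the firing cycle,
#' \eqn{Z(\tau) = -\lim_{\epsilon\to 0} \delta T(\tau,\epsilon)/\epsilon};
#' positive values mean a positive kick advances the spike. Analytic closed
#' forms exist for the one-dimensional models and the GIF; the adjoint method
#' works for the whole family; the direct method estimates \eqn{Z} from
#' explicit delta kicks and serves as a model-free cross-check.
#' @name prc
NULL

new_prc_grid <- function(tau, z_v, z_w = NULL, z_a = NULL, period, method,
                         kind, z_theta = NULL, norm_residual = NA_real_) {
  structure(list(tau = tau, z_v = z_v, z_w = z_w, z_a = z_a,
                 z_theta = z_theta, period = period, method = method,
                 kind = kind, norm_residual = norm_residual),
            class = "prc_grid")
}

#' @export
print.prc_grid <- function(x, ...) {
  cat(sprintf("PRC (%s, %s): %d points on [0, %.4g], Z(T*) = %.4g\n",
              x$kind, x$method, length(x$tau), x$period,
              x$z_v[length(x$z_v)]))
  invisible(x)
}

# velocity at threshold just before reset (the adaptation current there is
# a* - Delta/tau_a, i.e. the pre-jump value)
threshold_velocity <- function(model, adaptation, cycle) {
  a_pre <- cycle$a_star - adaptation$delta / adaptation$tau_a
  switch(model$kind,
    lif = model$mu - model$gamma * model$v_threshold - a_pre,
    gif = model$mu - model$gamma * model$v_threshold -
      model$beta_w * cycle$w_at_threshold - a_pre,
    qif = Inf)
}

#' Analytic PRC of the adapting leaky integrate-and-fire model
#'
#' \deqn{Z(\tau) = \frac{e^{\gamma(\tau - T^*)}}{\mu - \gamma v_T - a^* +
#' \Delta/\tau_a},}
#' the one-dimensional adjoint solution with
#' \eqn{Z(T^*) = 1/\dot v(T^*)}.
#'
#' @param model an [model_spec()] object with \code{kind = "lif"}.
#' @param adaptation an [adaptation_spec()] object.
#' @param cycle the matching [find_limit_cycle()] result.
#' @return a \code{"prc_grid"} object on the trajectory grid of \code{cycle}.
#' @export
prc_lif <- function(model, adaptation, cycle) {
  stopifnot(model$kind == "lif")
  vdot <- threshold_velocity(model, adaptation, cycle)
  if (vdot <= 0)
    stop_cfg("velocity at threshold non-positive (%g): model does not fire through the threshold", vdot)
  tau <- cycle$trajectory$t
  z <- exp(model$gamma * (tau - cycle$period)) / vdot
  new_prc_grid(tau, z, period = cycle$period, method = "analytic", kind = "lif")
}

#' Analytic PRC of the adapting generalized integrate-and-fire model
#'
#' Valid on the oscillatory (resonator) branch
#' \eqn{\Omega^2 = (\beta_w + \gamma)/\tau_w - \lambda^2/4 > 0} with
#' \eqn{\lambda = \gamma + 1/\tau_w}:
#' \deqn{Z(\tau) = \frac{e^{(\lambda/2)(\tau-T^*)}\left[\cos(\Omega(\tau-T^*))
#'  - \frac{1-\tau_w\gamma}{2\tau_w\Omega}\sin(\Omega(\tau-T^*))\right]}
#'  {\mu - \gamma v_T - \beta_w w_0(T^*) - a^* + \Delta/\tau_a}.}
#' The exponent groups \eqn{\lambda/2}; this convention is fixed by agreement
#' with the adjoint solution (checked in the test suite). The PRC can be
#' partially negative (type II resetting).
#'
#' @inheritParams prc_lif
#' @export
prc_gif <- function(model, adaptation, cycle) {
  stopifnot(model$kind == "gif")
  lambda <- model$gamma + 1 / model$tau_w
  omega2 <- (model$beta_w + model$gamma) / model$tau_w - lambda^2 / 4
  if (omega2 <= 0)
    stop_cfg("non-oscillatory subthreshold dynamics (Omega^2 = %g <= 0); use prc_adjoint()", omega2)
  omega <- sqrt(omega2)
  vdot <- threshold_velocity(model, adaptation, cycle)
  if (vdot <= 0)
    stop_cfg("velocity at threshold non-positive (%g)", vdot)
  tau <- cycle$trajectory$t
  s <- tau - cycle$period
  z <- exp(lambda / 2 * s) *
    (cos(omega * s) - (1 - model$tau_w * model$gamma) /
       (2 * model$tau_w * omega) * sin(omega * s)) / vdot
  new_prc_grid(tau, z, period = cycle$period, method = "analytic", kind = "gif")
}

#' Analytic PRC of the adapting quadratic integrate-and-fire (theta) model
#'
#' Evaluates the one-dimensional quadrature form of the adjoint solution in
#' theta coordinates,
#' \eqn{Z_\theta(\tau) = Z_\theta(T^*)\exp\int_\tau^{T^*}
#' \partial_\theta f\,ds} with \eqn{Z_\theta(T^*) = 1/\dot\theta(T^*) = 1/2},
#' and converts to the voltage response
#' \eqn{Z(\tau) = Z_\theta(\tau)\,(1 + \cos\theta_0(\tau))}, the sensitivity
#' to kicks applied to \eqn{v} (where the noise enters).
#'
#' @inheritParams prc_lif
#' @export
prc_qif <- function(model, adaptation, cycle) {
  stopifnot(model$kind == "qif")
  tr <- cycle$trajectory
  n <- nrow(tr)
  h <- cycle$period / (n - 1)
  dfdtheta <- sin(tr$theta) * (1 - model$mu + tr$a)
  # I(tau_j) = int_{tau_j}^{T*} dfdtheta ds via reversed cumulative trapezoid
  cum <- c(0, cumsum(0.5 * h * (dfdtheta[-1] + dfdtheta[-n])))
  integral_to_end <- cum[n] - cum
  z_theta <- 0.5 * exp(integral_to_end)
  z_v <- z_theta * (1 + cos(tr$theta))
  new_prc_grid(tr$t, z_v, period = cycle$period, method = "analytic",
               kind = "qif", z_theta = z_theta)
}

#' PRC by backward integration of the adjoint system
#'
#' Integrates \eqn{\dot{\mathbf Z} = -A^{\mathsf T}(t)\,\mathbf Z} backward
#' from \eqn{t = T^*}, where \eqn{A(t)} is the Jacobian of the model along the
#' limit cycle, with end conditions \eqn{Z_w(T^*) = Z_a(T^*) = 0} and
#' \eqn{Z(T^*) = 1/\dot v_0(T^*)}. The output satisfies the normalization
#' \eqn{\mathbf Z(t)\cdot\dot{\mathbf X}_0(t) = 1} at every grid point; the
#' maximum residual is checked against \code{norm_tol}.
#'
#' For the QIF the adjoint is solved in theta coordinates (the Jacobian needs
#' off-grid states, interpolated by cubic splines) and converted to the
#' voltage response as in [prc_qif()].
#'
#' @inheritParams prc_lif
#' @param model any [model_spec()] kind.
#' @param norm_tol maximum tolerated normalization residual.
#' @return a \code{"prc_grid"} with components \code{z_v}, \code{z_w} (gif),
#'   \code{z_a}, and the achieved \code{norm_residual}.
#' @export
prc_adjoint <- function(model, adaptation, cycle, norm_tol = 1e-6) {
  tr <- cycle$trajectory
  n <- nrow(tr)
  h <- cycle$period / (n - 1)
  tau_a <- adaptation$tau_a
  kind <- model$kind

  if (kind == "qif") {
    th_fun <- splinefun(tr$t, tr$theta, method = "natural")
    a_fun <- function(t) cycle$a_star * exp(-t / tau_a)
    rhs <- function(t, z) {
      th <- th_fun(t)
      dfdth <- sin(th) * (1 - model$mu + a_fun(t))
      c(-dfdth * z[1], (1 + cos(th)) * z[1] + z[2] / tau_a)
    }
    z_end <- c(0.5, 0)  # 1/theta_dot at threshold theta = pi
  } else if (kind == "lif") {
    rhs <- function(t, z) c(model$gamma * z[1], z[1] + z[2] / tau_a)
    z_end <- c(1 / threshold_velocity(model, adaptation, cycle), 0)
  } else {
    rhs <- function(t, z) c(model$gamma * z[1] - z[2] / model$tau_w,
                            model$beta_w * z[1] + z[2] / model$tau_w,
                            z[1] + z[3] / tau_a)
    z_end <- c(1 / threshold_velocity(model, adaptation, cycle), 0, 0)
  }

  m <- length(z_end)
  out <- matrix(NA_real_, n, m)
  out[n, ] <- z_end
  z <- z_end
  for (j in seq(n, 2)) {
    t <- tr$t[j]
    k1 <- rhs(t, z)
    k2 <- rhs(t - h / 2, z - h / 2 * k1)
    k3 <- rhs(t - h / 2, z - h / 2 * k2)
    k4 <- rhs(t - h, z - h * k3)
    z <- z - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[j - 1, ] <- z
  }

  a0 <- tr$a
  a0dot <- -a0 / tau_a
  if (kind == "qif") {
    z_theta <- out[, 1]
    z_a <- out[, 2]
    theta_dot <- (1 - cos(tr$theta)) + (1 + cos(tr$theta)) * (model$mu - a0)
    resid <- max(abs(z_theta * theta_dot + z_a * a0dot - 1))
    z_v <- z_theta * (1 + cos(tr$theta))
    grid <- new_prc_grid(tr$t, z_v, z_a = z_a, period = cycle$period,
                         method = "adjoint", kind = kind, z_theta = z_theta,
                         norm_residual = resid)
  } else if (kind == "lif") {
    v_dot <- -model$gamma * tr$v + model$mu - a0
    resid <- max(abs(out[, 1] * v_dot + out[, 2] * a0dot - 1))
    grid <- new_prc_grid(tr$t, out[, 1], z_a = out[, 2], period = cycle$period,
                         method = "adjoint", kind = kind, norm_residual = resid)
  } else {
    v_dot <- -model$gamma * tr$v - model$beta_w * tr$w + model$mu - a0
    w_dot <- (tr$v - tr$w) / model$tau_w
    resid <- max(abs(out[, 1] * v_dot + out[, 2] * w_dot + out[, 3] * a0dot - 1))
    grid <- new_prc_grid(tr$t, out[, 1], z_w = out[, 2], z_a = out[, 3],
                         period = cycle$period, method = "adjoint", kind = kind,
                         norm_residual = resid)
  }
  if (is.finite(resid) && resid > norm_tol)
    stop_cfg("adjoint normalization residual %g exceeds tolerance %g", resid, norm_tol)
  grid
}

#' Direct (delta-kick) PRC estimate
#'
#' Applies an instantaneous voltage kick of size \code{epsilon} at each
#' requested phase of the deterministic limit cycle and measures the shift of
#' the next spike, \eqn{Z(\tau) \approx -\delta T(\tau,\epsilon)/\epsilon}.
#' Two kick sizes (\code{epsilon} and \code{epsilon/2}) are combined by
#' Richardson extrapolation toward \eqn{\epsilon \to 0}, removing the
#' leading \eqn{O(\epsilon)} bias. The unperturbed return time is computed by
#' the same integrator so that discretization errors cancel in the
#' difference.
#'
#' @inheritParams prc_adjoint
#' @param epsilon kick amplitude (> 0); the second kick is half of it.
#' @param phases phases in \eqn{[0, T^*]} at which to estimate \eqn{Z}.
#' @return a \code{"prc_grid"} with \code{z_v} at the requested phases.
#' @export
prc_direct <- function(model, adaptation, cycle, epsilon = 1e-4,
                       phases = seq(0, cycle$period, length.out = 33)) {
  if (epsilon <= 0)
    stop_cfg("epsilon must be positive: the PRC is defined as a limit of finite kicks")
  if (any(phases < 0 | phases > cycle$period))
    stop_cfg("phases must lie within [0, T*]")
  pars <- if_pars(model, adaptation)
  tr <- cycle$trajectory
  qif <- model$kind == "qif"
  xs <- if (qif) tr$theta else tr$v
  x_fun <- splinefun(tr$t, xs, method = "natural")
  w_fun <- if (model$kind == "gif") splinefun(tr$t, tr$w, method = "natural")
  h_int <- cycle$period / 4096

  kick <- function(x, eps) {
    if (!qif) return(x + eps)
    half <- cos(x / 2)
    if (abs(half) < 1e-8) return(x)   # |v| = infinity: a finite kick is void
    2 * atan(tan(x / 2) + eps)
  }
  one <- function(tau, eps) {
    x0 <- x_fun(tau)
    w0 <- if (model$kind == "gif") w_fun(tau) else model$w_reset
    a0 <- cycle$a_star * exp(-tau / adaptation$tau_a)
    s0 <- if_cross_from_cpp(pars, x0, w0, a0, h_int, 10 * cycle$period + 1)
    s1 <- if_cross_from_cpp(pars, kick(x0, eps), w0, a0, h_int,
                            10 * cycle$period + 1)
    if (is.na(s1))
      stop_cfg("kicked trajectory failed to fire at phase %g (epsilon %g)", tau, eps)
    -(s1 - s0) / eps
  }
  z1 <- vapply(phases, one, numeric(1), eps = epsilon)
  z2 <- vapply(phases, one, numeric(1), eps = epsilon / 2)
  z <- 2 * z2 - z1
  new_prc_grid(phases, z, period = cycle$period, method = "direct",
               kind = model$kind)
}

#' Finite Fourier transform of a PRC
#'
#' \deqn{\tilde Z(\omega) = \frac{1}{T^*}\int_0^{T^*} Z(\tau)
#' e^{-i\omega\tau}\,d\tau,} evaluated by the trapezoid rule on the PRC grid.
#' \eqn{\tilde Z(0)} is the mean of \eqn{Z} and
#' \eqn{\tilde Z(-\omega) = \overline{\tilde Z(\omega)}}.
#'
#' @param prc a \code{"prc_grid"} on a uniform grid.
#' @param omegas angular frequencies.
#' @return object of class \code{"prc_transform"}: list with \code{omega} and
#'   complex \code{z_tilde}.
#' @export
prc_fourier <- function(prc, omegas) {
  n <- length(prc$tau)
  if (n < 2) stop_cfg("empty or degenerate PRC grid")
  h <- prc$period / (n - 1)
  w <- trapz_weights(n, h) * prc$z_v
  zt <- vapply(omegas, function(om)
    sum(w * exp(-1i * om * prc$tau)), complex(1)) / prc$period
  structure(list(omega = omegas, z_tilde = zt, period = prc$period),
            class = "prc_transform")
}

# |Z~(omega)|^2 on a (possibly long) omega grid, evaluated in chunks to bound
# memory; optionally on a decimated tau grid.
zt_power <- function(prc, omegas, chunk = 4096L) {
  n <- length(prc$tau)
  h <- prc$period / (n - 1)
  w <- trapz_weights(n, h) * prc$z_v
  out <- numeric(length(omegas))
  for (i in seq(1, length(omegas), by = chunk)) {
    j <- i:min(i + chunk - 1L, length(omegas))
    ph <- outer(omegas[j], prc$tau)
    re <- cos(ph) %*% w
    im <- sin(ph) %*% w
    out[j] <- (re^2 + im^2)
  }
  out / prc$period^2
}
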