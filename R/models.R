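#' Specify a deterministic integrate-and-fire model
#'
#' Defines the deterministic skeleton of the model family
#' \deqn{\dot v = f_0(v, w) + \mu - a, \qquad \dot w = f_1(v, w),}
#' with the fire-and-reset rule: when \eqn{v} reaches \code{v_threshold} a
#' spike is recorded, \eqn{v \to} \code{v_reset}, \eqn{w \to} \code{w_reset},
#' and the adaptation variable jumps by \eqn{\Delta/\tau_a}.
#'
#' Supported kinds: \code{"lif"} with \eqn{f_0 = -\gamma v}; \code{"qif"} with
#' \eqn{f_0 = v^2} and threshold/reset at \eqn{\pm\infty} (integrated
#' internally as the theta neuron via \eqn{\theta = 2\,\mathrm{atan}(v)});
#' \code{"gif"} with \eqn{f_0 = -\gamma v - \beta_w w},
#' \eqn{f_1 = (v - w)/\tau_w}.
#'
#' @param kind one of \code{"lif"}, \code{"qif"}, \code{"gif"}.
#' @param mu constant drive current (dimensionless).
#' @param gamma leak coefficient (lif/gif; may be negative for the gif).
#' @param beta_w coupling of the auxiliary variable (gif).
#' @param tau_w time constant of the auxiliary variable (gif, > 0).
#' @param v_threshold,v_reset firing threshold and reset voltage. Ignored for
#'   \code{"qif"}, whose threshold and reset sit at plus/minus infinity.
#' @param w_reset reset value of the auxiliary variable (gif).
#' @return an object of class \code{"if_model"}.
#' @examples
#' model_spec("lif", mu = 5)
#' model_spec("gif", mu = 20, gamma = 1, beta_w = 1.5, tau_w = 1.5)
#' @export
model_spec <- function(kind = c("lif", "qif", "gif"), mu,
                       gamma = 1, beta_w = 0, tau_w = 1,
                       v_threshold = 1, v_reset = 0, w_reset = 0) {
  kind <- match.arg(kind)
  check_scalar(mu, "mu")
  if (kind == "gif") {
    check_scalar(tau_w, "tau_w", lower = .Machine$double.eps)
    check_scalar(beta_w, "beta_w")
  }
  if (kind == "qif") {
    v_threshold <- Inf
    v_reset <- -Inf
  } else {
    check_scalar(v_threshold, "v_threshold")
    check_scalar(v_reset, "v_reset")
    if (v_reset >= v_threshold) stop_cfg("v_reset must lie below v_threshold")
  }
  structure(list(kind = kind, mu = mu, gamma = gamma, beta_w = beta_w,
                 tau_w = tau_w, v_threshold = v_threshold, v_reset = v_reset,
                 w_reset = w_reset),
            class = "if_model")
}

#' Specify the spike-triggered adaptation current
#'
#' Between spikes the adaptation current relaxes as
#' \eqn{\tau_a \dot a = -a}; at each spike it jumps by \eqn{\Delta/\tau_a}.
#' \code{delta = 0} encodes the absence of adaptation.
#'
#' @param tau_a adaptation time constant (> 0).
#' @param delta total jump parameter \eqn{\Delta \ge 0} (the per-spike
#'   increment of \eqn{a} is \eqn{\Delta/\tau_a}).
#' @return an object of class \code{"adaptation"}.
#' @export
adaptation_spec <- function(tau_a = 1, delta = 0) {
  check_scalar(tau_a, "tau_a", lower = .Machine$double.eps)
  check_scalar(delta, "delta", lower = 0)
  structure(list(tau_a = tau_a, delta = delta), class = "adaptation")
}

# integer model code + parameter list handed to the C++ integrators
if_pars <- function(model, adaptation) {
  list(kind = match(model$kind, c("lif", "qif", "gif")) - 1L,
       mu = model$mu, gamma = model$gamma, beta_w = model$beta_w,
       tau_w = model$tau_w, v_threshold = model$v_threshold,
       v_reset = model$v_reset, w_reset = model$w_reset,
       tau_a = adaptation$tau_a)
}

#' Deterministic drift of the model
#'
#' Evaluates the noiseless vector field at a state, without applying the
#' fire-and-reset rule: \eqn{(\dot v, \dot w, \dot a) =
#' (f_0(v,w) + \mu - a,\; f_1(v,w),\; -a/\tau_a)}.
#'
#' @param model an [model_spec()] object.
#' @param adaptation an [adaptation_spec()] object.
#' @param state named or positional numeric vector \code{c(v, w, a)}; \code{w}
#'   and \code{a} default to 0 when omitted.
#' @return named numeric vector \code{c(v = dv, w = dw, a = da)}.
#' @examples
#' if_drift(model_spec("lif", mu = 5), adaptation_spec(), c(v = 0))
#' @export
if_drift <- function(model, adaptation, state) {
  if (!inherits(model, "if_model")) stop_cfg("unknown model kind")
  v <- unname(if (!is.null(names(state))) state[["v"]] else state[1])
  w <- unname(if (!is.null(names(state)) && "w" %in% names(state)) state[["w"]]
              else if (length(state) >= 2) state[2] else 0)
  a <- unname(if (!is.null(names(state)) && "a" %in% names(state)) state[["a"]]
              else if (length(state) >= 3) state[3] else 0)
  if (!all(is.finite(c(v, w, a)))) stop_cfg("state must be finite")
  dv <- switch(model$kind,
    lif = -model$gamma * v + model$mu - a,
    qif = v^2 + model$mu - a,
    gif = -model$gamma * v - model$beta_w * w + model$mu - a)
  dw <- if (model$kind == "gif") (v - w) / model$tau_w else 0
  c(v = dv, w = dw, a = -a / adaptation$tau_a)
}

#' Deterministic peak adaptation value
#'
#' On the limit cycle the adaptation current right after a spike settles at
#' \deqn{a^* = \frac{\Delta/\tau_a}{1 - e^{-T^*/\tau_a}}.}
#'
#' @param delta total jump parameter \eqn{\Delta \ge 0}.
#' @param tau_a adaptation time constant (> 0).
#' @param period deterministic firing period \eqn{T^*} (> 0).
#' @return the fixed point \eqn{a^*}; 0 when \code{delta = 0}.
#' @export
peak_adaptation <- function(delta, tau_a, period) {
  check_scalar(delta, "delta", lower = 0)
  check_scalar(tau_a, "tau_a", lower = .Machine$double.eps)
  if (!is.numeric(period) || length(period) != 1L || is.na(period) || period <= 0)
    stop_cfg("period must be positive")
  if (delta == 0) return(0)
  (delta / tau_a) / (1 - exp(-period / tau_a))
}

# crossing time of the noiseless model for a frozen peak-adaptation value
if_cross_time <- function(pars, a_star, h, horizon) {
  res <- if_cross_cpp(pars, a_star, h, horizon)
  if (is.na(res[1])) return(NULL)
  list(time = res[1], x = res[2], w = res[3])
}

#' Find the deterministic limit cycle
#'
#' Solves for the self-consistent pair \eqn{(T^*, a^*)} of the noiseless
#' model: integrating from the reset point with the adaptation current
#' \eqn{a(t) = a^* e^{-t/\tau_a}} must reach the threshold at \eqn{t = T^*},
#' while \eqn{a^*} equals its fixed point [peak_adaptation()]. Because
#' \eqn{a^*(T)} is strictly decreasing and the crossing time is increasing in
#' the adaptation level, the residual \eqn{g(T) = T_{cross}(a^*(T)) - T} is
#' monotone and the solution is found by bracketed root finding; this remains
#' robust for strong adaptation (\eqn{\nu < 0}), where the voltage initially
#' moves away from the threshold and plain fixed-point iteration on
#' \eqn{a^*} can cycle.
#'
#' @param model an [model_spec()] object (must be tonically firing).
#' @param adaptation an [adaptation_spec()] object.
#' @param tolerance convergence tolerance on \eqn{a^*} (and \eqn{T^*}).
#' @param n_grid points of the returned trajectory grid per period (also the
#'   number of RK4 steps per period used by the final integration).
#' @param horizon maximum integration time before declaring the model not
#'   tonically firing.
#' @return an object of class \code{"limit_cycle"}: a list with
#'   \code{period}, \code{a_star}, \code{w_at_threshold}, \code{v_dot_end}
#'   (velocity at threshold, just before reset), the sampled
#'   \code{trajectory} (data frame \code{t, v, w, a}; for the qif
#'   additionally \code{theta}), and the input specs.
#' @examples
#' lc <- find_limit_cycle(model_spec("lif", mu = 5), adaptation_spec())
#' lc$period  # equals log(5/4)
#' @export
find_limit_cycle <- function(model, adaptation, tolerance = 1e-10,
                             n_grid = 4096, horizon = 500) {
  pars <- if_pars(model, adaptation)
  tau_a <- adaptation$tau_a
  delta <- adaptation$delta
  h0 <- 2e-3 * max(1, if (model$kind == "gif") model$tau_w else 1)

  cross_refined <- function(a_star, h_guess) {
    cr <- if_cross_time(pars, a_star, h_guess, horizon)
    if (is.null(cr))
      stop_cfg("not tonically firing: no threshold crossing within horizon %g",
               horizon)
    # refine with a step tied to the period found
    if_cross_time(pars, a_star, cr$time / 2048, 2 * cr$time)$time
  }

  if (delta == 0) {
    period <- cross_refined(0, h0)
    a_star <- 0
  } else {
    a_min <- delta / tau_a  # the T -> Inf limit of the fixed point
    t_ref <- cross_refined(a_min, h0)
    cross_a <- function(a) {
      cr <- if_cross_time(pars, a, t_ref / 1024, horizon)
      if (is.null(cr)) NA_real_ else cr$time
    }
    # residual of the self-consistency condition in a*; crossing failure at
    # large a means the fixed point lies below (treat as negative residual)
    f_res <- function(a) {
      tc <- cross_a(a)
      if (is.na(tc)) return(-a)
      (delta / tau_a) / (1 - exp(-tc / tau_a)) - a
    }
    a_hi <- a_min * 2 + 1e-12
    it <- 0
    while (f_res(a_hi) > 0) {
      a_hi <- a_hi * 2
      it <- it + 1
      if (it > 60) stop_cfg("limit-cycle solver failed to bracket a*")
    }
    a_star <- uniroot(f_res, c(a_min, a_hi), tol = min(tolerance, 1e-12))$root
    period <- cross_a(a_star)
    if (is.na(period) || abs(f_res(a_star)) > 1e4 * max(tolerance, 1e-13) * max(1, a_star))
      stop_cfg("limit-cycle solver did not converge (residual %g at a* = %g)",
               f_res(a_star), a_star)
    a_star <- (delta / tau_a) / (1 - exp(-period / tau_a))
  }

  traj <- if_traj_cpp(pars, a_star, period, as.integer(n_grid))
  t <- traj[, 1]
  a0 <- a_star * exp(-t / tau_a)
  if (model$kind == "qif") {
    theta <- traj[, 2]
    v <- tan(theta / 2)
    trajectory <- data.frame(t = t, v = v, w = traj[, 3], a = a0, theta = theta)
    v_dot_end <- Inf  # v blows up at the threshold; theta velocity is finite
    theta_dot_end <- (1 - cos(pi)) + (1 + cos(pi)) * (model$mu - a0[length(a0)])
  } else {
    trajectory <- data.frame(t = t, v = traj[, 2], w = traj[, 3], a = a0)
    end <- nrow(trajectory)
    d <- if_drift(model, adaptation,
                  c(v = trajectory$v[end], w = trajectory$w[end], a = a0[end]))
    v_dot_end <- unname(d["v"])
    theta_dot_end <- NA_real_
  }
  structure(list(period = period, a_star = a_star,
                 w_at_threshold = trajectory$w[nrow(trajectory)],
                 v_dot_end = v_dot_end, theta_dot_end = theta_dot_end,
                 trajectory = trajectory, n_grid = n_grid,
                 model = model, adaptation = adaptation),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("Deterministic limit cycle (%s): T* = %.6g, a* = %.6g\n",
              x$model$kind, x$period, x$a_star))
  invisible(x)
}

# closed-form period of the non-adaptive LIF (used in tests and as a solver
# cross-check): T* = (1/gamma) log((mu - gamma v_R)/(mu - gamma v_T))
lif_period_exact <- function(mu, gamma = 1, v_reset = 0, v_threshold = 1) {
  num <- mu - gamma * v_reset
  den <- mu - gamma * v_threshold
  if (den <= 0) stop_cfg("not tonically firing: mu <= gamma * v_threshold")
  log(num / den) / gamma
}
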