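#' Traub-Miles model parameters
#'
#' Parameter set for the Traub-Miles conductance-based neuron with a slow
#' M-type potassium adaptation current
#' \eqn{I_{adap} = \bar g\, z\,(V - E_K)},
#' \eqn{\tau_z \dot z = h_\infty(V) - z} with
#' \eqn{h_\infty(V) = 1/(1+e^{-(V+20)/5})}. Defaults are the simulation
#' values of the tonically firing regime (units: mV, ms, \eqn{\mu}A/cm^2,
#' mS/cm^2). The membrane capacitance is 1 \eqn{\mu}F/cm^2, fixed by the
#' convention that \eqn{a^* = I_{adap}/C} is reported in mV/ms.
#'
#' @param I injected current (\eqn{\mu}A/cm^2).
#' @param g_na,g_k,g_l,g_bar maximal conductances of the sodium, delayed
#'   rectifier, leak and M currents (mS/cm^2).
#' @param e_na,e_k,e_l reversal potentials (mV).
#' @param tau_z adaptation gating time constant (ms).
#' @param capacitance membrane capacitance (\eqn{\mu}F/cm^2).
#' @param d_white white-noise intensity ((\eqn{\mu}A/cm)^2 ms).
#' @param sigma2 OU variance ((\eqn{\mu}A/cm)^2).
#' @param tau_eta OU correlation time (ms).
#' @return an object of class \code{"tm_params"}.
#' @export
tm_params <- function(I = 5, g_na = 100, g_k = 80, g_l = 0.1, g_bar = 5,
                      e_na = 50, e_k = -100, e_l = -67, tau_z = 100,
                      capacitance = 1, d_white = 0.1, sigma2 = 0.1,
                      tau_eta = 10) {
  for (nm in c("g_na", "g_k", "g_l", "g_bar"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(tau_z, "tau_z", lower = .Machine$double.eps)
  structure(list(I = I, g_na = g_na, g_k = g_k, g_l = g_l, g_bar = g_bar,
                 e_na = e_na, e_k = e_k, e_l = e_l, tau_z = tau_z,
                 capacitance = capacitance, d_white = d_white,
                 sigma2 = sigma2, tau_eta = tau_eta),
            class = "tm_params")
}

tm_par_vec <- function(p) {
  c(p$capacitance, p$I, p$g_na, p$g_k, p$g_l, p$g_bar, p$e_na, p$e_k, p$e_l,
    p$tau_z, p$d_white, p$sigma2, p$tau_eta)
}

#' Gating rate functions of the Traub-Miles model
#'
#' Evaluates \eqn{a_x(V)}, \eqn{b_x(V)} for \eqn{x \in \{h, m, n\}} and the
#' steady state \eqn{h_\infty(V)} of the adaptation gate. Rates with a
#' removable singularity (e.g. \eqn{a_m} at \eqn{V = -54} mV) are evaluated
#' through their analytic limit.
#'
#' @param V membrane potential (mV, vectorized).
#' @return data frame with one row per voltage.
#' @export
tm_rates <- function(V) {
  out <- t(vapply(V, tm_rates_cpp, numeric(7)))
  as.data.frame(out)
}

#' Deterministic derivatives of the Traub-Miles system
#'
#' \eqn{C\dot V = -I_{ion} - I_{adap} + I}, first-order kinetics for the
#' gating variables, and \eqn{\tau_z\dot z = h_\infty(V) - z}. Noise terms
#' are handled by the stochastic stepper, not here.
#'
#' @param state named numeric vector \code{c(V, h, m, n, z)}.
#' @param params a [tm_params()] object.
#' @param eta_ext additional current (e.g. a frozen colored-noise value).
#' @return named derivative vector.
#' @export
tm_derivatives <- function(state, params, eta_ext = 0) {
  s <- unname(state[c("V", "h", "m", "n", "z")])
  d <- tm_deriv_cpp(tm_par_vec(params), s, eta_ext)
  c(V = d[1], h = d[2], m = d[3], n = d[4], z = d[5])
}

#' Deterministic limit cycle of the Traub-Miles model
#'
#' Integrates the noiseless system (RK4) until the interspike interval has
#' settled, with spikes defined as upward crossings of 0 mV. Returns the
#' period and the effective peak adaptation drive
#' \deqn{a^* = \bar g\, z_{peak}\,(V_{rest} - E_K)/C \quad [mV/ms],}
#' the analog of the peak adaptation value of the integrate-and-fire theory:
#' the slow gate \eqn{z} at its post-spike maximum times the driving force at
#' the subthreshold resting level (for the default parameters the resting
#' potential coincides with the leak reversal \eqn{E_L = -67} mV, which is
#' used as the reference). The raw values of \eqn{I_{adap}/C} at the
#' spike-defining crossing and at its cycle-wide maximum (both inflated by
#' the large spike-time driving force) are returned as diagnostics.
#'
#' @param params a [tm_params()] object.
#' @param dt RK4 step (ms).
#' @param n_spikes number of spikes integrated before the period is read off
#'   (the default comfortably outlasts the \eqn{\sim\tau_z} build-up of the
#'   adaptation gate).
#' @return an object of class \code{"tm_cycle"}.
#' @export
tm_limit_cycle <- function(params, dt = 0.01, n_spikes = 150) {
  res <- tm_limit_cycle_cpp(tm_par_vec(params), dt, n_spikes,
                            max_time = 1e5, step_protocol = FALSE, t_on = 0)
  isis <- res$isis
  n <- length(isis)
  if (n >= 2 && abs(isis[n] - isis[n - 1]) > 1e-4 * isis[n])
    warning("period not fully settled: last two ISIs differ by ",
            format(abs(isis[n] - isis[n - 1])))
  z_peak <- max(res$traj$z)
  a_star <- params$g_bar * z_peak * (params$e_l - params$e_k) /
    params$capacitance
  structure(list(period = res$period, a_star = a_star, z_peak = z_peak,
                 a_star_crossing = res$a_star_cross,
                 a_star_max = res$a_star_max, z_cross = res$z_cross,
                 state_cross = res$state_cross, trajectory = res$traj,
                 isis = isis, dt = dt, params = params),
            class = "tm_cycle")
}

#' @export
print.tm_cycle <- function(x, ...) {
  cat(sprintf("Traub-Miles limit cycle: T* = %.4g ms, a* = %.4g mV/ms\n",
              x$period, x$a_star))
  invisible(x)
}

#' Spike-frequency adaptation under a current step
#'
#' Applies the injected current from \code{t_on} onward (zero before) and
#' returns the sequence of interspike intervals, which increases toward the
#' adapted steady-state period as the slow gate \eqn{z} builds up.
#'
#' @param params a [tm_params()] object.
#' @param t_on current onset time (ms).
#' @param n_spikes spikes to collect.
#' @param dt RK4 step (ms).
#' @return numeric vector of ISIs (ms).
#' @export
tm_step_response <- function(params, t_on = 25, n_spikes = 20, dt = 0.01) {
  res <- tm_limit_cycle_cpp(tm_par_vec(params), dt, n_spikes,
                            max_time = 1e5, step_protocol = TRUE, t_on = t_on)
  res$isis
}

#' Direct PRC of the Traub-Miles model
#'
#' Small instantaneous voltage pulses applied at a set of phases of the
#' deterministic limit cycle; the shift of the next 0 mV upward crossing
#' gives \eqn{Z(\tau) = -\delta T(\tau,\epsilon)/\epsilon}, Richardson
#' extrapolated over \code{epsilon} and \code{epsilon/2}. The unperturbed
#' return time is computed by the same integrator so residual limit-cycle
#' drift cancels.
#'
#' @param params a [tm_params()] object.
#' @param cycle a [tm_limit_cycle()] result (computed if missing).
#' @param epsilon pulse amplitude in mV.
#' @param n_phases number of phases on \eqn{[0, T^*)}.
#' @param dt integration step (ms).
#' @return a \code{"prc_grid"} with \code{z_v} in (mV/ms)^-1.
#' @export
tm_prc <- function(params, cycle = NULL, epsilon = 0.1, n_phases = 128,
                   dt = 0.01) {
  if (epsilon <= 0) stop_cfg("epsilon must be positive")
  if (is.null(cycle)) cycle <- tm_limit_cycle(params, dt = dt)
  pv <- tm_par_vec(params)
  tr <- cycle$trajectory
  tt <- cycle$period
  # kicks exactly at the crossing are ill-defined (the reference spike itself
  # is being triggered); evaluate interior phases and close both endpoints
  # with the boundary condition Z(T*) = Z(0) = 1/dV/dt at the crossing
  phases <- seq(2 * dt, tt - 2 * dt, length.out = n_phases)
  state_at <- function(tau) {
    if (tau <= tr$t[1]) return(as.numeric(cycle$state_cross))
    i <- findInterval(tau, tr$t)
    i2 <- min(i + 1, nrow(tr))
    f <- if (i2 > i) (tau - tr$t[i]) / (tr$t[i2] - tr$t[i]) else 0
    (1 - f) * c(tr$V[i], tr$h[i], tr$m[i], tr$n[i], tr$z[i]) +
      f * c(tr$V[i2], tr$h[i2], tr$m[i2], tr$n[i2], tr$z[i2])
  }
  one <- function(tau, eps) {
    s0 <- state_at(tau)
    base <- tm_cross_from_cpp(pv, s0, dt, 5 * tt)
    s1 <- s0; s1[1] <- s1[1] + eps
    pert <- tm_cross_from_cpp(pv, s1, dt, 5 * tt)
    if (is.na(pert))
      stop_cfg("kicked trajectory failed to fire at phase %g (epsilon %g)",
               tau, eps)
    -(pert - base) / eps
  }
  z1 <- vapply(phases, one, numeric(1), eps = epsilon)
  z2 <- vapply(phases, one, numeric(1), eps = epsilon / 2)
  z <- 2 * z2 - z1
  d_cross <- tm_deriv_cpp(pv, as.numeric(cycle$state_cross), 0)
  z_end <- 1 / d_cross[1]
  new_prc_grid(c(0, phases, tt), c(z_end, z, z_end), period = tt,
               method = "direct", kind = "traub_miles")
}

#' Map the Traub-Miles model into the SCC theory
#'
#' Builds a theory context from the numerically measured period, peak
#' adaptation drive \eqn{a^* = I_{adap}/C} and PRC, identifying the
#' adaptation time scale with the gating time constant,
#' \eqn{\tau_a = \tau_z}. [scc_general()], [cv_theory()] etc. then apply
#' unchanged.
#'
#' @param params a [tm_params()] object.
#' @param prc a [tm_prc()] result (computed if missing).
#' @param cycle a [tm_limit_cycle()] result (computed if missing).
#' @param noise optional [noise_spec()] override; defaults to the noise
#'   parameters stored in \code{params}.
#' @param a_star optional override of the peak adaptation drive (e.g. 0 to
#'   obtain the no-adaptation reduction \eqn{\rho_k = \rho_{k,\eta}}).
#' @return a \code{"theory_context"}.
#' @export
tm_theory_adapter <- function(params, prc = NULL, cycle = NULL, noise = NULL,
                              a_star = NULL) {
  if (is.null(cycle)) cycle <- tm_limit_cycle(params)
  if (is.null(prc)) prc <- tm_prc(params, cycle)
  if (is.null(noise))
    noise <- noise_spec(d_white = params$d_white, sigma2 = params$sigma2,
                        tau_eta = params$tau_eta)
  # resample the PRC on a fine uniform grid for the quadratures
  tau <- seq(0, cycle$period, length.out = 2049)
  z <- spline(prc$tau, prc$z_v, xout = tau)$y
  prc_fine <- new_prc_grid(tau, z, period = cycle$period, method = prc$method,
                           kind = "traub_miles")
  new_theory_context(prc_fine, cycle$period,
                     a_star %||% cycle$a_star, params$tau_z, noise)
}

#' Stochastic simulation of the Traub-Miles model
#'
#' Euler-Maruyama integration with white current noise and OU colored noise,
#' started on the deterministic limit cycle; spikes are upward crossings of
#' 0 mV with a 2 ms lockout.
#'
#' @param params a [tm_params()] object.
#' @param n_spikes spikes to collect (after discarding \code{n_burn}).
#' @param dt step size (ms).
#' @param seed integer seed.
#' @param n_burn initial spikes discarded.
#' @param cycle optional precomputed [tm_limit_cycle()].
#' @return a \code{"spike_train"} (times in ms).
#' @export
tm_simulate <- function(params, n_spikes = 5000, dt = 0.005, seed = 1,
                        n_burn = 20, cycle = NULL) {
  if (is.null(cycle)) cycle <- tm_limit_cycle(params)
  set.seed(seed)
  spikes <- sim_tm_cpp(tm_par_vec(params), as.numeric(cycle$state_cross),
                       dt, as.integer(n_spikes + n_burn),
                       max_time = 1e3 * (n_spikes + n_burn) * cycle$period,
                       lockout = 2)
  new_spike_train(spikes[-seq_len(n_burn)],
                  meta = list(params = params, dt = dt, seed = seed,
                              n_burn = n_burn))
}
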