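#' Simulation controls
#'
#' @param dt Euler-Maruyama step size (default 1e-4; halve it to check
#'   step-size robustness).
#' @param n_spikes number of spikes to collect (>= 2).
#' @param seed integer seed for the RNG.
#' @param max_time wall-clock model-time budget; exceeded means the model is
#'   not firing under the given parameters.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 1e-4, n_spikes = 10000, seed = 1,
                       max_time = Inf) {
  check_scalar(dt, "dt", lower = .Machine$double.eps)
  if (n_spikes < 2) stop_cfg("n_spikes must be >= 2")
  structure(list(dt = dt, n_spikes = as.integer(n_spikes),
                 seed = as.integer(seed), max_time = max_time),
            class = "sim_config")
}

#' Simulate the full stochastic model
#'
#' Euler-Maruyama integration of the stochastic integrate-and-fire system
#' with spike-triggered adaptation and OU colored noise. Initial conditions
#' sit on the deterministic limit cycle (\eqn{v_0 = v_R}, \eqn{w_0 = w_R},
#' \eqn{a_0 = a^*}, \eqn{\eta_0 = 0}), which suppresses transients. Spike
#' times are located by linear interpolation within the crossing step; at a
#' spike \eqn{v \to v_R}, \eqn{w \to w_R} and \eqn{a \to a + \Delta/\tau_a}.
#'
#' The QIF is integrated in theta coordinates when \eqn{D = 0} (the smooth
#' colored drive transforms exactly); with white noise it is integrated in
#' \eqn{v} with numerical bounds \eqn{\pm}\code{v_bound} standing in for
#' \eqn{\pm\infty} and the asymptotic \eqn{1/v} crossing-time correction.
#' In green mode the OU and white sources share one increment per step with
#' opposite signs (exact anti-correlation).
#'
#' @param model an [model_spec()] object.
#' @param adaptation an [adaptation_spec()] object.
#' @param noise a [noise_spec()] object.
#' @param sim a [sim_config()] object.
#' @param cycle optional precomputed [find_limit_cycle()] (used for the
#'   initial adaptation value \eqn{a^*}).
#' @param v_bound numerical stand-in for the infinite QIF threshold.
#' @return an object of class \code{"spike_train"}: list with
#'   \code{spike_times}, \code{isis} and \code{meta} (full provenance).
#' @export
simulate_train <- function(model, adaptation, noise, sim, cycle = NULL,
                           v_bound = 1000) {
  stopifnot(inherits(model, "if_model"), inherits(adaptation, "adaptation"),
            inherits(noise, "noise_spec"), inherits(sim, "sim_config"))
  if (noise$mode == "shared_channel" &&
      abs(adaptation$tau_a - noise$tau_eta) > 1e-12 * max(1, adaptation$tau_a))
    stop_cfg("shared_channel mode requires tau_a = tau_eta")
  a0 <- if (adaptation$delta > 0) {
    if (is.null(cycle)) cycle <- find_limit_cycle(model, adaptation, n_grid = 512)
    cycle$a_star
  } else 0
  theta_mode <- model$kind == "qif" && noise$d_white == 0
  pars <- if_pars(model, adaptation)
  set.seed(sim$seed)
  spikes <- sim_if_cpp(pars, adaptation$delta / adaptation$tau_a, a0,
                       noise$d_white, noise$sigma2, noise$tau_eta,
                       if (noise$mode == "green") 1L else 0L,
                       sim$dt, sim$n_spikes, theta_mode, v_bound,
                       sim$max_time)
  new_spike_train(spikes, meta = list(model = model, adaptation = adaptation,
                                      noise = noise, sim = sim,
                                      a_star = a0, theta_mode = theta_mode))
}

new_spike_train <- function(spike_times, meta = list()) {
  if (is.unsorted(spike_times, strictly = TRUE))
    stop_cfg("spike times must be strictly increasing")
  structure(list(spike_times = spike_times, isis = diff(spike_times),
                 meta = meta),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes, mean ISI %.5g, CV %.3g\n",
              length(x$spike_times), mean(x$isis),
              sd(x$isis) / mean(x$isis)))
  invisible(x)
}

isis_of <- function(x) {
  if (inherits(x, "spike_train")) x$isis
  else if (is.numeric(x)) x
  else stop_cfg("expected a spike_train or a numeric ISI vector")
}

# delete-one-block jackknife over non-overlapping ISI blocks
block_jackknife <- function(x, stat, block = 100L) {
  n <- length(x)
  nb <- max(2L, n %/% block)
  idx <- split(seq_len(n), cut(seq_len(n), nb, labels = FALSE))
  reps <- vapply(idx, function(i) stat(x[-i]), numeric(1))
  sqrt((nb - 1) / nb * sum((reps - mean(reps))^2))
}

#' Estimate serial correlation coefficients of the ISIs
#'
#' Sample SCC
#' \eqn{\hat\rho_k = \sum_i (T_i - \bar T)(T_{i+k} - \bar T) /
#' \sum_i (T_i - \bar T)^2} using the overall sample mean, with standard
#' errors by delete-one-block jackknife over non-overlapping blocks (the
#' default block of 100 ISIs exceeds the correlation length of all model
#' setups considered here).
#'
#' @param train a \code{"spike_train"} or numeric ISI vector.
#' @param k_max largest lag.
#' @param block jackknife block length in ISIs.
#' @return data frame with \code{lag} (0..k_max), \code{rho_hat}, \code{se};
#'   lag 0 has \code{rho_hat = 1}.
#' @export
estimate_scc <- function(train, k_max = 5, block = 100L) {
  x <- isis_of(train)
  n <- length(x)
  if (n < k_max + 2) stop_cfg("need at least k_max + 2 ISIs")
  if (var(x) == 0) stop_cfg("undefined SCC: ISI variance is zero")
  scc_of <- function(y, k) {
    d <- y - mean(y)
    sum(d[1:(length(y) - k)] * d[(1 + k):length(y)]) / sum(d^2)
  }
  rho <- vapply(seq_len(k_max), function(k) scc_of(x, k), numeric(1))
  se <- vapply(seq_len(k_max), function(k)
    block_jackknife(x, function(y) scc_of(y, k), block), numeric(1))
  data.frame(lag = 0:k_max, rho_hat = c(1, rho), se = c(0, se))
}

#' Estimate the coefficient of variation of the ISIs
#'
#' Sample standard deviation over sample mean, standard error by
#' delete-one-block jackknife.
#'
#' @inheritParams estimate_scc
#' @return list with \code{cv}, \code{se} and \code{n}.
#' @export
estimate_cv <- function(train, block = 100L) {
  x <- isis_of(train)
  if (length(x) < 2) stop_cfg("need at least 2 ISIs")
  cv_of <- function(y) sd(y) / mean(y)
  list(cv = cv_of(x), se = block_jackknife(x, cv_of, block), n = length(x))
}

#' Spike-count Fano factor in a fixed window
#'
#' Variance-to-mean ratio of spike counts in consecutive windows of length
#' \code{window}. For long windows it approaches \eqn{S(0)/r_0}, the
#' low-frequency limit of the spike-train power spectrum over the rate.
#'
#' @param train a \code{"spike_train"}.
#' @param window window length (same time units as the spike times).
#' @return list with \code{fano}, \code{n_windows}, \code{mean_count}.
#' @export
estimate_fano <- function(train, window) {
  st <- train$spike_times
  t_total <- st[length(st)] - st[1]
  n_win <- floor(t_total / window)
  if (n_win < 2) stop_cfg("window too long: fewer than 2 windows")
  idx <- 1L + floor((st - st[1]) / window)
  counts <- tabulate(idx[idx <= n_win], n_win)  # drop the partial tail window
  list(fano = var(counts) / mean(counts), n_windows = n_win,
       mean_count = mean(counts))
}

#' Simulate a stationary Ornstein-Uhlenbeck path
#'
#' Exact discrete-time update \eqn{\eta_{j+1} = \phi\eta_j +
#' \sigma\sqrt{1-\phi^2}\,\varepsilon_j} with \eqn{\phi = e^{-dt/\tau_\eta}},
#' started from the stationary distribution.
#'
#' @param n number of samples.
#' @param dt sampling step.
#' @param tau_eta correlation time.
#' @param sigma2 stationary variance.
#' @param seed optional integer seed.
#' @return numeric vector of length \code{n}.
#' @export
simulate_ou <- function(n, dt, tau_eta, sigma2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- exp(-dt / tau_eta)
  innov <- rnorm(n, sd = sqrt(sigma2 * (1 - phi^2)))
  innov[1] <- rnorm(1, sd = sqrt(sigma2))
  as.numeric(filter(innov, phi, method = "recursive"))
}

#' Monte-Carlo oracle for the SCC via the linearized stochastic map
#'
#' Independent route to the general SCC: the deviations of the peak
#' adaptation values follow the linear map
#' \eqn{\delta a_{i+1} = (\alpha\nu)\,\delta a_i +
#' (\alpha a^*/\tau_a)(H_i + \Xi_i)}, where \eqn{H_i} is the PRC-weighted
#' integral of the OU noise over the i-th interval and \eqn{\Xi_i} the
#' corresponding white-noise integral. Here the \eqn{H_i} are generated
#' honestly from a simulated OU path sampled on a fine grid (so their whole
#' joint correlation structure, with
#' \eqn{\langle H_iH_{i+k}\rangle = \beta^{k-1}\langle H_iH_{i+1}\rangle},
#' emerges rather than being imposed), interval deviations are recovered via
#' \eqn{\delta T_{i+1} = (\tau_a/a^*)(\delta a_i - e^{T^*/\tau_a}
#' \delta a_{i+1})}, and the SCC is estimated from them.
#'
#' Requires adaptation (\eqn{\Delta > 0}); for \eqn{\Delta = 0} use
#' [scc_colored()] directly. Only the independent noise mode is supported
#' (the figure setups it validates use independent sources).
#'
#' @param ctx a [build_context()] result with \code{a_star > 0}.
#' @param n number of intervals to simulate.
#' @param seed integer seed.
#' @param k_max largest lag.
#' @param m_sub OU sampling points per period.
#' @param n_segments segments used for the Monte-Carlo standard error.
#' @return data frame with \code{lag}, \code{rho}, \code{se}.
#' @export
map_oracle <- function(ctx, n = 30000, seed = 1, k_max = 5, m_sub = 256L,
                       n_segments = 20L) {
  if (is.null(ctx$a_star) || ctx$a_star <= 0)
    stop_cfg("map_oracle requires adaptation (a_star > 0)")
  m <- ctx$alpha * ctx$nu
  if (abs(m) >= 1) stop_cfg("stochastic map unstable: |alpha*nu| >= 1")
  if (ctx$noise$mode == "green")
    stop_cfg("map_oracle supports independent noise sources only")
  set.seed(seed)
  tt <- ctx$period
  prc <- ctx$prc
  # PRC resampled on the sub-grid
  tau_sub <- seq(0, tt, length.out = m_sub + 1L)
  z_sub <- spline(prc$tau, prc$z_v, xout = tau_sub)$y
  h <- tt / m_sub
  wts <- trapz_weights(m_sub + 1L, h)

  noise <- ctx$noise
  if (noise$sigma2 > 0) {
    eta <- simulate_ou(n * m_sub + 1L, h, noise$tau_eta, noise$sigma2)
    idx <- outer(0:m_sub, (0:(n - 1)) * m_sub, "+") + 1L
    hi <- as.numeric((wts * z_sub) %*% matrix(eta[idx], nrow = m_sub + 1L))
    rm(idx)
  } else hi <- numeric(n)
  xi <- if (noise$d_white > 0)
    rnorm(n, sd = sqrt(2 * noise$d_white * ctx$int_z2)) else numeric(n)

  q <- ctx$alpha * ctx$a_star / ctx$tau_a
  da <- as.numeric(filter(q * (hi + xi), m, method = "recursive"))
  dT <- (ctx$tau_a / ctx$a_star) *
    (da[-length(da)] - exp(tt / ctx$tau_a) * da[-1])
  burn <- min(200L, length(dT) %/% 10L)  # map relaxation from delta_a_0 = 0
  dT <- dT[-seq_len(burn)]

  scc_of <- function(y, k) {
    d <- y - mean(y)
    sum(d[1:(length(y) - k)] * d[(1 + k):length(y)]) / sum(d^2)
  }
  rho <- vapply(seq_len(k_max), function(k) scc_of(dT, k), numeric(1))
  seg <- split(dT, cut(seq_along(dT), n_segments, labels = FALSE))
  se <- vapply(seq_len(k_max), function(k) {
    reps <- vapply(seg, function(s) scc_of(s, k), numeric(1))
    sd(reps) / sqrt(length(reps))
  }, numeric(1))
  data.frame(lag = seq_len(k_max), rho = rho, se = se)
}
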