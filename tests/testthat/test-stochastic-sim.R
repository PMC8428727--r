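# Euler-Maruyama simulator, ISI estimators and the stochastic-map oracle

test_that("deterministic limit: all ISIs equal the period", {
  m <- model_spec("lif", mu = 5)
  tr <- simulate_train(m, adaptation_spec(), noise_spec(),
                       sim_config(dt = 1e-4, n_spikes = 30, seed = 1))
  expect_lt(diff(range(tr$isis)), 1e-10)
  expect_lt(abs(mean(tr$isis) - log(5 / 4)), 1e-4)  # O(dt) Euler bias
  expect_true(all(diff(tr$spike_times) > 0))
  expect_length(tr$isis, 29)
})

test_that("one-variable IF with white noise generates a renewal train", {
  m <- model_spec("lif", mu = 5)
  tr <- simulate_train(m, adaptation_spec(), noise_spec(d_white = 0.01),
                       sim_config(dt = 1e-4, n_spikes = 8000, seed = 2))
  sc <- estimate_scc(tr, 5)
  expect_true(all(abs(sc$rho_hat[-1]) < 3 * sc$se[-1]))
  expect_equal(sc$rho_hat[1], 1)  # lag 0
})

test_that("QIF colored-noise setup reproduces mean ISI and CV", {
  s <- qif_fig2()
  tr <- simulate_train(s$model, s$adaptation, s$noise,
                       sim_config(dt = 1e-4, n_spikes = 2500, seed = 7))
  expect_within(mean(tr$isis), 3.95, 0.1)
  cv <- estimate_cv(tr)
  expect_within(cv$cv, 0.2, 0.03)
})

test_that("SCC estimator: degenerate and synthetic sequences", {
  # perfectly alternating ISIs: rho_1 -> -1
  alt <- rep(c(1, 2), 500)
  expect_within(estimate_scc(alt, 2)$rho_hat[2], -1, 0.01)
  # shuffling destroys serial order
  s <- qif_fig2()
  tr <- simulate_train(s$model, s$adaptation, s$noise,
                       sim_config(dt = 1e-4, n_spikes = 2000, seed = 3))
  set.seed(99)
  sh <- estimate_scc(sample(tr$isis), 5)
  expect_true(all(abs(sh$rho_hat[-1]) < 3 * sh$se[-1]))
  expect_error(estimate_scc(rep(1, 100), 3), "variance")
  expect_error(estimate_scc(c(1, 2), 5), "at least")
})

test_that("CV estimator: deterministic and exponential reference cases", {
  m <- model_spec("lif", mu = 5)
  trd <- simulate_train(m, adaptation_spec(), noise_spec(),
                        sim_config(dt = 1e-4, n_spikes = 30, seed = 1))
  expect_lt(estimate_cv(trd)$cv, 1e-9)
  set.seed(5)
  expo <- rexp(20000, rate = 2)
  cv <- estimate_cv(expo)
  expect_within(cv$cv, 1, 3 * cv$se + 0.01)
})

test_that("simulated OU process has the specified marginal and memory", {
  n <- 200000; dt <- 0.01; te <- 0.5; s2 <- 0.7
  eta <- simulate_ou(n, dt, te, s2, seed = 11)
  se_var <- s2 * sqrt(2 * (2 * te / dt) / n)  # crude effective-n correction
  expect_within(var(eta), s2, 3 * se_var)
  for (lag in c(10, 50)) {
    emp <- cor(eta[-(1:lag)], eta[-((n - lag + 1):n)])
    expect_within(emp, exp(-lag * dt / te), 0.02)
  }
})

test_that("halving the step changes rho_1 by less than its standard error", {
  s <- lif_weak()
  tr1 <- simulate_train(s$model, s$adaptation, s$noise,
                        sim_config(dt = 2e-4, n_spikes = 6000, seed = 13))
  tr2 <- simulate_train(s$model, s$adaptation, s$noise,
                        sim_config(dt = 1e-4, n_spikes = 6000, seed = 13))
  s1 <- estimate_scc(tr1, 1); s2 <- estimate_scc(tr2, 1)
  expect_lt(abs(s1$rho_hat[2] - s2$rho_hat[2]),
            2 * sqrt(s1$se[2]^2 + s2$se[2]^2))
})

test_that("green mode uses exactly anti-correlated increments", {
  # with D = tau_eta sigma^2 the low-frequency input power cancels; the
  # resulting rho_1 must be more negative than in independent mode
  m <- model_spec("lif", mu = 5)
  ad0 <- adaptation_spec(2, 0)
  ns_g <- noise_spec(d_white = 0.1, sigma2 = 0.1 / 0.25, tau_eta = 0.25,
                     mode = "green")
  ns_i <- noise_spec(d_white = 0.1, sigma2 = 0.1 / 0.25, tau_eta = 0.25)
  tr_g <- simulate_train(m, ad0, ns_g, sim_config(1e-4, 8000, seed = 17))
  tr_i <- simulate_train(m, ad0, ns_i, sim_config(1e-4, 8000, seed = 17))
  r_g <- estimate_scc(tr_g, 1)$rho_hat[2]
  r_i <- estimate_scc(tr_i, 1)$rho_hat[2]
  expect_lt(r_g, 0)
  expect_gt(r_i, 0)
  ctx <- build_context(m, ad0, ns_g)
  expect_within(r_g, scc_general(ctx, 1)$rho, 3 * estimate_scc(tr_g, 1)$se[2] + 0.02)
})

test_that("map oracle reproduces the closed forms", {
  # sigma = 0: matches the pure-adaptation geometric sequence
  s0 <- lif_weak()
  ctx0 <- build_context(s0$model, s0$adaptation, noise_spec(d_white = 0.01))
  mo0 <- map_oracle(ctx0, n = 30000, seed = 3)
  th0 <- scc_adaptation(ctx0$alpha, ctx0$nu, 1:5)
  expect_true(all(abs(mo0$rho - th0) < 3 * mo0$se))

  # full noise: independent route to the general SCC
  s <- lif_fig3("a")
  ctx <- build_context(s$model, s$adaptation, s$noise)
  mo <- map_oracle(ctx, n = 30000, seed = 4)
  th <- scc_general(ctx, 1:5)$rho
  expect_true(all(abs(mo$rho - th) < 3 * mo$se + 0.005))

  ctx_na <- build_context(s$model, adaptation_spec(2, 0), s$noise)
  expect_error(map_oracle(ctx_na, 100, 1), "requires adaptation")
})

test_that("i.i.d. peak-adaptation deviations give the lag-1-only pattern", {
  # alpha nu = 0: delta a_i i.i.d., rho_1 = -alpha/(1+alpha^2), rho_k>1 = 0
  alpha <- 0.6; tt <- -log(alpha) * 2  # period consistent with tau_a = 2
  set.seed(8)
  da <- rnorm(60000)
  dT <- da[-length(da)] - exp(tt / 2) * da[-1]
  r <- estimate_scc(dT, 3)
  expect_within(r$rho_hat[2], -alpha / (1 + alpha^2), 3 * r$se[2])
  expect_true(all(abs(r$rho_hat[3:4]) < 3 * r$se[3:4]))
})

test_that("long-window Fano factor matches the SCC-sum prediction", {
  s <- qif_fig2()
  ctx <- build_context(s$model, s$adaptation, s$noise)
  lf <- low_freq_spike_spectrum(1 / ctx$period, cv_theory(ctx),
                                scc_series(ctx, 20))
  tr <- simulate_train(s$model, s$adaptation, s$noise,
                       sim_config(dt = 1e-4, n_spikes = 8000, seed = 21),
                       cycle = ctx$cycle)
  f <- estimate_fano(tr, window = 150 * ctx$period)
  # ~50 windows: the count-variance estimate carries ~20% sampling error
  expect_gt(f$fano / lf$fano, 0.5)
  expect_lt(f$fano / lf$fano, 2.0)
})
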