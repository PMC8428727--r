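# closed-form serial correlation coefficients: limit cases, decomposition,
# time- vs frequency-domain equivalence, CV, spectra

test_that("nu parameter: limits and signs", {
  s <- lif_weak()
  lc <- find_limit_cycle(s$model, adaptation_spec(2, 0))
  prc <- prc_lif(s$model, adaptation_spec(2, 0), lc)
  expect_equal(nu_parameter(prc, 0, 2), 1)  # no adaptation

  ctx_w <- build_context(s$model, s$adaptation, s$noise)
  expect_lt(ctx_w$nu, 1)   # positive PRC, a* > 0
  expect_gt(ctx_w$nu, 0)   # weak adaptation

  st <- lif_strong()
  ctx_s <- build_context(st$model, st$adaptation, st$noise)
  expect_lt(ctx_s$nu, 0)   # strong adaptation

  g <- gif_sets()$c        # resonator with tau_a ~ T*/2: nu can exceed 1
  ctx_g <- build_context(g$model, g$adaptation, noise_spec(sigma2 = 1e-3, tau_eta = 1))
  expect_gt(ctx_g$nu, 1)
})

test_that("adaptation SCC is the printed geometric sequence", {
  expect_equal(scc_adaptation(0.5, 0.5, 1), -0.21875)
  expect_equal(scc_adaptation(0.7, 1, 1:4), rep(0, 4))  # (1 - nu) factor
  k <- 1:6
  r <- scc_adaptation(0.6, 0.4, k)
  expect_equal(r[-1] / r[-6], rep(0.24, 5))  # ratio alpha * nu
  # oscillatory branch for nu < 0
  ro <- scc_adaptation(0.6, -0.5, 1:4)
  expect_true(all(sign(ro) == c(-1, 1, -1, 1)))
  expect_error(scc_adaptation(1.2, 0.9, 1), "unstable")
})

test_that("colored-noise SCC: geometric ratio, white-noise suppression, sign", {
  s <- lif_fig3("a")
  ctx <- build_context(s$model, s$adaptation, s$noise)
  r <- scc_colored(ctx, 1:5)
  expect_equal(r[-1] / r[-5], rep(ctx$beta, 4), tolerance = 1e-12)
  expect_true(all(r > 0))  # positive PRC -> non-negative prefactor

  # D >> tau_eta sigma^2 suppresses the colored part
  big_d <- build_context(s$model, s$adaptation,
                         noise_spec(d_white = 100, sigma2 = 0.02, tau_eta = 0.5))
  expect_lt(abs(scc_colored(big_d, 1)), 1e-3)
  expect_lt(abs(scc_colored(big_d, 1)) / abs(r[1]), 1e-2)

  none <- build_context(s$model, s$adaptation, noise_spec())
  expect_error(scc_colored(none, 1), "both noise intensities")
})

test_that("time-domain and frequency-domain evaluations agree to 1e-6", {
  for (panel in c("a", "b")) {
    s <- lif_fig3(panel)
    ctx <- build_context(s$model, s$adaptation, s$noise)
    for (k in 1:2) {
      td <- scc_colored(ctx, k)
      fd <- scc_colored(ctx, k, method = "frequency")
      expect_lt(abs(td - fd) / abs(td), 1e-6)
    }
  }
})

test_that("general SCC: exact limit-case reductions", {
  m <- model_spec("lif", mu = 5)
  ad <- adaptation_spec(2, 2)

  # sigma = 0: rho_k = rho_{k,a} exactly
  ctx <- build_context(m, ad, noise_spec(d_white = 0.01))
  expect_identical(scc_general(ctx, 1:6)$rho,
                   scc_adaptation(ctx$alpha, ctx$nu, 1:6))

  # delta = 0: nu = 1 and rho_k = rho_{k,eta} exactly
  ctx0 <- build_context(m, adaptation_spec(2, 0),
                        noise_spec(sigma2 = 0.1, tau_eta = 1))
  expect_identical(ctx0$nu, 1)
  expect_identical(scc_general(ctx0, 1:6)$rho, scc_colored(ctx0, 1:6))

  # tau_a = tau_eta: B = 0, single geometric sequence
  sc <- shared_channel_lif()
  ctx_s <- build_context(sc$model, sc$adaptation, sc$noise)
  tab <- scc_general(ctx_s, 1:6)
  expect_equal(tab$B, rep(0, 6))
  expect_equal(tab$rho[-1] / tab$rho[-6],
               rep(ctx_s$alpha * ctx_s$nu, 5), tolerance = 1e-9)

  # no correlation-inducing process at all: renewal flag
  ctx_r <- build_context(m, adaptation_spec(2, 0), noise_spec(d_white = 0.01))
  tab_r <- scc_general(ctx_r, 1:3)
  expect_true(attr(tab_r, "renewal"))
  expect_equal(tab_r$rho, rep(0, 3))
})

test_that("decomposition identity and geometric tail decay", {
  sets <- list(qif_fig2(), lif_fig3("a"), lif_fig3("b"))
  for (s in sets) {
    ctx <- build_context(s$model, s$adaptation, s$noise)
    tab <- scc_general(ctx, 1:12)
    rebuilt <- (tab$A / tab$C) * tab$rho_a + (tab$B / tab$C) * tab$rho_eta
    expect_equal(tab$rho, rebuilt, tolerance = 1e-10)
    # tail decays geometrically with ratio max(|alpha nu|, beta)
    r <- max(abs(ctx$alpha * ctx$nu), ctx$beta)
    expect_lt(abs(tab$rho[12]), 2 * abs(tab$rho[6]) * r^6)
  }
})

test_that("QIF with colored noise and adaptation shows the mixed pattern", {
  s <- qif_fig2()
  ctx <- build_context(s$model, s$adaptation, s$noise)
  tab <- scc_general(ctx, 1:8)
  expect_gt(tab$rho[1], 0)            # weak positive at lag 1
  expect_true(all(tab$rho[2:8] < 0))  # pronounced negative beyond
})

test_that("green-noise spectrum: printed limits", {
  expect_equal(green_noise_spectrum(1e14, 0.18, 0.045, 1), 2 * 0.18,
               tolerance = 1e-6)
  expect_equal(green_noise_spectrum(0, 0.18, 0.045, 1) /
               green_noise_spectrum(1e14, 0.18, 0.045, 1), 0.25,
               tolerance = 1e-6)
  # perfect cancellation at D = tau_eta sigma^2
  expect_equal(green_noise_spectrum(0, 0.3, 0.3 / 2, 2), 0, tolerance = 1e-12)
})

test_that("spectrum-based SCC: OU cross-check, white limit, green sign", {
  s <- lif_fig3("a")
  ctx <- build_context(s$model, s$adaptation, s$noise)
  sfun <- isicorr:::context_spectrum(ctx)
  expect_equal(scc_spectrum(ctx$prc, sfun, ctx$period, 1),
               scc_colored(ctx, 1), tolerance = 1e-6)

  # flat (white) spectrum carries no interval correlations
  flat <- scc_spectrum(ctx$prc, function(w) rep(1, length(w)), ctx$period, 1)
  expect_equal(flat, 0, tolerance = 1e-10)

  # green noise without adaptation: negative lag-1 correlation
  g <- green_lif(adapting = FALSE)
  ctx_g <- build_context(g$model, g$adaptation, g$noise)
  rho1 <- scc_general(ctx_g, 1)$rho
  expect_lt(rho1, 0)
  via_spec <- scc_spectrum(ctx_g$prc, isicorr:::context_spectrum(ctx_g),
                           ctx_g$period, 1)
  expect_equal(rho1, via_spec, tolerance = 1e-4)
})

test_that("theoretical CV: limits and closed forms", {
  m <- model_spec("lif", mu = 5)
  # white noise, no adaptation: CV^2 = 2 D int Z^2 / T*^2
  ctx_w <- build_context(m, adaptation_spec(2, 0), noise_spec(d_white = 0.01))
  expect_equal(cv_theory(ctx_w),
               sqrt(2 * 0.01 * ctx_w$int_z2) / ctx_w$period,
               tolerance = 1e-12)
  # noise -> 0: CV -> 0 proportionally to the amplitude
  ctx_small <- build_context(m, adaptation_spec(2, 0), noise_spec(d_white = 1e-8))
  expect_equal(cv_theory(ctx_small) / cv_theory(ctx_w), 1e-3, tolerance = 1e-9)

  s <- qif_fig2()
  ctx <- build_context(s$model, s$adaptation, s$noise)
  expect_within(cv_theory(ctx), 0.2, 0.05)
})

test_that("low-frequency spectrum limit and tail summation", {
  # renewal: S(0) = r0 CV^2
  lf0 <- low_freq_spike_spectrum(2, 0.3, numeric(0))
  expect_equal(lf0$s0, 2 * 0.09)
  # single geometric sequence summed in closed form
  rho1 <- -0.2; b <- 0.5
  lf1 <- low_freq_spike_spectrum(1, 0.2, rho1 * b^(0:40))
  expect_equal(lf1$s0, 0.04 * (1 + 2 * rho1 / (1 - b)), tolerance = 1e-9)
  # analytic tail of an scc_series reproduces a brute-force long sum
  s <- qif_fig2()
  ctx <- build_context(s$model, s$adaptation, s$noise)
  ser <- scc_series(ctx, 10)
  long <- scc_general(ctx, 1:200)$rho
  lf_a <- low_freq_spike_spectrum(1 / ctx$period, cv_theory(ctx), ser)
  lf_b <- low_freq_spike_spectrum(1 / ctx$period, cv_theory(ctx), long)
  expect_equal(lf_a$s0, lf_b$s0, tolerance = 1e-8)
})

test_that("sign structure along parameter sweeps", {
  # resonator without adaptation: rho_1(tau_eta) dips negative at
  # intermediate correlation times and is positive for tau_eta >> T*
  g <- gif_resonator_noadapt()
  lc <- find_limit_cycle(g$model, g$adaptation)
  tes <- 10^seq(-2, 1.2, length.out = 12) * lc$period
  r1 <- vapply(tes, function(te) {
    ctx <- build_context(g$model, g$adaptation,
                         noise_spec(sigma2 = 1e-3, tau_eta = te), cycle = lc)
    scc_general(ctx, 1)$rho
  }, numeric(1))
  i_min <- which.min(r1)
  expect_gt(i_min, 1); expect_lt(i_min, length(r1))   # interior minimum
  expect_lt(min(r1), 0)
  expect_gt(r1[length(r1)], 0)

  # weakly adapting GIF: rho_1 crosses zero exactly once along a D sweep
  b <- gif_sets()$b
  lcb <- find_limit_cycle(b$model, b$adaptation)
  ds <- 10^seq(-4, 0, length.out = 15)
  r9 <- vapply(ds, function(D) {
    ctx <- build_context(b$model, b$adaptation,
                         noise_spec(d_white = D, sigma2 = 0.1, tau_eta = 1),
                         cycle = lcb)
    scc_general(ctx, 1)$rho
  }, numeric(1))
  expect_equal(sum(diff(sign(r9)) != 0), 1)
  expect_gt(r9[1], 0); expect_lt(r9[length(r9)], 0)
})
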