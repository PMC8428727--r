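# agreement between the analytic, adjoint and direct PRC routes, the adjoint
# boundary/normalization conditions, and the finite Fourier transform

test_that("LIF closed form: boundary value, monotonicity, adjoint agreement", {
  m <- model_spec("lif", mu = 5)
  ad0 <- adaptation_spec()
  lc0 <- find_limit_cycle(m, ad0)
  p0 <- prc_lif(m, ad0, lc0)
  expect_equal(p0$z_v[length(p0$z_v)], 0.25, tolerance = 1e-10)
  expect_true(all(p0$z_v > 0))
  expect_true(all(diff(p0$z_v) > 0))  # gamma > 0: increasing exponential

  for (s in list(lif_strong(), lif_weak())) {
    lc <- find_limit_cycle(s$model, s$adaptation)
    pa <- prc_lif(s$model, s$adaptation, lc)
    pj <- prc_adjoint(s$model, s$adaptation, lc)
    expect_lt(max(abs(pa$z_v - pj$z_v)), 1e-4)
    expect_lt(pj$norm_residual, 1e-6)
    expect_equal(pa$z_v[length(pa$z_v)], 1 / lc$v_dot_end, tolerance = 1e-8)
    expect_equal(pj$z_a[length(pj$z_a)], 0)  # end condition, exact
  }
})

test_that("GIF closed form agrees with the adjoint and is partially negative", {
  for (s in gif_sets()) {
    lc <- find_limit_cycle(s$model, s$adaptation)
    pa <- prc_gif(s$model, s$adaptation, lc)
    pj <- prc_adjoint(s$model, s$adaptation, lc)
    expect_lt(max(abs(pa$z_v - pj$z_v)), 1e-4)
    expect_lt(pj$norm_residual, 1e-6)
    expect_equal(pa$z_v[length(pa$z_v)], 1 / lc$v_dot_end, tolerance = 1e-8)
  }
  # resonator case: negative on about the first half of the period
  s <- gif_sets()$c
  lc <- find_limit_cycle(s$model, s$adaptation)
  z <- prc_gif(s$model, s$adaptation, lc)
  frac_neg <- max(z$tau[z$z_v < 0]) / lc$period
  expect_gt(frac_neg, 0.3)
  expect_lt(frac_neg, 0.6)
})

test_that("non-oscillatory GIF branch is rejected with guidance", {
  m <- model_spec("gif", mu = 5, gamma = 1, beta_w = 0.01, tau_w = 10)
  ad <- adaptation_spec(2, 1)
  lc <- find_limit_cycle(m, ad)
  expect_error(prc_gif(m, ad, lc), "non-oscillatory")
})

test_that("QIF quadrature form coincides with the adjoint solution", {
  s <- qif_fig2()
  lc <- find_limit_cycle(s$model, s$adaptation)
  pq <- prc_qif(s$model, s$adaptation, lc)
  pj <- prc_adjoint(s$model, s$adaptation, lc)
  expect_lt(max(abs(pq$z_v - pj$z_v)), 1e-6)
  expect_lt(pj$norm_residual, 1e-6)
  expect_true(all(pq$z_v >= 0))  # type I: non-negative PRC
  # adaptation skews the maximum to the right of T*/2
  expect_gt(pq$tau[which.max(pq$z_v)] / lc$period, 0.5)
})

test_that("direct delta-kick estimate matches the analytic PRC", {
  s <- lif_weak()
  lc <- find_limit_cycle(s$model, s$adaptation)
  phases <- seq(0.05, lc$period - 0.05, length.out = 7)
  pd <- prc_direct(s$model, s$adaptation, lc, phases = phases)
  ref <- prc_lif(s$model, s$adaptation, lc)
  zr <- spline(ref$tau, ref$z_v, xout = phases)$y
  expect_lt(max(abs(pd$z_v - zr) / abs(zr)), 1e-3)

  g <- gif_sets()$c
  lcg <- find_limit_cycle(g$model, g$adaptation)
  ph_g <- seq(0.05, lcg$period - 0.05, length.out = 7)
  pdg <- prc_direct(g$model, g$adaptation, lcg, phases = ph_g)
  refg <- prc_gif(g$model, g$adaptation, lcg)
  zg <- spline(refg$tau, refg$z_v, xout = ph_g)$y
  expect_lt(max(abs(pdg$z_v - zg)), 1e-3 * max(abs(zg)))

  expect_error(prc_direct(s$model, s$adaptation, lc, epsilon = 0), "positive")
  expect_error(prc_direct(s$model, s$adaptation, lc, phases = -1), "within")
})

test_that("sign convention: a positive kick where Z > 0 shortens the ISI", {
  # 3-point check per model, directly on the integrated dynamics
  sets <- list(lif_weak(), gif_sets()$b, qif_fig2())
  for (s in sets) {
    lc <- find_limit_cycle(s$model, s$adaptation)
    ref <- prc_adjoint(s$model, s$adaptation, lc)
    phases <- lc$period * c(0.6, 0.75, 0.9)  # late phases: Z > 0 in all sets
    stopifnot(all(spline(ref$tau, ref$z_v, xout = phases)$y > 0))
    pd <- prc_direct(s$model, s$adaptation, lc, phases = phases,
                     epsilon = 1e-4)
    # prc_direct reports -(deltaT)/eps, so positive values mean shortened ISI
    expect_true(all(pd$z_v > 0))
  }
})

test_that("finite Fourier transform invariants", {
  s <- lif_weak()
  lc <- find_limit_cycle(s$model, s$adaptation)
  prc <- prc_lif(s$model, s$adaptation, lc)
  n <- length(prc$tau)
  h <- lc$period / (n - 1)

  ft <- prc_fourier(prc, c(0, 0.7, 3.1, -3.1))
  # zt(0) is the period-average of Z
  expect_equal(Re(ft$z_tilde[1]), trapz(prc$z_v, h) / lc$period,
               tolerance = 1e-12)
  expect_equal(Im(ft$z_tilde[1]), 0)
  # Hermitian symmetry
  expect_equal(ft$z_tilde[4], Conj(ft$z_tilde[3]), tolerance = 1e-12)

  # constant PRC: closed form c (1 - e^{-i w T}) / (i w T)
  const <- new_prc_grid(prc$tau, rep(2, n), period = lc$period,
                        method = "analytic", kind = "lif")
  w <- 1.3
  ftc <- prc_fourier(const, w)
  expect_equal(ftc$z_tilde[1],
               2 * (1 - exp(-1i * w * lc$period)) / (1i * w * lc$period),
               tolerance = 1e-6)
  expect_equal(Re(prc_fourier(const, 0)$z_tilde[1]), 2, tolerance = 1e-12)

  # Wiener-Khinchin consistency on the grid: |Z~|^2 equals the transformed
  # double-sum autocorrelation built from the same quadrature weights
  omegas <- c(0.9, 4.2)
  p2 <- isicorr:::zt_power(prc, omegas)
  wts <- trapz_weights(n, h)
  for (i in seq_along(omegas)) {
    phase <- outer(prc$tau, prc$tau, "-") * omegas[i]
    acf2 <- sum(outer(wts * prc$z_v, wts * prc$z_v) * cos(phase)) / lc$period^2
    expect_equal(p2[i], acf2, tolerance = 1e-10)
  }

  expect_error(prc_fourier(new_prc_grid(numeric(0), numeric(0), period = 1,
                                        method = "analytic", kind = "lif"), 1),
               "empty")
})
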