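# canonical parameter sets used across the test files (figure setups of the
# adaptive-IF / colored-noise study the package implements)

qif_fig2 <- function() list(
  model = model_spec("qif", mu = 5),
  adaptation = adaptation_spec(tau_a = 6, delta = 18),
  noise = noise_spec(sigma2 = 0.5, tau_eta = 4))

lif_fig3 <- function(panel = c("a", "b")) {
  panel <- match.arg(panel)
  if (panel == "a") list(
    model = model_spec("lif", mu = 5),
    adaptation = adaptation_spec(tau_a = 2, delta = 2),
    noise = noise_spec(d_white = 1e-3, sigma2 = 0.02, tau_eta = 0.5))
  else list(
    model = model_spec("lif", mu = 20),
    adaptation = adaptation_spec(tau_a = 1, delta = 10),
    noise = noise_spec(d_white = 1e-3, sigma2 = 0.02, tau_eta = 5))
}

lif_strong <- function()  # strong adaptation, nu < 0
  list(model = model_spec("lif", mu = 20),
       adaptation = adaptation_spec(tau_a = 2, delta = 20),
       noise = noise_spec(sigma2 = 0.1, tau_eta = 1))

lif_weak <- function()   # weak adaptation, 0 < nu < 1
  list(model = model_spec("lif", mu = 5),
       adaptation = adaptation_spec(tau_a = 2, delta = 2),
       noise = noise_spec(sigma2 = 0.1, tau_eta = 0.7))

gif_sets <- function() list(
  a = list(model = model_spec("gif", mu = 10, gamma = 1, beta_w = 3, tau_w = 1.5),
           adaptation = adaptation_spec(tau_a = 10, delta = 10)),
  b = list(model = model_spec("gif", mu = 20, gamma = 1, beta_w = 1.5, tau_w = 1.5),
           adaptation = adaptation_spec(tau_a = 10, delta = 10)),
  c = list(model = model_spec("gif", mu = 1, gamma = -1, beta_w = 5, tau_w = 1.1),
           adaptation = adaptation_spec(tau_a = 1, delta = 2.3)))

gif_resonator_noadapt <- function()  # non-adaptive resonator, w_reset = 1
  list(model = model_spec("gif", mu = 1, gamma = -1, beta_w = 5, tau_w = 1.1,
                          w_reset = 1),
       adaptation = adaptation_spec(tau_a = 1, delta = 0))

green_lif <- function(adapting = FALSE) {
  tau_eta <- if (adapting) 0.67 else 0.22
  list(model = model_spec("lif", mu = 5),
       adaptation = if (adapting) adaptation_spec(2, 2) else adaptation_spec(2, 0),
       noise = noise_spec(d_white = 0.18, sigma2 = 0.045 / tau_eta,
                          tau_eta = tau_eta, mode = "green"))
}

shared_channel_lif <- function(mu = 5, delta = 2, tau_c = 0.5, d_white = 0.05)
  list(model = model_spec("lif", mu = mu),
       adaptation = adaptation_spec(tau_c, delta),
       noise = noise_spec(d_white = d_white, sigma2 = 0.1, tau_eta = tau_c,
                          mode = "shared_channel"))

# internal numerics reused by the tests
trapz <- isicorr:::trapz
trapz_weights <- isicorr:::trapz_weights
new_prc_grid <- isicorr:::new_prc_grid

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", x, tol, target))
}
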