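# GIF resonator without adaptation (w_reset = 1): colored noise alone can
# produce negative rho_1 at intermediate tau_eta
model: {kind: gif, mu: 1, gamma: -1, beta_w: 5, tau_w: 1.1, w_reset: 1}
adaptation: {tau_a: 1, delta: 0}
noise: {d_white: 0, sigma2: 1.0e-3, tau_eta: 1.0, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
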