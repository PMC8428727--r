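# adaptive GIF resonator, nu > 1 (partially negative PRC, tau_a ~ T*/2)
model: {kind: gif, mu: 1, gamma: -1, beta_w: 5, tau_w: 1.1}
adaptation: {tau_a: 1, delta: 2.3}
noise: {d_white: 0, sigma2: 1.0e-3, tau_eta: 1.0, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
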