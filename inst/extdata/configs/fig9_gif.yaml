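# GIF with weak adaptation, both white and colored noise (validity scan)
model: {kind: gif, mu: 20, gamma: 1, beta_w: 1.5, tau_w: 1.5}
adaptation: {tau_a: 10, delta: 10}
noise: {d_white: 0.01, sigma2: 0.1, tau_eta: 1, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
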