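# adaptive LIF, strong adaptation (nu < 0), colored noise of moderate range
model: {kind: lif, mu: 20, gamma: 1}
adaptation: {tau_a: 2, delta: 20}
noise: {d_white: 0, sigma2: 0.1, tau_eta: 1.0, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
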