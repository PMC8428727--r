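# adaptive LIF, weak adaptation (0 < nu < 1)
model: {kind: lif, mu: 5, gamma: 1}
adaptation: {tau_a: 2, delta: 2}
noise: {d_white: 0, sigma2: 0.1, tau_eta: 0.7, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
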