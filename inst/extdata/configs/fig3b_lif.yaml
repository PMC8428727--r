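# adaptive LIF, oscillatory adaptation pattern (nu < 0)
model: {kind: lif, mu: 20, gamma: 1}
adaptation: {tau_a: 1, delta: 10}
noise: {d_white: 1.0e-3, sigma2: 2.0e-2, tau_eta: 5, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
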