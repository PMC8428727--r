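# non-adaptive LIF under green (network-like) noise, tau_eta ~ T*
model: {kind: lif, mu: 5, gamma: 1}
adaptation: {tau_a: 2, delta: 0}
noise: {d_white: 0.18, sigma2: 0.2045, tau_eta: 0.22, mode: green}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
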