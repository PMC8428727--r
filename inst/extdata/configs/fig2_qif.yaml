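# adaptive QIF (theta) with pure colored noise
model: {kind: qif, mu: 5}
adaptation: {tau_a: 6, delta: 18}
noise: {d_white: 0, sigma2: 0.5, tau_eta: 4, mode: independent}
sim: {dt: 1.0e-4, n_spikes: 20000, seed: 1}
analysis: {k_max: 8, statistics: [theory, simulation]}
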