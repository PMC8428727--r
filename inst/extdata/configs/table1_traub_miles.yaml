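# Traub-Miles model with M current, standard parameter table
model: {kind: traub_miles, mu: 0}
adaptation: {tau_a: 100, delta: 0}
noise: {d_white: 0.1, sigma2: 0.1, tau_eta: 10, mode: independent}
sim: {dt: 5.0e-3, n_spikes: 5000, seed: 1}
analysis: {k_max: 8, statistics: [theory]}
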