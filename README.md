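# isicorr

Serial interspike-interval (ISI) correlations in tonically firing neurons
with spike-frequency adaptation and colored noise: closed-form weak-noise
theory, stochastic simulators, and the estimators needed to validate one
against the other.

## The problem

Spike trains of real neurons are rarely renewal processes: the intervals
`T_i` between consecutive spikes are correlated over several lags. The two
main mechanisms are **spike-triggered adaptation** (a slow inhibitory
current `a(t)` incremented at every spike, decaying with time constant
`tau_a`) and **temporally correlated input noise** (modeled as an
Ornstein-Uhlenbeck process `eta(t)` with variance `sigma^2` and correlation
time `tau_eta`). This package implements a perturbative theory for the
serial correlation coefficient

    rho_k = < dT_i dT_{i+k} > / < dT_i^2 >,      dT_i = T_i - <T>,

for the multidimensional stochastic integrate-and-fire family

    v'     = f0(v, w) + mu - a + eta + sqrt(2 D) xi_v(t)
    w'     = f1(v, w)
    tau_a a'   = -a            (+ Delta/tau_a at each spike)
    tau_eta eta' = -eta + sqrt(2 tau_eta sigma^2) xi_eta(t)

with fire-and-reset rule at `v = v_T`, covering the leaky (LIF), quadratic
(QIF/theta) and generalized (GIF, resonator) integrate-and-fire models, and
— through a numerical adapter — the Traub-Miles conductance-based neuron
with an M-type adaptation current.

## The result at the core

For weak noise the SCC is a **sum of two geometric sequences**,

    rho_k = (A/C) rho_{k,a} + (B/C) rho_{k,eta},

where `rho_{k,a} ~ (alpha nu)^{k-1}` is the pure-adaptation coefficient
(`alpha = exp(-T*/tau_a)`, `nu` the adaptation response parameter computed
from the phase-response curve Z), and `rho_{k,eta} ~ beta^{k-1}` the
pure-colored-noise coefficient (`beta = exp(-T*/tau_eta)`), with prefactors
A, B, C that mix both processes. All ingredients are computed by the
package: the deterministic limit cycle `(T*, a*)`, the PRC (closed forms,
adjoint integration, or direct delta kicks), the covariance functionals of
the noise, the theoretical coefficient of variation, and the low-frequency
spike-train spectrum `S(0) = r0 CV^2 (1 + 2 sum_k rho_k)`. Green
(network-like) noise with suppressed low-frequency power and the
shared-channel case `tau_a = tau_eta` are included.

## Worked example

The adaptive QIF (theta) neuron with pure colored noise (`mu = 5`,
`tau_a = 6`, `Delta = 18`, `tau_eta = 4`, `sigma^2 = 0.5`):

```r
library(isicorr)
model      <- model_spec("qif", mu = 5)
adaptation <- adaptation_spec(tau_a = 6, delta = 18)
noise      <- noise_spec(sigma2 = 0.5, tau_eta = 4)

ctx <- build_context(model, adaptation, noise)
#> Theory context: T* = 3.9501, a* = 6.2203, alpha = 0.5177, beta = 0.3725, nu = 0.1031

round(scc_general(ctx, k = 1:5), 4)
#>   lag     rho   rho_a rho_eta       A      B      C
#> 1   1  0.0186 -0.3723  0.4586 -0.4038 -0.302 0.6387
#> 2   2 -0.0682 -0.0199  0.1708 -0.4038 -0.302 0.6387
#> 3   3 -0.0294 -0.0011  0.0636 -0.4038 -0.302 0.6387
#> 4   4 -0.0112 -0.0001  0.0237 -0.4038 -0.302 0.6387
#> 5   5 -0.0042  0.0000  0.0088 -0.4038 -0.302 0.6387

cv_theory(ctx)
#> [1] 0.185
```

The neuron fires with period `T* = 3.95`; adjacent intervals are weakly
*positively* correlated (`rho_1 = 0.019`, the slow noise wins at lag 1)
while all higher lags are *negative* (adaptation wins) — a pattern no
single geometric sequence can produce. A stochastic simulation of the same
system confirms the prediction:

```r
train <- simulate_train(model, adaptation, noise,
                        sim_config(dt = 1e-4, n_spikes = 5000, seed = 1))
#> Spike train: 5000 spikes, mean ISI 3.9452, CV 0.184

estimate_scc(train, k_max = 5)
#>   lag rho_hat     se   (theory)
#>     1  0.0072 0.0149    0.0186
#>     2 -0.0702 0.0132   -0.0682
#>     3 -0.0209 0.0152   -0.0294
#>     4  0.0012 0.0126   -0.0112
#>     5 -0.0138 0.0162   -0.0042
```

Every estimate is within sampling error of the closed form, and the
simulated CV (0.184) matches `cv_theory` (0.185).

Packaged parameter sets for all canonical model setups are available via
`figure_config()`; `run_experiment()` and `sweep_parameter()` execute them
end to end, and `exec/isicorr` exposes the same pipeline as a command-line
tool (`limit-cycle`, `prc`, `theory`, `simulate`, `compare`, `sweep`,
`reproduce`).

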