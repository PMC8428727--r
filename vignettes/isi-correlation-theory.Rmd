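---
title: "Weak-noise theory of interspike-interval correlations: models, methods, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak-noise theory of interspike-interval correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isicorr)
```

# The model class and its assumptions

`isicorr` treats stochastic integrate-and-fire (IF) neurons of the form

$$\dot v = f_0(v,\mathbf w) + \mu - a + \eta(t) + \sqrt{2D}\,\xi_v(t),
\qquad \dot w_j = f_j(v,\mathbf w),$$
$$\tau_a \dot a = -a \;(+\,\Delta/\tau_a \text{ at each spike}), \qquad
\tau_\eta\dot\eta = -\eta + \sqrt{2\tau_\eta\sigma^2}\,\xi_\eta(t),$$

with the fire-and-reset rule $v\to v_R$, $\mathbf w\to\mathbf w_R$ at the
threshold $v_T$. Implemented members: the leaky IF
($f_0=-\gamma v$), the quadratic IF ($f_0=v^2$, threshold and reset at
$\pm\infty$), and the generalized IF with one auxiliary variable
($f_0=-\gamma v-\beta_w w$, $f_1=(v-w)/\tau_w$), plus the conductance-based
Traub–Miles neuron with an M-type adaptation current handled through a
numerical adapter.

Two standing assumptions define the theory's domain:

1. **Mean-driven firing.** The noiseless system has a stable limit cycle
   with period $T^*$ and peak adaptation value
   $a^* = (\Delta/\tau_a)/(1-e^{-T^*/\tau_a})$. Excitable
   (fluctuation-driven) regimes are out of scope; the solvers raise an
   error instead of extrapolating.
2. **Weak noise.** Interval deviations $\delta T_i = T_i - T^*$ are treated
   in linear response through the phase-response curve (PRC) $Z(\tau)$, and
   the mean ISI is approximated by $T^*$. Empirically the quantitative
   range extends to a coefficient of variation of roughly 0.15–0.3
   depending on which noise amplitude is scaled, with the qualitative lag
   structure surviving well beyond.

# The serial correlation coefficient

For lag $k \ge 1$ the theory yields a sum of two geometric sequences,

$$\rho_k = \frac{A}{C}\,\rho_{k,a} + \frac{B}{C}\,\rho_{k,\eta},$$

with

$$\rho_{k,a} = -\frac{\alpha(1-\alpha^2\nu)(1-\nu)}{1+\alpha^2-2\alpha^2\nu}
(\alpha\nu)^{k-1}, \qquad
\rho_{k,\eta} = \rho_{1,\eta}\,\beta^{k-1},$$

$\alpha = e^{-T^*/\tau_a}$, $\beta = e^{-T^*/\tau_\eta}$, and the
adaptation response parameter
$\nu = 1 - (a^*/\tau_a)\int_0^{T^*} Z(\tau)e^{-\tau/\tau_a}d\tau$. The
stability of the underlying linearized map requires $|\alpha\nu| < 1$,
checked at context construction. Sign structure: integrator models
(positive PRC) have $\nu<1$, hence negative adaptation-induced
correlations, monotone for $\nu>0$ and oscillatory for $\nu<0$; resonator
models can reach $\nu>1$, turning the adaptation contribution positive.

**Primary evaluation route.** `scc_general()` does not evaluate the
$A,B,C$ expressions directly. It computes the peak-adaptation covariances
$c_k$ generated by the linearized stochastic map
$\delta a_{i+1} = (\alpha\nu)\delta a_i + q(H_i+\Xi_i)$ in closed form and
converts them to $\rho_k$ via
$\rho_k = [(1+\alpha^2)c_k - \alpha(c_{k-1}+c_{k+1})] /
[(1+\alpha^2)c_0 - 2\alpha c_1]$. The two routes are algebraically
identical, but the covariance route is numerically stable at the removable
singularity $\alpha\nu = \beta$, where $A$ and $B$ individually diverge
like $1/(\alpha\nu-\beta)$ while $\rho_k$ stays finite; the factor
$[(\alpha\nu)^k - \beta^k]/(\alpha\nu-\beta)$ is switched to its analytic
limit $k(\alpha\nu)^{k-1}$ when $|\alpha\nu - \beta| < 10^{-9}$. The
$A,B,C$ coefficients are still reported (they are the natural reading
aids), and the decomposition identity is exercised in the test suite away
from the singular set.

Here $H_i$ and $\Xi_i$ are the PRC-weighted integrals of the colored and
white noise over one interval. The needed moments are covariance double
integrals over one period,

$$\langle H^2\rangle+\langle\Xi^2\rangle = \sigma^2\!\!\iint\!
Z(\tau)Z(\tau')e^{-|\tau-\tau'|/\tau_\eta} + 2D\!\int\! Z^2, \qquad
\langle H_iH_{i+1}\rangle = \sigma^2\!\!\iint\! Z(\tau)Z(\tau')
e^{-(T^*+\tau'-\tau)/\tau_\eta},$$

which also give the theoretical CV (`cv_theory()`) and, summed with the
analytic geometric tails, the low-frequency spike-train spectrum
$S(0) = r_0\,CV^2(1+2\sum_k\rho_k)$ and asymptotic Fano factor
(`low_freq_spike_spectrum()`).

## Quadrature choices

All period integrals use the composite trapezoid rule on the limit-cycle
grid (4096 uniform intervals by default; halving the grid moves no reported
quantity at the tolerances used). Three details deserve note:

* The lag-1 double integral factorizes exactly because
  $T^*+\tau'-\tau \ge 0$ on the domain, so it is computed as a product of
  two single integrals written in overflow-safe form
  ($e^{-(T^*-\tau)/\tau_\eta}$ rather than $e^{+\tau/\tau_\eta}$ —
  relevant when $\tau_\eta \ll T^*$ in time-constant sweeps).
* The $|\tau-\tau'|$ kernel integral is evaluated in $O(N)$ by a recursive
  causal exponential convolution (exact decay factor per step, trapezoid
  within the step) instead of an $O(N^2)$ outer product.
* The frequency-domain form
  $\rho_{k,\eta} = \int |\tilde Z|^2 S(\omega) e^{-ik\omega T^*}d\omega /
  \int |\tilde Z|^2 S(\omega)d\omega$ (`scc_spectrum()`, also the
  `method = "frequency"` cross-check of `scc_colored()`) splits the
  spectrum into its flat floor $S(\infty)$ — integrated in closed form,
  since a flat spectrum contributes $2\pi\!\int\!Z^2/T^{*2}$ to the
  denominator and exactly nothing to lags $k\ge1$ (the PRC autocorrelation
  vanishes beyond one period) — plus the decaying remainder, integrated by
  composite Simpson on $[0, 400/T^*]$ with at least 256 points per
  oscillation of $\cos(k\omega T^*)$, using the even symmetry of the
  integrand (the imaginary part cancels identically). Without the split,
  the $O(\omega^{-2})$ tail of $|\tilde Z|^2$ times a white floor would
  need impractically large truncation frequencies; with it, the truncation
  error is $O(\omega_{max}^{-3})$ and the time- and frequency-domain
  routes agree to better than $10^{-6}$ relative on the validation sets.

## Noise modes

* **independent** — white and OU increments drawn independently.
* **green** — network-like fluctuations: the OU and white sources share
  one increment per step with opposite signs ($\xi_v = -\xi_\eta$). The
  input spectrum is
  $S(\omega) = 2D + (2\tau_\eta\sigma^2 -
  4\sqrt{D\tau_\eta\sigma^2})/(1+\tau_\eta^2\omega^2)$ — flat at high
  frequencies, suppressed at low ones, vanishing at zero when
  $D=\tau_\eta\sigma^2$. Analytically this is equivalent to an OU process
  with *effective* variance
  $\sigma_{\rm eff}^2 = \sigma^2 - 2\sqrt{D\sigma^2/\tau_\eta}$ (possibly
  negative) plus ordinary white noise, so the whole adaptation theory
  carries over by substituting $\sigma^2 \to \sigma_{\rm eff}^2$ in the
  covariance integrals; the spectral route with the green spectrum is kept
  as an independent check. Negative $\sigma_{\rm eff}^2$ is how green
  noise produces negative interval correlations even without adaptation.
* **shared_channel** — adaptation and colored noise as one population of
  slow stochastic adaptation channels; $\tau_a = \tau_\eta$ is enforced at
  composition time, which makes $\alpha=\beta$, hence $B=0$ and a single
  geometric sequence.

# Phase-response curves

Four routes, mutually validating:

* **Closed forms** for the LIF and GIF. The GIF form is valid on the
  oscillatory branch $\Omega^2 = (\beta_w+\gamma)/\tau_w - \lambda^2/4 > 0$
  with $\lambda = \gamma + 1/\tau_w$ (the characteristic frequency of the
  subthreshold Jacobian); outside it the function refuses and points to the
  adjoint route.
* **One-dimensional quadrature** for the QIF, evaluated in theta
  coordinates ($\theta = 2\arctan v$, firing at $\pi$, reset at $-\pi$ —
  which also removes the unbounded blow-up from every deterministic
  integration in the package) and converted to the voltage response
  $Z = Z_\theta(1+\cos\theta_0)$, the sensitivity relevant to noise
  entering the voltage equation.
* **Adjoint integration**: $\dot{\mathbf Z} = -A^T(t)\mathbf Z$ backward
  from $t=T^*$ with end conditions $Z_w(T^*)=Z_a(T^*)=0$,
  $Z(T^*)=1/\dot v_0(T^*)$, by RK4 on the trajectory grid (cubic-spline
  interpolation of the stored orbit where the Jacobian is
  state-dependent). The normalization
  $\mathbf Z\cdot\dot{\mathbf X}_0 = 1$ is monitored at every grid point
  and an excessive residual is an error, not a warning.
* **Direct delta kicks**: $Z \approx -\delta T(\tau,\epsilon)/\epsilon$
  with two kick sizes ($\epsilon$, $\epsilon/2$) combined by Richardson
  extrapolation, because the defining expression is a limit and single-kick
  estimates carry an $O(\epsilon)$ bias. The unperturbed return time is
  recomputed by the same integrator so that discretization errors cancel in
  the difference. A kick size of zero is rejected.

# Deterministic limit cycle

Between spikes the adaptation current is exactly
$a(t) = a^* e^{-t/\tau_a}$, so the limit-cycle problem reduces to one
unknown. The solver brackets the self-consistency residual
$F(a) = (\Delta/\tau_a)/(1-e^{-T_{\rm cross}(a)/\tau_a}) - a$ and calls
`uniroot` (tolerance $10^{-12}$). A plain fixed-point iteration on $a^*$
was rejected during development: it diverges for strong adaptation
($\nu<0$, where the voltage initially recedes from threshold) and the
crossing time is not even monotone in $a$ for the resonator GIF, whereas
$F$ always changes sign on $[\Delta/\tau_a, \infty)$ and a failed crossing
at large $a$ simply counts as a negative residual. Integration is RK4 with
2048 steps per period during the solve (4096 for the final stored
trajectory), with bisection on RK4 substeps locating the threshold crossing
to near machine precision. Reference values reproduced to three digits
include the non-adaptive LIF closed form
$T^* = \gamma^{-1}\log[(\mu-\gamma v_R)/(\mu-\gamma v_T)]$ and the periods
0.22/0.05 (LIF $\mu=5/20$), 1.04/0.67 (adaptive LIF), 3.95 (adaptive QIF),
1.91/0.57/1.24/1.76 (GIF variants).

Voltage conventions: $v_T = 1$, $v_R = 0$ for LIF/GIF (configurable; these
values are the ones consistent with all the reference periods above),
$w_R = 0$ unless stated.

# Stochastic simulation and estimation

Euler–Maruyama with default $dt = 10^{-4}$ (a convergence test halving
$dt$ is part of the suite; finer steps are available through
`sim_config()`). Initial conditions sit on the deterministic limit cycle
($v_0 = v_R$, $a_0 = a^*$, $\eta_0 = 0$), suppressing transients. Spike
times are located by linear interpolation inside the crossing step, which
removes the leading $O(dt)$ bias of step-quantized spike times. The QIF is
integrated in theta coordinates whenever $D = 0$ (the smooth colored drive
transforms exactly); with white noise it runs in $v$ with bounds
$\pm 1000$ standing in for $\pm\infty$ and the asymptotic $1/v$
crossing-time correction. In green mode a single normal increment per step
is used with opposite signs for the two sources — exact anti-correlation
rather than an approximation.

`estimate_scc()` implements the sample SCC with the overall mean;
standard errors for it and for `estimate_cv()` come from a delete-one-block
jackknife over non-overlapping blocks of 100 ISIs, longer than the
correlation length $\max(\tau_a,\tau_\eta)/T^*$ of every setup shipped
with the package. `estimate_fano()` counts spikes in consecutive windows
and discards the partial tail window.

**The stochastic-map oracle.** `map_oracle()` is an independent
Monte-Carlo route to the same closed form: it simulates an actual OU path
on a fine grid, integrates it against the PRC to obtain the $H_i$ — so
their joint correlation structure *emerges* instead of being imposed —
drives the linear map with them, converts $\delta a_i$ to interval
deviations, and estimates the SCC. Agreement with `scc_general()` within
Monte-Carlo error is an acceptance-level test.

# Traub–Miles with an M current

Deterministic runs use RK4 at $dt = 0.01$ ms, stochastic runs
Euler–Maruyama at $dt = 0.005$ ms (the gating dynamics at the spike
upstroke is stiff); gating variables are clamped to $[0,1]$ after each
stochastic step, and rates with removable singularities (e.g. the
$m$-activation at $-54$ mV) evaluate through their analytic limits. Spikes
are upward crossings of 0 mV (the spike overshoots this by tens of mV,
making the choice insensitive) with a 2 ms lockout in the stochastic case;
crossings are refined by bisection on RK4 substeps, without which the
delta-kick PRC does not converge below $10^{-3}$ relative. The membrane
capacitance is 1 µF/cm², fixed by the convention that the adaptation
drive $I_{adap}/C$ is quoted in mV/ms.

The theory adapter identifies $\tau_a$ with the gating time constant
$\tau_z$ and needs a scalar $a^*$. The raw current $I_{adap}/C =
\bar g z (V-E_K)/C$ is dominated by the driving-force excursion during the
spike (peak 16.3 mV/ms, crossing value 10.8 mV/ms for the default
parameters), which is not the quantity the interval statistics feel: over
the subthreshold drift the driving force is nearly constant. The package
therefore defines
$a^* = \bar g\, z_{peak} (V_{rest}-E_K)/C$ — the post-spike maximum of the
slow gate times the driving force at the subthreshold resting level, which
for the default parameters sits at the leak reversal $-67$ mV — giving
$a^* = 4.19$ mV/ms; the raw crossing and maximum values are returned as
diagnostics. With $(T^*, a^*, \tau_z)$ and the measured PRC, the IF theory
reproduces the simulated SCCs of the conductance-based model within
sampling error.

One honest caveat: the delta-kick PRC of this model shows a tiny negative
excursion (below 1% of the maximum) confined to the spike downstroke,
where a depolarizing kick can marginally delay repolarization. It is
irrelevant to every integral the theory uses, and the PRC is strictly
positive over the subthreshold phase.

# Problem sizes and reproducibility

The validation suite runs each figure-level comparison with $2\times10^4$
spikes at $dt = 10^{-4}$ (acceptance CV checks use 3000–5000 spikes),
sizes at which the jackknife standard error of $\rho_1$ is below 0.02 for
every setup; these are the package's standard validation conditions.
`run_experiment()` writes CSV tables plus a JSON provenance record
(configuration hash, seed, package version) and is byte-identical across
re-runs with the same configuration and seed.

# Known limitations

* The mean ISI is approximated by $T^*$; systematic corrections to the
  mean first-passage time are not modeled.
* Quantitative SCC accuracy degrades beyond CV ≈ 0.15–0.3; only the
  qualitative lag structure should be trusted there.
* No subthreshold adaptation (the adaptation variable does not couple to
  $v$ between spikes), at most one auxiliary variable is exercised, and
  excitable regimes are rejected rather than approximated.
* The synthetic trains are exactly the model class of the theory —
  stationary, with purely spike-triggered adaptation and Gaussian OU/white
  input. Agreement on them validates the mathematics and the code, not the
  adequacy of the model class for any particular real neuron: real data
  add nonstationarity, non-Gaussian synaptic input, and mixed adaptation
  mechanisms that are out of scope here.
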