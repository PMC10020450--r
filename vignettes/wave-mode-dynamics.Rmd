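---
title: "Wave-mode dynamics, critical synchronization, and shallow learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-mode dynamics, critical synchronization, and shallow learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetcow)
```

## The model

This package simulates weakly evanescent cortical wave (WETCOW) modes.  A
mode is a Fourier component of the brain's electrostatic potential treated
as a dynamical node with amplitude $A$ and phase $\phi$:

$$\frac{dA}{dt} = (\gamma_0 + \gamma)\,A + A^2\left[w^a\cos(\phi-\psi) -
\alpha\right], \qquad
\frac{d\phi}{dt} = \omega + A\,w^\phi\cos\phi.$$

Here $\omega$ is the linear angular frequency, $\gamma$ a background
excitation (or damping) rate, $\gamma_0$ a sensory drive that enters the
amplitude equation only, $\alpha > 0$ a saturation strength, and $w^a$,
$w^\phi$, $\psi$ shape the amplitude and phase nonlinearities.  Units are
arbitrary; the package normalizes $\omega = 1$ by default.  The default
constants are $w^a = w^\phi = \sqrt 5$, $\psi = 2\arctan(1/3)$, $\alpha=3$,
for which the critical phase is $\phi^c = \arctan(1/2)$ and the coupling
factor

$$w = \frac{w^\phi\cos\phi^c}{\alpha + w^a\cos(\phi^c+\psi)}$$

is exactly $1/2$ (`coupling_factor(mode_params())`).  This is in contrast
with the leaky integrate-and-fire unit (`lif_params()`, `integrate_lif()`),
which produces no oscillation at all below its ad-hoc threshold; the
wave-mode equations cover the whole range from small harmonic oscillation
to spiking in one differentiable system.

## Criticality: what is exact and what is approximate

With total drive $\gamma_t = \gamma_0 + \gamma$, define $\omega_c =
\gamma_t w$, $\gamma_c = \omega/w$ and the criticality parameter $c_r =
\gamma_t/\gamma_c$.  The closed form for the effective spiking frequency is

$$\omega_s = \omega\sqrt{1 - c_r^2}.$$

Two different statements hide in this formula, and the package's tests
treat them differently.

**The threshold is exact.**  The spiking regime ends where the joint fixed
point of the two equations is born ($\dot A = \dot\phi = 0$).  Eliminating
$A$ gives $\gamma_t = \omega\,(\alpha + w^a\cos(u-\psi))/(w^\phi\cos u)$
over the locking branch, whose minimum is attained at $u = -\phi^c$ and
equals exactly $\omega/w = \gamma_c$.  Numerically, a mode driven at
$0.97\,\gamma_c$ keeps rotating and spiking while one at $1.03\,\gamma_c$
locks after a single spike-like transition — the suite asserts this
bracketing.  Above threshold the mode is silent: this is the single-spike
supercritical behaviour.

**The frequency curve is an approximation.**  The closed form follows from
freezing the amplitude at its fixed-point continuation value $A^\* =
\gamma_t w / w^\phi$, which turns the phase equation into
$\dot\phi = \omega + B\cos\phi$ with constant $B = \gamma_t w$; that
oscillator's mean frequency is exactly $\sqrt{\omega^2 - B^2}$.  In the
free-running system the amplitude oscillates around $A^\*$ within each
cycle, and the measured peak-to-peak frequency falls below the closed form:
with the default constants the relative deviation grows from about 1% at
$c_r = 0.1$ through 5% at $c_r = 0.3$ to roughly 20–23% near $c_r = 0.95$.
We verified this is a property of the dynamics and not of the integrator:
the polar and complex-form integrations agree to $10^{-8}$, halving the
tolerances does not move the result, and clamping the amplitude at $A^\*$
reproduces the closed form to integration accuracy.  The package therefore
uses the closed form as the design tool it is (thresholds and
synchronization targets are set with it), and measures frequencies from
simulation whenever a quantitative frequency is claimed.  Where this
vignette or the tests compare networks against "the driven single mode",
the comparison is measurement against measurement, which is sharp to
machine-level precision.

## One dynamics, two coordinate systems

Substituting $a = Ae^{i\phi}$ shows the polar pair is the complex equation

$$\dot a = \Gamma a + \beta_{a^\dagger} a a^\dagger + \beta_a a^2 -
\alpha\, a\,(aa^\dagger)^{1/2}$$

with $\Gamma = \gamma_t + i\omega$ and the exact correspondence

$$\beta_{a^\dagger} = \tfrac12 w^a\cos\psi + \tfrac{i}{2}(w^\phi + w^a\sin\psi),
\qquad
\beta_a = \tfrac12 w^a\cos\psi + \tfrac{i}{2}(w^\phi - w^a\sin\psi),$$

valid for every parameter set (`as_complex_params()`): the $aa^\dagger$
term carries no phase factor and the $a^2$ term carries $e^{2i\phi}$, and
their combination produces the $\cos(\phi-\psi)$ amplitude nonlinearity and
the pure $\cos\phi$ phase nonlinearity simultaneously.  The suite checks
cross-integrator agreement to $10^{-4}$ sup-norm on random parameter sets.

The same change of variables matters for networks.  The phase coupling in
polar form divides by the receiving amplitude, which becomes violently
stiff when amplitudes dip toward zero between unaligned spikes.
`integrate_network()` therefore integrates the Cartesian form

$$\dot z_i = (\gamma_i + i\omega_i) z_i + z_i\left[w^a_i\,\mathrm{Re}(z_i
e^{-i\psi_i}) + i w^\phi_i\,\mathrm{Re}(z_i) - \alpha_i |z_i|\right] +
\sum_{j\neq i} w_{ij} e^{-i\delta_{ij}} z_j,$$

which is polynomial and has no singularity; `network_rhs()` still exposes
the polar derivatives (with an amplitude floor of $10^{-12}$, below which
the phase derivative falls back to $\omega_i$) and the two agree to
$10^{-5}$ on integrated trajectories.

## Critically synchronized memory loops

A mode driven at $\gamma_0$ spikes at $\omega_s(\gamma_0)$.  A network can
sustain the same activity with **no** drive when every row of its coupling
feeds the drive back: $\sum_j w_{ij}\cos\delta_{ij} = \gamma_0$ and
$\sum_j w_{ij}\sin\delta_{ij} = 0$.  `build_sync_couplings()` samples
magnitudes and lags uniformly in the requested ranges and applies a
least-norm additive correction to the magnitudes so both row sums hold to
$10^{-10}$; rows that would need negative magnitudes are resampled, and
near the capacity limit a deterministic fallback aligns the row's links
with the target direction.  One mode is structurally infeasible (an empty
sum cannot equal a positive drive); two modes suffice, at the price of a
single large coupling — the two-node loop in the test suite feeds back
$\gamma_0 = 1.8$ through one link per row and reproduces the driven mode's
measured frequency to $10^{-7}$ relative (with identical initial
conditions the reduction is exact).

With heterogeneous linear frequencies the plain conditions leave each mode
a different effective frequency; the network then only loosely
frequency-locks, with spike offsets that we measured at up to 40% of the
period.  The remedy is the heterogeneous construction
(`heterogeneous_tune()`): under full synchrony the coupling terms reduce to
effective parameters

$$\bar\gamma_i = \gamma_i + \sum_j w_{ij}\cos\delta_{ij}, \qquad
\bar\omega_i = \omega_i - \sum_j w_{ij}\sin\delta_{ij},$$

and requiring a common $\omega_s = \sqrt{\bar\omega_i^2 - \bar\gamma_i^2
w_i^2}$ fixes the phase-side row sum of every mode.  Note the sign of the
phase-side sum: evaluating the coupling term $\sin(\phi_j - \phi_i -
\delta_{ij})$ at $\phi_j = \phi_i$ gives $-\sin\delta_{ij}$, so a positive
lag *lowers* the effective frequency; the package consistently uses this
dynamics-derived sign (the opposite choice demonstrably fails to lock).
With it, ten-mode networks with frequencies drawn uniformly from $(0,2)$
and couplings inside $w_{ij}\in[0,0.2]$, $\delta_{ij}\in(-\pi/2,\pi/2)$
lock with zero measured frequency spread and zero spike-time offsets to
solver precision, from random initial phases, in one to three time units —
less than half of one mean linear period $2\pi/\langle\omega_i\rangle$.

`sync_demo_network()` packages the two reference regimes.  Both use ten
modes, the default constants, and $\bar\omega = 1$:

* `subcritical`: no background activation, row sums replicate $\gamma_0=1$
  ($c_r = 0.5$) — the loop is self-sustained purely by coupling;
* `near_critical`: background $\gamma_i = 1.14$ plus coupling drive $0.8$
  ($\bar\gamma = 1.94$, $c_r = 0.97$).  A pure-coupling drive of $1.94$ is
  impossible inside the study magnitude range (nine links of at most $0.2$
  reach $1.8$), which is why the near-critical regime keeps a background
  term; where a drive is split between background and coupling is otherwise
  unobservable in the dynamics.

For demonstration networks with fewer than ten modes the magnitude range is
scaled up ($w_{\max} = 2/(N-1)$) so the same row sums remain feasible.

## Measuring spiking and synchrony

Spikes are local maxima of $A(t)$ with topographic prominence at least half
the amplitude range, separated by at least half the analytic period when it
is defined; peak times are refined by quadratic interpolation
(`detect_spikes()`).  The effective frequency estimate is $2\pi$ over the
median inter-spike interval, with the interquartile range as dispersion —
the median makes single outlier gaps irrelevant, and fewer than three
spikes yield an explicitly undefined result.  `sync_metrics()` adds
pairwise nearest-spike offsets normalized by the common period, the
Kuramoto order parameter $R(t) = |\langle e^{i\phi}\rangle|$ on wrapped
phases, and a synchronization time defined as the earliest moment from
which $R \ge 0.95$ holds through the end of the run; the first quarter of
every trajectory is excluded from spike statistics.  The $0.95$ level and
the transient fraction are conventions, stated here because the underlying
theory offers no canonical metric.

`classify_regime()` labels a trajectory `linear`, `anharmonic`,
`subcritical_spiking`, or `supercritical`.  The documented heuristics: a
steady state is "spiky" when the amplitude sweeps more than half of its own
maximum; spiking requires at least three detected spikes; supercritical is
$c_r \ge 1$ or a prominent transient event followed by a non-spiky steady
state; the linear/anharmonic boundary puts the peak amplitude under 10% of
the stall scale $\omega/(w^\phi\cos\phi^c)$ and the Hann-windowed harmonic
distortion of $A\cos\phi$ under 5%.

## From tissue to mode parameters

The linear dispersion relation of weakly evanescent waves in anisotropic,
inhomogeneous tissue links a wavevector $k$ to a growth rate and frequency
through the permittivity-scaled conductivity tensor $\Sigma$:

$$\gamma = \frac{\Sigma_{ij}k_ik_j}{k^2}, \qquad
\omega = -\frac{(\partial_i\Sigma_{ij})\,k_j}{k^2}.$$

`dispersion_rates()` evaluates both at grid points of a
`conductivity_field()` with central differences (one-sided and flagged at
boundaries); `direction_scan()` samples directions uniformly and reports
the growth-maximizing one, which for a symmetric positive tensor is its
leading eigenvector.  The module supplies $(\gamma, \omega)$ values for
`mode_params()`; no automatic pipeline is imposed because the mapping from
tissue location and wavevector to a network of interest is a modeling
decision, not a numerical one.  Solving the full potential equation in
space and time is out of scope.

## The shallow synchronization classifier

The classifier realizes a single layer of per-class synchronized loops.
Design choices, all reconstructions (the underlying idea fixes the
architecture but not the arithmetic), all config-overridable:

* **Encoder** (`make_encoder()`, `encode_excitations()`): pixels of a
  $7\times7$ pattern, row-major, are split into one contiguous group per
  loop mode; group mean intensity maps affinely to a drive rate via the
  criticality scale, $\gamma = c_r\,\omega/w$.  The classifier uses
  $c_r \in [0.1, 0.45]$ so that construction-plus-presented drive stays
  subcritical (a stand-alone encoder defaults to $[0.1, 0.95]$).
* **Construction** (`construct_classifier()`): one pass over the training
  examples computes each class's mean drive vector $\bar d$.  The class
  loop replicates $\bar d$ on the amplitude side and tunes the phase-side
  sums so that all modes share one effective frequency *under the doubled
  drive* $2\bar d$ — the condition that holds when the class prototype is
  presented on top of the loop's own feedback.  The loop's reference
  response (per-mode measured spiking frequencies under $\bar d$) is
  recorded by one integration per class.  No example is visited twice
  (`attr(model, "n_example_visits")` proves it) and no gradient is taken.
* **Decision** (`predict()`): each loop is driven with the encoded pattern
  and integrated for 20 target periods; the score is the negative RMS
  deviation of the measured per-mode frequencies from the class reference.
  Matching drives reproduce the reference deterministically (score 0);
  mismatched drives break the frequency equalization and shift the
  response.  Ties break to the lowest class index.
* **Refinement** (`refine_classifier()`): seeded coordinate search that
  re-solves one coupling row at a time, preserving the row conditions
  exactly, and accepts only non-increasing training error.
* **Continual learning**: class loops are disjoint and each is built from
  its own seeded stream, so adding a class leaves existing loops
  bit-identical — the structural form of resistance to catastrophic
  forgetting.  This is a statement about the architecture, not about
  biological memory.

Image-benchmark accuracies reported for this family of algorithms on
external datasets are not reproducible from this package: they depend on
data not shipped here and on construction details that are not public.
The optional IDX reader (`read_idx_dataset()`) exists for demonstration
only; all tests run on the synthetic generator below.

## Synthetic data

`random_network()` draws $\omega_i \sim U(0, 2)$ — a uniform law with mean
1 and standard deviation $3^{-1/2} \approx 0.577$; a sample of ten draws
shows a sample standard deviation near 0.58 — with $w_{ij} \sim U(0, 0.2)$ and $\delta_{ij} \sim
U(-\pi/2, \pi/2)$.  `make_pattern_dataset()` builds $k$ binary $7\times7$
prototypes at pairwise Hamming distance $\ge 15$ and corrupts them with
independent per-pixel flips; Bernoulli flips are used precisely because at
rate $1/2$ every pixel is marginally uniform and classifier accuracy must
fall to $1/k$, giving an analytic chance anchor.  All generators are pure
functions of their configuration.  What the generator does *not* emulate:
correlated pixel noise, stroke-like structure, class imbalance, intensity
gradients — so a perfect score on separable prototypes demonstrates the
mechanism, not image-recognition performance.

## Numerical choices and problem sizes

Integration uses `deSolve::ode` (lsoda) at `rtol = 1e-8`, `atol = 1e-10`;
output grids are 0.02 time units for single modes and 0.05 for networks
(keeping phase advance well under half a turn per sample for unwrapping).
Default initial conditions are $A(0) = 10^{-3}$, $\phi(0) = 0$, recorded in
trajectory metadata together with solver settings and seeds.  The test
suite and the acceptance script use: frequency sweeps over six criticality
values with horizons of 30 effective periods plus transient; ten-mode
networks for 150 (subcritical) or 400 (near-critical) time units;
three-class pattern sets with 16 examples per class and six-mode loops.
These sizes hold every measured quantity far from its decision boundary —
synchronization metrics sit ten orders of magnitude inside their bounds —
while keeping a full run in minutes on one core.

## Known limitations

* The closed-form frequency curve is quantitatively loose away from the
  threshold (see above); thresholds and targets built from it are exact.
* Row-sum conditions are necessary, not sufficient, for synchronization;
  the package verifies lock dynamically rather than proving it.
* Couplings are static within a run; no plasticity during integration.
* Spatial mode evolution, stochastic forcing, and full spatio-temporal PDE
  solutions of the potential equation are out of scope.
* The classifier's score needs one short integration per class per
  pattern; it is a mechanism demonstration, not an optimized inference
  engine.
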