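# wetcow

Simulation and analysis of **weakly evanescent cortical wave (WETCOW)
modes**: nonlinear oscillators in which every network node carries both an
amplitude and a phase, and the phase difference between nodes gates both
amplitude growth and phase pull.  The package is for computational
neuroscientists and dynamical-systems researchers who want to study
critical synchronization as a memory mechanism — and for anyone who wants a
reproducible, tested reference implementation of the model's closed-form
criticality predictions, its network synchronization conditions, and the
shallow oscillator-based classifier they suggest.

## The model

A single mode evolves as

```
dA/dt   = (gamma0 + gamma) A + A^2 [ w_a cos(phi - psi) - alpha ]
dphi/dt = omega + A w_phi cos(phi)
```

with sensory drive `gamma0` entering the amplitude equation only.  With
coupling factor `w = w_phi cos(phi_c) / (alpha + w_a cos(phi_c + psi))` and
critical phase `phi_c = arctan[ w_a sin(psi) / sqrt(alpha^2 - (w_a
sin(psi))^2) ]`, the mode spikes below the critical rate `gamma_c =
omega / w` at the effective frequency

```
omega_s = omega * sqrt(1 - c_r^2),     c_r = (gamma0 + gamma) / gamma_c
```

and performs a single spike-like transition followed by silence above it.
Networks couple modes through complex weights `w_ij exp(i delta_ij)`; a
loop whose coupling rows satisfy `sum_j w_ij cos(delta_ij) = gamma0` and
whose phase-side sums equalize the modes' effective frequencies replicates
the activity of a driven mode **with no external drive** — a critically
synchronized memory state.  A dispersion module maps anisotropic
conductivity tensor fields to per-mode growth rates and frequencies
(`gamma = Sigma_ij k_i k_j / k^2`, `omega = -d_i Sigma_ij k_j / k^2`), and
a leaky integrate-and-fire unit is included as the conventional baseline.

## Worked example

A mode at 90% of criticality (`gamma = 1.8`, since `gamma_c = 2` for the
default constants):

```r
library(wetcow)

p <- mode_params(gamma = 1.8)
criticality(p)
#> # A tibble: 1 × 8
#>   phi_c     w omega_c gamma_c   c_r omega_s   T_s supercritical
#>   <dbl> <dbl>   <dbl>   <dbl> <dbl>   <dbl> <dbl> <lgl>
#> 1 0.464   0.5     0.9       2   0.9   0.436  14.4 FALSE
```

`phi_c = 0.464` is `arctan(1/2)`, the coupling factor is exactly `1/2`, and
the closed form predicts spiking at `omega_s = 0.436` (period 14.4).
Simulating and measuring:

```r
traj <- integrate_mode(p, t_end = 200)
late <- dplyr::filter(traj, time >= 50)
estimate_effective_frequency(detect_spikes(late))
#> # A tibble: 1 × 5
#>    mode n_spikes omega_s_hat dispersion defined
#>   <int>    <int>       <dbl>      <dbl> <lgl>
#> 1     1        8       0.349   0.000102 TRUE
```

The mode spikes regularly (inter-spike dispersion `1e-4`) at a measured
`0.349` — below the closed-form `0.436`: the prediction is exact at the
spiking threshold but approximate in between, a point discussed at length
in the methods vignette (`vignettes/wave-mode-dynamics.Rmd`).

A ten-mode memory loop with frequencies drawn uniformly from (0, 2),
couplings inside the study ranges, and no external drive:

```r
net <- sync_demo_network("subcritical", seed = 1)
set.seed(2)
traj <- integrate_network(net,
  init = list(amplitude = rep(1e-3, 10), phase = runif(10, -pi, pi)),
  t_end = 150, dt_out = 0.05)
glance(sync_metrics(traj))
#> # A tibble: 1 × 4
#>   common_period freq_spread sync_time max_offset_frac
#>           <dbl>       <dbl>     <dbl>           <dbl>
#> 1          8.01    1.94e-15      4.25        8.87e-16
```

All ten modes spike at one common frequency (spread `2e-15`), with
spike-time offsets at solver precision, and reach the order-parameter
criterion at `t = 4.25` — inside one mean linear period (`2*pi` here).
The shallow classifier built on such loops
(`construct_classifier()`, `predict()`, `evaluate_classifier()`) scores
100% on noiseless separable synthetic patterns and decays to chance as
pixel-flip noise approaches 1/2.

## Command line

A thin launcher over the same functions lives at `inst/exec/wetcow`:

```sh
wetcow simulate-mode --config cfg.yaml --out outdir
wetcow build-sync    --config net.yaml --out outdir
```

Subcommands: `simulate-mode`, `simulate-network`, `build-sync`,
`verify-sync`, `analyze`, `dispersion`, `gen-data`, `train`, `predict`,
`evaluate`.  Every run writes a JSON manifest (config echo, package
version, seed) beside its outputs, so any number in a report can be
regenerated from the repository alone.
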