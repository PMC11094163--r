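---
title: "Methods: digital simulation of programmed dual-wavelength PDT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital simulation of programmed dual-wavelength PDT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtsim)
```

## The scientific problem

Photodynamic therapy (PDT) with light-responsive micelles separates drug
release from drug activation: 405 nm light degrades the PEG-b-PNBMA micelle
and releases the Rose Bengal photosensitizer, 580 nm light activates the
released drug to generate cytotoxic singlet oxygen. A sequential lighting
program must therefore choose an order — release first (`405-580`) or
activate first (`580-405`) — and the effect of that choice interacts with
drug concentration, irradiation time and delivered power. `pdtsim`
implements the digital half of such a treatment-design study: a synthetic
stand-in for the in vitro viability dataset, a neural-network surrogate of
viability versus the four treatment factors, and an agent-based simulation
that plays out the two protocols and quantifies their difference.

## The synthetic data generator

The in vitro measurements the surrogate would normally be trained on are
not published, so the generator emulates them from a parametric ground
truth. Viability at concentration $c$ (mg mL$^{-1}$), protocol $\rho$, time
$t$ (min) and input power $P$ (mW) is

$$V(c,\rho,t,P) \;=\; 1 - E_{\max}(\rho)\,
\frac{c^{h}}{EC_{50}^{h}+c^{h}}\,\frac{D}{D_{50}+D},
\qquad D = P\,t,$$

a Hill curve in concentration multiplied by a saturating function of light
dose, with a protocol-specific maximal effect. This form was chosen because
it is the simplest interpretable surface that reproduces the study's
simulation endpoints with four constants: with the defaults
$EC_{50} = 0.8$ mg mL$^{-1}$, $h = 2$, $D_{50} = 500$ mW min,
$E_{\max}(405\text{-}580) = 0.93$ and $E_{\max}(580\text{-}405) = 0.65$,
the surface returns $V = 0.2146$ and $0.4511$ at
(2 mg mL$^{-1}$, 60 min, 400 mW) — the $\approx 0.2$ and $0.45$ endpoints of
the protocol-comparison run — and a protocol gap inside $[0.15, 0.25]$ at
every grid point with $c \ge 1$ mg mL$^{-1}$. The $E_{\max}$ pair is fully
determined by those two endpoints once the other constants are set.

The factorial grid is 9 concentrations (0.25–2.25 mg mL$^{-1}$, step 0.25)
$\times$ 2 protocols $\times$ 3 times (20/40/60 min) $\times$ 7 transmitter
powers (−18 … −12 dBm, i.e. 316.2–1258.9 mW via the +43 dB system offset),
giving $9 \cdot 2 \cdot 3 \cdot 7 = 378 = 252 + 126$ records — the only
grid shape consistent with the reported train/validation sizes, since the
concentration and time levels themselves are not reported. Measurement
noise is additive Gaussian with SD 0.08 on the viability fraction, clipped
(not resampled) to $[0,1]$ — the simplest deterministic truncation rule;
0.08 places the surrogate's achievable validation $R^2$ in the mid-0.8 to
low-0.9 range, matching the reported fit quality, which is the only
property of the unpublished raw data that can be targeted. The 252/126
split is uniform at random (seeded), with no stratification, since nothing
more specific is reported.

What the generator does **not** emulate: cell-line identity, spheroid
geometry, uptake kinetics, inter-plate batch effects, or
heteroscedasticity of a real viability assay (real readouts are noisier
near 50% kill than near the extremes). Tests passing on this generator
therefore demonstrate that the pipeline recovers a known surface of the
assumed shape under i.i.d. noise — not that the published fit statistics
would be reproduced on the original measurements.

## The surrogate network

The surrogate is the study's stated architecture: inputs (concentration,
protocol, time, power), one hidden layer of 20 tanh units, affine output,
with predictions clipped to $[0,1]$. Continuous inputs are z-scored on the
training split only; protocol is a binary code (405-580 → 1). Because the
original optimizer, initialization and stopping rule are unreported, the
package makes deterministic choices: seeded uniform $(-0.5, 0.5)$ initial
weights with the output bias started at the training-mean viability,
full-batch iRprop$^-$ (resilient backpropagation — a first-order method
with per-parameter adaptive step sizes, steps in $[10^{-8}, 1]$, grow
factor 1.2, shrink factor 0.5) for a default 5000 epochs, no early
stopping. iRprop$^-$ was chosen because it is insensitive to the loss
scale, converges quickly on a 121-parameter problem, and is exactly
reproducible.

The training criterion is the SSE penalized by L2 weight decay,
$\mathrm{SSE} + \lambda \sum_j \theta_j^2$. Decay is needed because 121
parameters against 252 noisy points otherwise chase noise: without it the
validation $R^2$ falls to ≈0.78–0.80, well below the ≈0.92 ceiling set by
the generator's noise. The default $\lambda = 0.1$ maximizes median
validation $R^2$ over five initialization seeds on the default dataset and
still leaves a noise-free surface interpolated to a grid mean absolute
error below 0.01, so the regularizer costs essentially nothing in bias at
this data size. Reported metrics are always the plain $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$ (each split's own mean in SST) and unpenalized
SSE. The originally reported $R^2$ is described as likelihood-based and
scaled; that exact formula is not recoverable, so the package reports the
standard definition and makes no claim of numerical equality with the
original training-set statistics. A split whose viability is constant has
$\mathrm{SST}=0$; $R^2$ is then flagged undefined (`NA`) rather than
raising an error.

Factor importance is permutation importance on the validation split (mean
SSE increase over 20 reshuffles of one column at a time, seeded); the
original work shows only profile plots, and permutation importance is the
standard model-agnostic, directly testable substitute — an inert factor
has importance ≈ 0 by construction.

## The agent-based simulation

Cell agents have two states (ACTIVE, DEAD; DEAD is absorbing);
photosensitizer agents have three (INACTIVE, or activated by either
protocol) and flip to the run's activated state when the light first comes
on. The schedule splits the total PDT time into two equal phases in
protocol order — only the total time is reported, so the symmetric split
is a documented assumption, adjustable through the schedule builder. The
time step is 1 min by default.

The update rule is likewise unreported; the package uses the simplest rule
that makes the simulation provably consistent with the surrogate it
queries: cytotoxicity is confined to the 580 nm (photoactivation) phase,
and during each of its $k$ steps every ACTIVE cell independently dies with
constant hazard $p = 1 - s^{1/k}$, where $s$ is the surrogate-predicted
viability at the simulated condition. Expected survival after $k$ steps is
then exactly $s$, so over replicates the mean final viability lies within
binomial Monte-Carlo error of the surrogate prediction (the test suite
checks a 99% CI at $n_{\text{cells}} \times$ replicates $= 20\,000$).
Photosensitizer agents are bookkeeping (100 per mg mL$^{-1}$, matching the
display-proportional agent crowds): the concentration effect enters
through the surrogate, and inventing separate micro-dynamics would add
untestable structure. Replicate $k$ uses seed $\text{seed}+k-1$, making
every trajectory reproducible. The simulated comparison covers the two
sequential protocols only; concurrent 405+580 illumination is a
photophysics condition (see below), not a simulation mode.

Default scales — 1000 cells × 20 replicates — keep the Monte-Carlo
standard error of a mean final viability below 0.004 while running in well
under a second per condition.

## Calibrated photophysics

* **Release kinetics**: first-order to a plateau, $f(t) = p(1 -
  e^{-kt})$. Only the 5-h anchors are reported (68% released with 405 nm
  pre-irradiation, 30% without), so the plateaus (0.75 / 0.45) are chosen
  between the anchors and 1, and the rates are solved exactly from the
  anchors ($k = -\ln(1 - 0.68/0.75)/5 = 0.4743$ h$^{-1}$ irradiated,
  $0.2197$ h$^{-1}$ dark). Both constants are overridable.
* **Singlet-oxygen fold**: linear in time, $1 + \beta t$, with slopes
  solved from the 40-min anchors — 6.6× (free RB, 580 nm), 1.37×
  (micellar RB, 580 nm), 2.58× (micellar RB, concurrent 405+580 nm). The
  405-only condition is described only as minimal; its slope defaults to
  the 580-only value, which is an explicit assumption. Curvature of the
  real kinetics is not modeled, since only single-time anchors are
  available.
* **Dosimetry**: fluence $=$ irradiance × time (2 mW cm$^{-2}$ × 40 min =
  4.8 J cm$^{-2}$); transmitter dBm settings convert to mW with a fixed
  +43 dB offset inferred from the printed seven-pair table. The loaded-drug
  concentration helper is the plain product carrier concentration × LE/100;
  note the source text's "14.2% … equating to 0.014 mg mL$^{-1}$" is
  internally inconsistent by a factor of ten (14.2% of 1 mg mL$^{-1}$ is
  0.142), and the package implements the dimensionally correct product. The
  reported loading (LE 14.2%) and encapsulation (EE 41.4%) efficiencies are
  likewise mutually inconsistent with the reported preparation masses under
  any single reading of "carrier weight"; the package implements the two
  defining ratios as stated and does not attempt a reconciliation.

## Agreement statistics

Tumor volume uses the caliper ellipsoid formula $V = L W^2 / 2$ (length
the larger axis; swapped axes are rejected rather than silently
reordered). Bland-Altman agreement reports bias $=$ mean$(a-b)$, the
sample SD of the differences, and 95% limits of agreement at $\pm 1.96$ SD
(normal quantile, not a $t$ quantile — the conventional choice). Because
the published agreement summary ("bias and 95% limits … 72.85 and 112.3")
does not say whether the second number is a limit, a half-width, or
1.96·SD, the result object exposes all of bias, SD, both limits and the
half-width so any reading can be recovered; the underlying paired volumes
are unpublished, so no numerical reproduction is attempted.

## Numerical and design notes

* All validation is fail-fast with invalid-argument errors; viability
  fractions, probabilities and predictions are clipped to $[0,1]$ only
  where the contract says so (noise truncation, network output).
* Determinism: every stochastic step (noise, split, initialization,
  permutations, Bernoulli deaths) flows from an explicit integer seed, and
  RNG state is restored after each seeded operation, so package calls do
  not perturb the caller's RNG stream.
* Problem sizes in the test suite and acceptance script are the design
  defaults (378-record dataset; 5000-epoch fits; five training seeds for
  the median validation $R^2$; 1000 cells × 20 replicates per simulated
  condition) — the scales at which the method is intended to run.
* Known limitations: the generator's i.i.d. noise and smooth surface are
  favorable to the surrogate; the protocol gap at exactly 1 mg mL$^{-1}$
  is 0.167 under the ground truth, so estimates of the "≈0.2" gap at that
  boundary concentration carry little margin and can fall slightly below
  0.15 for unlucky fits; and the equal-phase schedule plus
  kill-phase-only hazard are assumptions, not reported facts.

## A compact run

```{r example, eval = FALSE}
d   <- generate_dataset(seed = 1)
fit <- fit_surrogate(d, seed = 1)
fit$report$r2_validation

cmp <- compare_protocols(fit, 2, 60, 400,
                         simulation_config(n_cells = 1000, seed = 7,
                                           replicates = 20))
cmp$difference

release_fraction(5, "IRRADIATED_405")
sosg_fold(40, "RBM_CONCURRENT")
```
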