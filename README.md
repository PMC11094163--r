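# pdtsim

In-silico optimisation of **programmed dual-wavelength photodynamic therapy
(PDT)** with light-responsive photosensitizer-loaded micelles.

Rose Bengal (RB) loaded into PEG-b-PNBMA block-copolymer micelles (RB-M)
needs two light wavelengths with distinct roles: 405 nm light cleaves the
*o*-nitrobenzyl groups and degrades the micelle, releasing the drug; 580 nm
light photoactivates the released RB, generating cytotoxic singlet oxygen.
Because release and activation are separate events, the *order* of the two
light phases matters — irradiating 405 nm before 580 nm (the `405-580`
protocol) should kill more cells than the reverse (`580-405`). Testing
lighting programs in the wet lab is slow, so the question is answered
digitally: fit a surrogate model of measured cell viability versus the four
treatment factors, then interrogate it with an agent-based simulation of the
sequential protocols. `pdtsim` is aimed at researchers designing such
treatment programs who want the whole chain — data model, surrogate,
simulation, dosimetry — reproducible and testable.

## What the package computes

* **Synthetic factorial dataset** (`generate_dataset()`): the in vitro
  viability measurements are emulated by a ground-truth response surface

  V(c, ρ, t, P) = 1 − E<sub>max</sub>(ρ) · c<sup>h</sup>/(EC₅₀<sup>h</sup> + c<sup>h</sup>) · D/(D₅₀ + D),  D = P·t

  with concentration c (mg mL⁻¹), protocol ρ, PDT time t (min) and input
  power P (mW), plus truncated Gaussian noise — 9 concentrations × 2
  protocols × 3 times × 7 transmitter powers = 378 records, split 252/126
  into training and validation.
* **Surrogate** (`fit_surrogate()`, `predict_viability()`): a 4 → 20 (tanh)
  → 1 neural network trained by full-batch resilient backpropagation on a
  weight-decay-penalized SSE criterion, reported with R² = 1 − SSE/SST and
  SSE on both splits; `factor_importance()` ranks the factors by permutation
  importance and `protocol_curve()` traces viability vs concentration per
  protocol.
* **Agent-based simulation** (`run_simulation()`, `compare_protocols()`):
  cell agents (active/dead) and photosensitizer agents
  (inactive/activated-by-protocol) stepped over a two-phase light schedule;
  during the 580 nm phase each active cell dies with per-step hazard
  p = 1 − s^(1/k) (k kill steps), calibrating the expected surviving
  fraction to the surrogate prediction s.
* **Photophysics & dosimetry** (`degree_of_polymerization()`,
  `loading_efficiency()`, `encapsulation_efficiency()`,
  `release_fraction()`, `sosg_fold()`, `fluence()`, `dbm_to_milliwatts()`):
  DP = (I_b/6)/(I_a/180) from NMR integrals; LE/EE mass ratios; first-order
  release-to-plateau kinetics anchored at the 5-h release measurements
  (68% irradiated / 30% dark); linear singlet-oxygen fold anchored at the
  40-min SOSG measurements (6.6× free RB, 2.58× concurrent light);
  fluence = irradiance × time; transmitter dBm → mW conversion.
* **Method agreement** (`tumor_volume()`, `bland_altman()`): caliper volume
  L·W²·0.5 and Bland-Altman bias ± 1.96·SD limits of agreement.
* **Pipeline** (`run_pipeline()`): generate → fit → simulate → report, fully
  seeded, writing CSV/JSON artifacts; a shell wrapper ships in
  `inst/scripts/pdtsim-pipeline.R`.

## Worked example

```r
library(pdtsim)

degree_of_polymerization(ia = 180, ib = 198)
#> Degree of polymerization: 33 (raw 33.0000)

d   <- generate_dataset(seed = 1)            # 378 records, 252/126 split
fit <- fit_surrogate(d, seed = 1)
fit
#> Viability surrogate: 4 -> 20 (tanh) -> 1 network, seed 1, 5000 epochs
#>   TRAIN      (n = 252): R2 = 0.8826, SSE = 1.5631
#>   VALIDATION (n = 126): R2 = 0.9089, SSE = 0.6428

cmp <- compare_protocols(fit, 2, 60, 400,
                         simulation_config(n_cells = 1000, seed = 7,
                                           replicates = 20))
cmp
#> Protocol comparison at 2 mg/mL, 60 min, 400 mW:
#>   405-580 mean final viability: 0.2124
#>   580-405 mean final viability: 0.4424
#>   difference (580-405 minus 405-580): 0.2300

factor_importance(fit, d, seed = 1)
#>         factor  delta_sse
#>  concentration 9.45777612
#>       protocol 2.19086153
#>    input_power 0.03377054
#>       pdt_time 0.01630525
```

Reading the output: the surrogate explains ~91% of the held-out viability
variance; simulated PDT at 2 mg mL⁻¹, 60 min, 400 mW leaves ~21% of cells
alive under the release-first `405-580` program versus ~44% under `580-405`
— a ~0.2 viability advantage for releasing the drug before activating it —
and concentration dominates the factor ranking, far ahead of protocol, power
and time.

The calibrated kinetics return their anchors directly:

```r
release_fraction(5, "IRRADIATED_405")  #> 0.68
release_fraction(5, "DARK")            #> 0.3
sosg_fold(40, "FREE_RB_580")           #> 6.6
sosg_fold(40, "RBM_CONCURRENT")        #> 2.58
fluence(2, 40)                         #> 4.8 J/cm2
```

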