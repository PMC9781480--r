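# smtkinetics

Single-molecule tracking (SMT) follows individual fluorescently labeled
proteins — transcription factors, polymerases, histones — through
time-lapse movies of live cells, and turns their trajectories into binding
and diffusion kinetics. `smtkinetics` implements the full analysis chain
for 2D SMT movies, together with a ground-truth simulator, so that every
stage can be validated against known parameters:

* **Detection and linking** — Gaussian-bandpass spot detection with
  subpixel 2D-Gaussian localization, deterministic greedy
  nearest-neighbor track linking, and kymograph rendering.
* **Residence-time (survival) analysis** — bound-segment classification,
  survival distributions normalized to the bound fraction
  C<sub>eq</sub>, three alternative photobleaching corrections
  (intrinsic, whole-reference, immobile-fraction of a tri-exponential
  reference fit), dwell-model fitting (1–3 exponentials, power law,
  power-law + exponential hybrid) with BIC model selection, and derived
  binding kinetics.
* **MSD analysis** — time-averaged mean squared displacement, apparent
  diffusion coefficients with a localization-error offset, anomalous
  exponent α, confinement-radius fitting, and Gaussian-mixture
  decomposition of log₁₀ D into bound / intermediate / free states.
* **Simulation** — molecules switching between bound and diffusing
  states as a continuous-time Markov chain, Brownian and sphere-confined
  diffusion, localization error, per-exposure photobleaching, axial
  defocalization, time-lapse dark intervals, and a synthetic movie
  renderer (Gaussian PSF + Poisson noise).

## The model

A population of molecules distributes between diffusing and bound
states. The survival distribution S(t) — the fraction of bound molecules
still bound after dwell time t — is normalized so that its first point
equals the bound fraction

> C_eq = (bound detections) / (all detections),

and, after photobleaching correction, fitted with a bi-exponential

> S(t) = C_eq · [ F_NS · e^(−t/τ_NS) + F_S · e^(−t/τ_S) ],

whose short and long residence times are interpreted as non-specific and
specific chromatin binding. From the fit:

> τ_res = F_NS/(F_NS+F_S) · τ_NS + F_S/(F_NS+F_S) · τ_S
> N_trials = (F_S + F_NS) / F_S
> τ_search = (1 − C_eq)/C_eq · τ_res,  k_on* = 1/τ_search,  k_on = k_on*/S_eq

Motion is classified from the MSD: MSD(τ) ∝ τ^α with α ≈ 1 Brownian,
α < 1 sub-diffusive; confined motion is fitted with

> MSD(t) = R_c² · (1 − e^(−4·D·t / R_c²)),

and a population-average confinement radius is the fraction-weighted sum
of sub-population radii.

## Worked example

Simulate 400 molecules switching between diffusing (D = 0.5 µm²/s),
non-specifically bound (τ = 2 s) and specifically bound (τ = 10 s)
states at a 60/40 on-rate split, under time-lapse imaging (0.2 s
exposure + 0.3 s dark) with photobleaching 0.02/exposure — then recover
the kinetics blind:

```r
library(smtkinetics)

sim   <- simulateTracks(twoStateBindingParams(seed = 42, nMolecules = 400))
segs  <- classifyBound(sim$tracks, rMax = 0.22, nMin = 3)
curve <- buildSurvival(segs, sim$tracks)

ref      <- simulateTracks(immobileReferenceParams(seed = 43, nMolecules = 2000))
refCurve <- buildSurvival(classifyBound(ref$tracks, 0.22, 3), ref$tracks)
corr     <- correctPhotobleaching(curve, "immobile_fraction", refCurve)

fits <- fitDwellModels(corr, families = c("exp_1", "exp_2"), seed = 0)
deriveKinetics(fits@fits[["exp_2"]], Ceq = boundFraction(curve))
#> BindingKinetics:
#>   C_eq = 0.8568; F_NS = 0.6074, F_S = 0.3926
#>   tau_NS = 2.006 s, tau_S = 10.87 s, tau_res = 5.486 s
#>   tau_search = 0.9171 s, N_trials = 2.547, k_on* = 1.09 1/s
```

The generative truth was τ_NS = 2 s, τ_S = 10 s, fractions 0.6/0.4, and
a mean search (diffusing) interval of 1 s — all recovered within a few
percent. The closed-form helpers reproduce standard nuclear-search
numbers directly:

```r
populationRc(c(0.5, 0.5), c(0.13, 0.5))  # 0.315 um whole-population R_c
samplingVolume(0.3)                      # 0.1131 um^3 sampling volume
samplingVolume(1.0)                      # 4.189 um^3 (diploid yeast nucleus)
translocationDetectTime(1.6, 30)         # 3.309 s to detect replisome progress
```

A YAML-configured end-to-end pipeline (`runPipeline()`) and a thin
command-line front-end (`inst/scripts/smt.R`, subcommands
`simulate | detect | link | kymo | survival | msd | states | pipeline`)
wrap the same functions; every report embeds the resolved configuration
and seed, and identical configurations produce byte-identical reports.

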