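---
title: "Single-molecule FRET burst analysis: models and methods"
author: "fretBurst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule FRET burst analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretBurst)
```

## Scope

fretBurst implements the analysis chain used for confocal single-molecule
fluorescence measurements of freely diffusing labeled molecules under
pulsed interleaved excitation (PIE): burst detection and filtering,
corrected transfer-efficiency histograms, donor-lifetime versus efficiency
analysis for disordered chains, fluorescence correlation spectroscopy
(FCS), burst-wise anisotropy, and exact 2:1 binding-isotherm fits for
titrations of a protein dimer binding a labeled DNA probe. Because
instrument photon data of this kind are rarely deposited, the package
ships seeded generators that emulate the instrument at the photon level
with full ground truth, so every stage is testable end to end.

## The photon data model

A measurement is a time-ordered stream of detected photons, each carrying

* a **macrotime** (integer clock ticks since the start; default resolution
  12.5 ns),
* a **microtime** ("nanotime", integer TCSPC channels since the last
  excitation pulse pair; default resolution 16 ps), and
* a **detector id** (four channels: donor/acceptor emission × parallel/
  perpendicular polarization).

With 20 MHz interleaved donor/acceptor excitation the PIE period is
50 ns; microtimes in the `[0, 25)` ns window follow a donor-excitation
pulse, those in `[25, 50)` ns an acceptor-excitation pulse. The gate
boundaries, detector roles and resolutions travel with the data
(`ChannelMap`), and are configurable: the defaults above are documented
conventions, since only the repetition rate is fixed by the experiment.
Streams are stored as gzipped columnar text with a metadata header; the
round trip is lossless and schema violations (missing fields, unsorted
timestamps) are reported by name and index.

## From photons to efficiency histograms

1. **Aggregate removal.** The trace is cut into 2 s bins; bins whose
   photon count exceeds the mean + 6 SD (statistics computed once, in a
   single pass over the input) are dropped. This removes slowly
   diffusing bright aggregates. The rule is statistical: a spike must
   stand out against all bins including itself, so very short traces
   with a dominant spike are deliberately left alone (fewer than 2 bins:
   no-op).
2. **Burst search (delta-T).** Maximal runs of photons whose
   inter-photon gaps are all ≤ 100 µs, keeping runs of 30–1000 photons.
   The search runs over *all* photons, not only donor-excitation ones,
   because the PIE stoichiometry needs the acceptor-excitation photons
   of the same molecule transit.
3. **Gated counting.** Each burst photon is classified by (excitation
   gate, detection channel) into `nDD`, `nDA`, `nAA`, plus the
   polarization split of `nDD`.
4. **Correction chain.** In fixed order: background (rate × duration per
   class), spectral crosstalk (`nDA − l·nDD`), direct acceptor
   excitation (`nDA − α/(1−α)·nAA`), detection-efficiency
   `n′_D = γ·nDD`. The order is a package convention (the corrections
   themselves are standard; their order is not uniquely determined by
   the definitions). Corrected counts below zero are floored at zero and
   flagged; the floor leaves a small positive bias in donor-only data
   (≈ half the shot noise of the subtracted term), visible in the tests.
5. **Observables.**
   * transfer efficiency `E = n′_A / (n′_A + n′_D)` (not clipped to
     `[0,1]`: noise legitimately spills over),
   * stoichiometry
     `S = (nDA + nDD − δ·nAA) / (nDA + nDD + γ_PIE·nAA − δ·nAA)` with
     `δ = γ_PIE·α/(1−α)`, evaluated on background-corrected counts.
     The trailing denominator term is interpreted as `δ·nAA`, mirroring
     the numerator; `denominator = "literal"` keeps the alternative
     reading `δ·nDA`,
   * asymmetry confidence: the difference of mean arrival times of two
     photon classes within the burst divided by its null SD
     `σ = T/(2√3)·√(1/N₁ + 1/N₂)` (the SD of a difference of means of
     uniform arrival times). The numerator is reconstructed as this
     difference of mean arrival times — the natural statistic for which
     the printed σ is the null scale. Applied twice: donor- vs
     acceptor-emission after donor excitation (acceptor bleaching), and
     AA vs DD (PIE consistency). The default threshold 1.5 keeps
     ≈ 87% of truly symmetric bursts per test (two-sided normal tail),
   * anisotropy `r = (I∥ − G·I⊥)/(I∥ + 2G·I⊥)` on the donor-excitation
     donor-channel polarization counts (standard steady-state relation,
     documented as a convention).
6. **Selection and fitting.** FRET pairs are selected by
   `S ∈ [0.3, 0.7]` ("around 0.5"; the exact window is a package
   default) plus both asymmetry tests. Population means come from
   maximum-likelihood Gaussian mixtures on the *unbinned* burst
   efficiencies (1 or 2 components; histogram bins are display only).
   With two components the first mean can be pinned to `[−0.05, 0.05]`
   to absorb residual donor-only events. Component SDs are bounded below
   by half the display bin width (0.0125) so that degenerate data hit a
   defined floor. Starting values are deterministic, making the whole
   pipeline reproducible given stream + configuration.

Default correction factors are γ = γ_PIE = 1 and α = 0.042; measured
values must be supplied for real data. All defaults are echoed in every
output (config hash + seed in CSV headers).

## Donor lifetime versus efficiency

The mean donor microtime of a burst estimates the donor lifetime in the
presence of the acceptor, τ_DA. Normalized by the intrinsic donor
lifetime τ_D (photon-weighted mean microtime over donor-only bursts,
S ≥ 0.8, at least 50 bursts) it gives ρ = τ_DA/τ_D, estimated per burst
as ⟨t_D⟩/τ_D — a documented estimator choice, since mean detection times
and fitted lifetimes coincide only for single-exponential decays.

* **Static distances:** ρ = 1 − E.
* **Fast-exchanging chains:** distances fluctuating much faster than the
  transit raise the line to ρ = 1 − E + σ²/(1 − ⟨E⟩), where ⟨E⟩ and
  σ² are the mean and variance of E(r) = 1/(1 + (r/R₀)⁶) under the
  distance distribution P(r).

For the chain model we use the 3D Gaussian-chain end-to-end density
P(r) ∝ r²·exp(−3r²/(2⟨r²⟩)) on r ∈ (0, 10·√⟨r²⟩], with moments by
adaptive quadrature (absolute tolerance 1e−8) — checked in the tests
against brute-force Monte-Carlo sampling. The variance is computed from
the integral definition ∫(E(r) − ⟨E⟩)²P(r)dr. As ⟨E⟩ → 1 the dynamic
ratio is capped and flagged. The Förster radius default of 6.0 nm is a
free parameter (typical for mid-red dye pairs) recorded in output
metadata, as is the donor-only lifetime default 3.5 ns in the simulator;
neither is pinned by the analysis itself, which works in normalized
quantities.

`classifyBursts()` reports the per-burst (E, ρ) cloud and the mean
signed deviation from the static line; on static simulations the
deviation is zero and pooled clouds regress to slope −1, intercept 1,
while fast-exchange chain simulations sit on the dynamic line —
both verified in the test suite within Monte-Carlo error.

## Fluorescence correlation spectroscopy

Donor × acceptor photon streams are correlated with a multiple-tau
estimator: photons binned at the initial bin width, 16 lags per octave,
trace re-binned by 2 between octaves (quasi-logarithmic grid, default
1 µs–1 s, covering triplet and diffusion regimes at desk scale). The
estimator is `G(τ) = ⟨n_i(t)·n_j(t+τ)⟩ / (⟨n_i⟩⟨n_j⟩)`; the
normalization by `⟨n_i⟩²` is retained as an option
(`normalization = "printed"`) — the two coincide for equally bright
channels. Lags beyond 10% of the trace are rejected as statistically
unreliable.

Curves are fitted by weighted least squares (inverse squared SE) to the
single-species 3D diffusion + triplet model

G(τ) = 1 + a·(1 + nT·e^(−τ/τ_T)) / ((1 + τ/τ_D)·(1 + τ/(s²τ_D))^(1/2)),

the standard 3D Gaussian-volume form (amplitude a, triplet amplitude nT
and dwell τ_T, diffusion time τ_D, axial aspect ratio s fixed by default
— it is not identifiable from a single curve and must come from
calibration). When nT is consistent with zero, τ_T is unidentifiable and
flagged as NA. The normalized diffusion-time shift
θ = (τ_sample − τ_free)/(τ_bound − τ_free), clipped to [0, 1] with a
flag, is the FCS readout for titrations.

## Binding titrations

A titration of protein against a labeled DNA probe at fixed probe
concentration follows the exact (quadratic) bound fraction of 2:1
binding — the protein binds as a preformed dimer, and the formula treats
the supplied protein concentration as that of the binding entity
("as printed" units by default):

θ = (c_DNA + K_D + c_P − √((c_DNA + c_P + K_D)² − 4·c_DNA·c_P)) / (2·c_DNA).

The implementation evaluates the conjugate form
θ = 2c_P/(b + √(b² − 4·c_DNA·c_P)), b = c_DNA + c_P + K_D, which is
algebraically identical but avoids catastrophic cancellation when
K_D ≪ concentrations — verified against an independent mass-action root
finder to 1e−10 over 10⁴ random parameter draws.

Readouts (FRET shift, anisotropy shift, FCS shift) are normalized to
bound fractions by their free/bound endpoints; endpoints can be fixed
from the data or co-fitted with K_D (both modes provided, since either
is defensible and the choice is not always recorded). Errors are
reported as 2 SD from the fit covariance (a residual bootstrap is
optional; with 12-point designs both are mildly anti-conservative —
normal vs t quantiles — so nominal 95% intervals cover slightly less in
the replication test, which asserts near-nominal coverage). Fitted K_D
below half the probe concentration is
flagged as tight binding: there the curve is set by probe depletion and
affinities are too high to compare accurately.

## What the generators emulate — and what they do not

**Burst-level generator** (`simulateBurstDataset`): bursts with
exponential durations (mean 1 ms) and Poisson counts; per-photon physics
whose expectations are the exact inverse of the correction chain
(detection probabilities η_D = 1/(max(1,γ)(1+l)), η_A = γ·η_D; leaked
donor photons at odds l : 1; direct-excitation photons at rate
α/(1−α) × the AA rate), so corrected efficiencies are unbiased. Donor
microtimes are exponential with mean τ_D(1−E) truncated to the 25 ns
gate (the truncation shifts the mean by ≈ 0.02 ns at τ_D = 3.5 ns; the
donor-only estimator carries the same shift, so the ratio ρ largely
cancels it). Dynamic chains redraw E per photon from the chain's E(r)
distribution — the fast-exchange limit, consistent with µs-scale
dynamics; slower exchange regimes are out of scope. Optional mid-burst
acceptor bleaching exercises the asymmetry filter, and injected
aggregate events the aggregate filter. The triplet here is brightness
thinning only; time-correlated blinking lives in the trace generator.

**Trace-level generator** (`simulateDiffusionTrace`): reflecting
Brownian motion in a box ≥ 10× the focal waist, 3D Gaussian detection
profile with axial elongation s, inhomogeneous Poisson emission,
two-state telegraph triplet blinking, uniform background. Defaults
(waist 0.3 µm, D = 22.5 µm²/s, hence τ_diff = w²/4D = 1 ms) give
desk-scale runs of ~10 s simulated time. Correlations at lags below the
propagation step reflect the piecewise-constant intensity, so fits
should start above it.

Neither generator models instrument-response convolution beyond a fixed
offset, detector afterpulsing, dead time, or photobleaching kinetics
(beyond the explicit bleach flag). Passing tests therefore demonstrate
the correctness of the analysis chain under the stated generative model,
not robustness to these instrument artifacts in real data.

**Titration generator** (`simulateTitration`): exact isotherm θ plus
Gaussian noise *on the bound-fraction scale*, mapped linearly between
readout endpoints; with zero noise the readout is bitwise reproducible
from `isothermTheta()`. Default designs use 12 log-spaced points over
0.01–100 nM at c_DNA = 0.5 nM with noise SD 0.03.

All randomness flows from one explicit integer seed per generator call,
recorded in the output metadata.

## Numerical choices and degenerate inputs

* Mixture fits: L-BFGS-B with deterministic starts, box constraints
  (pinned mean in `[−0.05, 0.05]`, SDs ≥ 0.0125); SEs from the observed
  information; identical values fall to the SD floor with the exact
  mean; fewer than 100 bursts are refused.
* Quadrature: `integrate()` with absolute tolerance 1e−8 on
  (0, 10·√⟨r²⟩]; non-convergence is an error, not a silent fallback.
* FCS fits: parameter bounds keep a, τ_D, nT, τ_T positive and inside
  the lag range; curves narrower than 3 decades are refused.
* Isotherm: conjugate-form evaluation; θ = 0 exactly at zero protein;
  the discriminant is clamped at 0 against rounding.
* Burst tables with zero denominators (E, S, r) yield NA and are
  excluded from histograms rather than clipped.
* Problem sizes in the tests (3000–4500 bursts for population
  recoveries, ~10 s traces for FCS, 10⁴ draws for the isotherm
  cross-check, 10⁶ for chain-moment Monte Carlo) were chosen so the full
  suite completes in about a minute while keeping Monte-Carlo error well
  below the tolerances being asserted.

## Known limitations

* No photon-by-photon likelihood dynamics analysis (H2MM-style), burst
  variance analysis, or multi-color schemes beyond two.
* Gaussian-chain distances only; no self-avoiding-walk or worm-like
  chain families.
* Single-component diffusion + one triplet term in FCS; no flow or
  additional photophysics; no concentration calibration.
* 2:1 binding only; no Hill/cooperative or competitive models. Salt
  conditions are handled as independent datasets.
* Vendor raw formats (.ptu/.ht3) are out of scope; conversion to the
  columnar text container is upstream of this package.
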