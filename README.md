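# fretBurst

Single-molecule FRET burst analysis with pulsed interleaved excitation
(PIE), in R.

Confocal single-molecule fluorescence experiments on freely diffusing
labeled molecules produce streams of time-tagged photons: bursts of
30–1000 photons as individual molecules transit the focus. From these,
one can measure inter-dye distances and their dynamics (transfer
efficiency histograms, donor lifetime vs efficiency), molecular size
(FCS diffusion times), local dye mobility (anisotropy), and — by
titration — binding affinities. fretBurst implements this analysis chain
for researchers studying, e.g., transcription-factor dimers with
intrinsically disordered regions binding DNA response elements, together
with photon-level simulators that supply ground-truth data where
instrument recordings are unavailable.

## What it computes

* **Burst pipeline** — aggregate removal (2 s bins, mean + 6 SD cut),
  delta-T burst search (gaps ≤ 100 µs, 30–1000 photons), PIE-gated
  counting, and the correction chain (background → crosstalk l → direct
  acceptor excitation α → detection-efficiency γ), giving per burst:

  * transfer efficiency `E = n′_A / (n′_A + n′_D)`
  * stoichiometry
    `S = (n_DA + n_DD − δ·n_AA) / (n_DA + n_DD + γ_PIE·n_AA − δ·n_AA)`,
    `δ = γ_PIE·α/(1−α)`, α = 0.042 by default
  * asymmetry confidence `|Δ mean arrival| / σ`,
    `σ = T/(2√3)·√(1/N_D + 1/N_A)`, cutoff 1.5
  * anisotropy `r = (I∥ − G·I⊥) / (I∥ + 2G·I⊥)`

  plus Gaussian population fits of the unbinned E values, optionally
  with a donor-only component pinned near zero.

* **Lifetime dynamics** — per-burst normalized donor lifetime
  ρ = τ_DA/τ_D against E; static distances follow ρ = 1 − E, fast
  fluctuating distances the dynamic line ρ = 1 − E + σ²/(1 − ⟨E⟩), with
  ⟨E⟩, σ² from a Gaussian-chain distance distribution and the Förster
  relation E(r) = 1/(1 + (r/R₀)⁶).

* **FCS** — multiple-tau donor × acceptor cross-correlation and weighted
  fits of G(τ) = 1 + a(1 + nT·e^(−τ/τ_T)) /
  ((1 + τ/τ_D)·√(1 + τ/(s²τ_D))).

* **Binding** — the exact 2:1 isotherm
  θ = (c_DNA + K_D + c_P − √((c_DNA + c_P + K_D)² − 4c_DNA·c_P)) / (2c_DNA),
  evaluated in cancellation-safe form and fitted to normalized FRET /
  anisotropy / FCS shift titrations, with tight-binding flagging when
  K_D falls below half the probe concentration.

* **Simulators** — seeded photon-level burst and Brownian-trace
  generators (with leakage, direct excitation, γ imbalance, background,
  triplet, bleach-asymmetric bursts, aggregates) and titration
  generators, all returning complete ground truth.

## Worked example

```r
library(fretBurst)

# a simulated measurement: 2000 bursts at ground-truth E = 0.66 with
# crosstalk, direct excitation and background
sim <- simulateBurstDataset(nBursts = 2000, trueE = 0.66, leakage = 0.05,
                            alpha = 0.042, backgroundRates = rep(300, 4),
                            seed = 11)
sim$stream
#> PhotonStream with 475692 photons over 99.291 s
#>   timestamp resolution 12.5 ns, nanotime resolution 16 ps
#>   PIE period 50 ns; donor gate [0, 25) ns, acceptor gate [25, 50) ns
#>   seed: 11

cfg <- AnalysisConfig(corrections = sim$corrections)
tab <- burstPipeline(sim$stream, cfg)
c(bursts = nrow(tab), selected = sum(tab$selected))
#>   bursts selected
#>     1671     1327

fitPopulations(tab$E[tab$selected], nComponents = 1)
#> PopulationFit: 1 component(s), n = 1327 bursts
#>   mean = 0.6630 +/- 0.0036 (2 SE), sd = 0.0658, weight = 1.000
```

The pipeline finds 1671 bursts, keeps 1327 as stoichiometric,
symmetric FRET pairs (S ∈ [0.3, 0.7], both asymmetry tests ≤ 1.5), and
the Gaussian fit of their corrected efficiencies recovers the
ground-truth 0.66 within its 2 SE error — the corrections invert the
simulated crosstalk, direct excitation and background exactly in
expectation.

A binding titration at a 0.5 nM labeled DNA probe:

```r
s <- simulateTitration(kd = 1.9, cDna = 0.5, noiseSd = 0.03, seed = 7)
fitKd(s)
#> IsothermFit: Kd = 1.85 +/- 0.386 nM (2 SD)
```

The fitted dissociation constant (1.85 nM) agrees with the generating
1.9 nM within its 2 SD fit error.

See `vignettes/single-molecule-pipeline.Rmd` for the models,
assumptions, parameter conventions and numerical choices, and
`inst/scripts/fretburst` for a thin command-line front end
(`simulate`, `fret`, `lifetime`, `fcs`, `bind`).

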