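# BundleDecay

Quantification of neurofilament (NF) bundle dynamics in axonal neurites
from fluorescence microscopy, for cell biologists studying cytoskeletal
turnover.

Axonal neurites contain a centrally situated bundle of highly
phosphorylated, cross-linked NFs surrounded by individual, more mobile
NFs ("the surround"). When a GFP-tagged NF subunit is expressed for a
short pulse and then switched off, the decay of GFP in each compartment
reports NF turnover. BundleDecay implements the full quantification:

* **Lateral profiles** — transverse intensity traces across the neurite,
  averaged over a short longitudinal window;
* **Bundle/surround separation** — a reproducible threshold rule
  (surround mean + *k*·SD on a reference channel) replacing manual ROI
  selection, with surround correction: the two flanks are averaged and
  subtracted from the bundle mean;
* **Five-bin bundle profiling** — the bundle extent split into
  edge/interior/center/interior/edge bins of equal width, edge-normalized
  for distribution comparisons, raw for decay fitting;
* **Decay kinetics** — log-linear least-squares fits of
  `N(t) = N0 · exp(−λ(t − t0))`, half-life `T½ = ln(2)/λ`, bi-phasic fits
  with a fixed breakpoint, instantaneous and per-day decline rates and
  their compartment ratios, and photobleach-recovery fractions;
* **Statistics and reporting** — pooled-variance unpaired two-tailed
  t-tests, fold differences, deterministic CSV/JSON reports and figures;
* **A synthetic-neurite generator** — seeded, two-channel (GFP +
  phospho-NF stand-in) images with known compartment kinetics, per-bin
  decay, varicosities, camera noise and photobleach events, so the whole
  pipeline is testable end to end with no microscope data.

## A worked example

```r
library(BundleDecay)

res <- runPipeline(paperDefaultConfig(seed = 1), outDir = "bundledecay_out")
#> [measurements_main] simulating and quantifying (seed 1)
#> ...
#> [fit] fitting decays and assembling the report

halfLife(res$surroundEarly)   # 0.93  — surround half-life, days 2-4 (d)
halfLife(res$surroundLate)    # 5.50  — surround half-life, days 4-14 (d)
halfLife(res$fits$bundle)     # 5.44  — bundle half-life, days 2-14 (d)
res$ratios
#>      day2      day7
#> 23.105865  1.502685
res$comparison
#> bundle GFP: Early-On 1004.88 (n=30) vs Late-On 343.60 (n=30); fold 2.92, t = 37.19, p = 3.69e-42
res$recovery$surround
#> RecoveryResult: pre 1048.1 -> post 53.0 -> recovered 970.1 (92.6% of pre)
```

The run simulates a 30-cell synthetic cohort (days 2, 4, 7, 14, per-cell
cv 0.10), quantifies every frame through the profile pipeline, and fits
the compartment decays. The surround decays bi-phasically (fast early
phase, then a slow phase close to the bundle's rate); the bundle decays
slowly throughout; the surround's per-day decline is ~25-fold the
bundle's at day 2 but only ~1.5-fold by day 7; bundle-associated GFP is
~2.9-fold higher when expression precedes bundle formation (Early-On)
than after it (Late-On); and after a simulated photobleach the surround
refills to >90% of its pre-bleach level while the bundle stays bleached.
`bundledecay_out/` then contains the measurement CSVs, `fits.csv`,
`comparisons.csv`, `summary.json` and decay-curve figures.

Individual stages are exported: `renderNeuriteImage()` /
`renderTimeSeries()` / `applyBleach()` (synthesis),
`extractLateralProfile()`, `detectBundleExtent()`,
`surroundCorrectedBundle()`, `binBundle()`, `partitionSegments()`,
`measureCell()` (quantification), `fitExponential()`, `fitBiphasic()`,
`perBinHalfLives()`, `declineRate()`, `recoveryMetrics()` (kinetics),
`compareConditions()` and `buildReport()` (reporting). A thin
command-line driver with `simulate | quantify | fit | report | run`
subcommands ships in `inst/scripts/bundledecay.R`, configured by
`inst/extdata/paper_default.yaml`.

The methods vignette (`vignettes/neurite-bundle-kinetics.Rmd`) documents
the decay model, the generator's assumptions, the quantification
parameters and their defaults, and known limitations.

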