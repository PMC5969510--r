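# ccDFS

Dynamic force spectroscopy (DFS) analysis of coiled-coil rupture, for
single-molecule biophysicists working with AFM force-extension data —
and for anyone who needs a fully seeded, testable stand-in for such
data.

Short dimeric coiled coils loaded in the shear geometry rupture at
forces that grow linearly with the logarithm of the loading rate, as
predicted by the Bell-Evans model of thermally activated escape over a
single force-tilted barrier:

    k(F)  = k_off * exp(F * Δx / kBT)
    F*    = (kBT/Δx) * ln( ṙ Δx / (k_off kBT) )

where `F*` is the most probable rupture force at loading rate `ṙ`,
`k_off` the force-free dissociation rate and `Δx` the potential width.
Experimentally, each retract curve is the worm-like-chain (WLC)
stretching of two PEG spacers in series with a soft cantilever,
terminated by a single bond-rupture event; per retract speed, rupture
forces and loading rates (curve slope at rupture x retract speed) are
histogrammed, Gaussian fits give the most probable values, and the
`F*` vs `ln ṙ*` regression yields `(k_off, Δx)`.

The package provides:

* **Physics primitives** — `wlcForce()`, `seriesEquilibrium()`,
  `bellRate()`, `bellEvansMode()`, `ruptureForceDensity()`,
  `koffUpperBound()`.
* **A stochastic simulator** — `simulateCurve()` /
  `simulateEnsemble()` generate seeded retract traces through the full
  mechanical circuit with exact (closed-form) Bell-hazard rupture
  sampling, Gaussian force noise and blank curves;
  `simulateLinearLoadingEvents()` samples the idealized constant-rate
  law; `simulatePlateauCurve()` emulates rise-then-plateau traces for
  the simulation-comparison branch. Presets for the three coiled-coil
  constructs: `ccConstruct("A4B4" | "A4B3.5" | "A4B3")`.
* **Per-curve analysis** — `correctBaseline()`, `detectRupture()`,
  `fitWLC()`, `loadingRateOfEvent()`, `filterEvents()`,
  `analyzeCurves()`.
* **Ensemble inference** — `gaussianMostProbable()`,
  `buildSpeedEnsembles()` (with detection-limit censoring flags),
  `fitBellEvans()`, `aggregateReplicates()`, plus the plateau branch
  `plateauForce()`, `estimateKL()`, `speedToLoadingRate()`.
* **Reproducible I/O** — a plain-text TSV curve dialect
  (`writeForceCurve()` / `readForceCurves()`), JSON run manifests with
  byte-identical replay (`runFromManifest()`), and a command-line
  wrapper (`inst/scripts/ccdfs`, subcommands
  `simulate|analyze|dfs-fit|plateau|report`).

See the methods vignette (`vignettes/coiled-coil-dfs.Rmd`) for the
model, the simulator's assumptions and the numerical choices.

## Worked example

Simulate a full 8-speed panel (50-5000 nm/s, 350 curves per speed) for
the 4-heptad construct and run the whole inference chain:

```r
library(ccDFS)
run <- runDFSPipeline("A4B4", nCurvesPerSpeed = 350, seed = 42)
run
```

```
Dynamic force spectroscopy run
----------------------------------------------
  v [nm/s]   events    F* [pN]    r* [pN/s]
        50      237       33.9           54
       100      243       35.8          112
       200      243       39.0          258
       400      245       41.2          553
       800      245       43.0      1.2e+03
      1600      245       45.6     2.62e+03
      3200      244       48.3     5.44e+03
      5000      244       50.0     8.99e+03
----------------------------------------------
Bell-Evans fit over 8 speeds:
  koff   = 0.000345 1/s (x/ 1.31)
  deltaX = 1.32 nm (+/- 0.029)
----------------------------------------------
Filter tallies:
  accepted                                 1946
  no event detected                        853
  R2 < 0.95                                1
```

Reading the output: the most probable rupture force climbs from ~34 pN
at 50 nm/s to ~50 pN at 5000 nm/s — about 2.9 pN per e-fold of loading
rate, i.e. a slope of `kBT/Δx` with `Δx ≈ 1.3` nm. The intercept
extrapolates to `k_off ≈ 3.5e-4 1/s` (multiplicative standard error
1.31). The generating preset was `k_off = 3.2e-4 1/s`, `Δx = 1.29` nm:
the pipeline recovers the potential width to ~2% and the dissociation
rate well within its error, which is exponentially sensitive by
nature. At 400 nm/s the most probable rupture force is ~41 pN, the
hallmark rupture strength of the 4-heptad construct at that speed in
this geometry. The ~30% of curves with "no event detected" are almost
entirely the simulated blank (no-tether) cycles.

The same run from a shell:

```sh
inst/scripts/ccdfs simulate --construct A4B4 --n-curves 350 --seed 42 --out out/
inst/scripts/ccdfs analyze  --in out/curves --out out/per_curve.csv
inst/scripts/ccdfs dfs-fit  --in out/per_curve.csv --out out/dfs
inst/scripts/ccdfs report   --in out/dfs.json
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities
end to end from a single master seed — it simulates the stated
experiment (geometry, speed panels, construct presets), runs the full
curve-analysis and Bell-Evans pipeline, and writes one JSON object
with the most probable 400 nm/s rupture force of the 4-heptad
construct and the `(k_off, Δx)` recoveries for all three constructs:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
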