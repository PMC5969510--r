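---
title: "Dynamic force spectroscopy of coiled coils: model, simulator and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic force spectroscopy of coiled coils: model, simulator and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccDFS)
```

## The experiment and the model

In AFM-based single-molecule force spectroscopy (SMFS) of a coiled-coil
heterodimer loaded in the shear geometry, one peptide is tethered to a
glass slide and its partner to a soft cantilever, each through a
poly(ethylene glycol) (PEG) spacer of roughly 80 nm contour length. The
cantilever is retracted at constant speed $v$, the dimer is loaded with
increasing force until the strands separate, and the force-extension
trace of each retract cycle is recorded. Repeating this at retract
speeds between 50 and 5000 nm/s probes the loading-rate dependence of
the rupture force.

`ccDFS` implements both halves of this workflow:

* a **stochastic simulator** of retract traces, so that every stage of
  the analysis can be exercised and validated against known ground
  truth without instrument data; and
* the **inference chain** from raw traces to the force-free
  dissociation rate $k_\mathrm{off}$ and the potential width
  $\Delta x$: baseline correction, rupture detection, worm-like-chain
  (WLC) fitting and filtering, per-curve loading rates, per-speed
  histograms with Gaussian most-probable values, and the Bell-Evans
  regression with replicate aggregation.

### Spacer elasticity

PEG below ~100 pN is described by the worm-like chain
(Marko-Siggia interpolation),

$$ f(z) \;=\; \frac{k_BT}{p}\left[\frac{1}{4\,(1-z/L)^2} -
   \frac14 + \frac{z}{L}\right], $$

with persistence length $p$ and contour length $L$
(`wlcForce()`). The two spacers in series act as one WLC with
$L \approx 160$ nm. The cantilever (spring constant $k_c$, here
0.016-0.023 N/m) adds a Hookean compliance in series: at base
displacement $D = v\,t$ the equilibrium force satisfies
$z + f(z)/k_c = D$ (`seriesEquilibrium()`, solved by safeguarded
Newton iteration to $10^{-9}$ nm). The slope of the resulting
force-extension curve is the series stiffness
$k_S = (1/k_\mathrm{wlc} + 1/k_c)^{-1}$, and $k_S\,v$ is the loading
rate $\dot F$.

### Bond kinetics

Strand separation is modelled as thermally activated escape over a
single force-tilted barrier (Bell),

$$ k(F) = k_\mathrm{off}\, e^{F \Delta x / k_BT}, $$

so that under an (approximately) constant loading rate $\dot F$ the
most probable rupture force is linear in $\ln \dot F$,

$$ F^{*} = \frac{k_BT}{\Delta x}\,
   \ln\!\frac{\dot F\,\Delta x}{k_\mathrm{off}\,k_BT}, $$

clamped at zero below the threshold rate (`bellEvansMode()`). The
closed-form first-passage density and quantile function
(`ruptureForceDensity()`, `ruptureForceQuantile()`) serve as analytic
oracles for the simulator.

The three constructs studied - a 4-heptad dimer and two C-terminal
truncations (3.5 and 3 heptads of the B helix) - are available as
presets (`ccConstruct()`): $k_\mathrm{off}$ = 3.2e-4, 1.1e-1 and
6.5e-3 1/s with $\Delta x$ = 1.29, 0.89 and 1.03 nm. Longer coiled
coils tolerate larger deformation before strand separation (larger
$\Delta x$, slower $k_\mathrm{off}$); the incomplete half-heptad makes
the 3.5-heptad construct the mechanically weakest. These fitted values
describe the force-driven regime probed by the experiment; they do not
extrapolate to force-free dissociation, for which the equilibrium
bound $k_\mathrm{off} \le K_D\,k_\mathrm{on} < 10^{-4}$ 1/s
(`koffUpperBound()`) is the relevant constraint.

## The simulator: a stated world

`simulateCurve()` draws one retract trace through the full mechanical
circuit. The noiseless force follows the series equilibrium on a
uniform displacement grid; the rupture time is sampled by inverse
transform of the cumulative hazard $H(t) = \int_0^t k(F(t'))\,dt'$
against a unit-exponential draw. Because $F$ is piecewise linear in
$t$ on the grid, each hazard increment has an analytic primitive
($\int k_\mathrm{off} e^{aF} dt = k_\mathrm{off}(e^{aF_2}-e^{aF_1})/(a\dot F)$),
so the integration is exact and the rupture force at a given survival
draw is solved in closed form - no discretization bias, which a
trapezoid rule with step control could only bound. After rupture the
reported force is baseline. Gaussian white noise is added to the
*reported* force only; the hazard always sees the noiseless force.

The reported extension coordinate is the retract distance $v\,t$, so
the slope of a curve at rupture is the series stiffness of the circuit
and "slope times retract speed" recovers $dF/dt$ exactly; the truth
record stores the analytic value.

Defaults define the simulated world and are recorded in every
manifest:

| parameter | default | why |
|---|---|---|
| spacer contour length | 160 nm | two ~80 nm PEG spacers in series |
| spacer persistence length | 0.38 nm | literature-typical for PEG; not reported by the experiments emulated |
| cantilever stiffness | 20 pN/nm | middle of the calibrated 0.016-0.023 N/m range |
| temperature ($k_BT$) | 4.114 pN nm | room temperature, 298.15 K |
| force noise sd | 4 pN | plausible for a 0.02 N/m lever; instrument value not reported |
| blank-curve fraction | 0.3 | typical pickup efficiency; not reported |
| speed panel | 50-5000 nm/s, 8 speeds | the experimental range |
| samples per ramp | >= 2600 | instrument-like sampling density |

What the generator does **not** emulate: multiple tethers per curve,
unfolding intermediates, 1/f drift (an optional linear baseline tilt
exists for robustness tests), cantilever hydrodynamics, approach
segments, and the short force plateau of helix uncoiling, which the
experimental noise floor hides anyway. `simulatePlateauCurve()`
provides a separate phenomenological rise-then-plateau trace for the
steered-molecular-dynamics comparison branch (plateau averaging over a
stated extension window and the $dF/dt = k_L v$ conversion with
$k_L = 40$ pN/nm). A green test on synthetic data therefore
establishes correctness of the inference chain under the Bell+WLC
world, not instrument-level realism.

## Per-curve analysis

* **Baseline** (`correctBaseline()`): median of the trailing 10% of
  the trace (or a fitted line in `"linear"` mode); rupture forces are
  read relative to this baseline.
* **Detection** (`detectRupture()`): largest force drop completed
  within <= 2 nm of extension, on a running median; threshold
  $5\hat\sigma$ with $\hat\sigma$ the scaled median absolute deviation
  of the trailing baseline. The pre-drop force is extrapolated from a
  short linear fit so a steep loading ramp does not bias it. A second
  well-separated drop within 20% of the largest flags the curve
  ambiguous; ambiguous curves are excluded rather than guessed.
* **WLC fit** (`fitWLC()`): nonlinear least squares from the 5 pN
  crossing to 95% of the rupture force. The goodness statistic is
  computed on bin-averaged data (up to 50 bins): with 4 pN white noise
  a *perfect* WLC fit to raw samples has $R^2 \approx 0.85$-0.90
  simply because noise variance is a large fraction of signal
  variance, so a raw-$R^2 \ge 0.95$ filter would reject essentially
  everything. Averaging within bins suppresses white noise and leaves
  systematic misfit, which is what the filter is meant to catch; the
  conventional thresholds ($L > 100$ nm, $R^2 \ge 0.95$) then behave
  as intended. On simulated circuit curves the fitted contour length
  comes out 2-3% above the generating 160 nm because it absorbs the
  cantilever compliance - well clear of the 100 nm acceptance rule.
* **Loading rate** (`loadingRateOfEvent()`): ordinary least squares
  slope over the last 5 nm before rupture, times the retract speed.
  Note a known property: on a convex force-extension curve the 5 nm
  chord slope is systematically ~10-15% below the instantaneous
  stiffness at the rupture point, and 4 pN noise adds ~20% random
  slope error per event. The chord bias is a nearly uniform
  multiplicative shift of all loading rates, so it cancels from the
  Bell-Evans slope (and hence $\Delta x$) and moves $k_\mathrm{off}$
  by only ~x0.9, well inside its replicate scatter.

## Ensemble inference

Per speed, rupture forces are histogrammed on the linear scale and
loading rates in natural-log space (18 bins by default), and a
Gaussian is fitted to bin centers and counts by nonlinear least
squares (`gaussianMostProbable()`); its center is the most probable
value $F^*$ or $\dot F^*$. Fitting counts (not densities) over the
full histogram mirrors the conventional treatment; for the left-skewed
rupture-force law this pulls the fitted mode ~1-2 pN below the
analytic mode - a nearly uniform offset across speeds that shifts the
Bell-Evans intercept (hence $k_\mathrm{off}$, by a factor ~1.3) but
not the slope. A peak-region-only fit was evaluated as an alternative
and rejected: three-parameter fits on ~5 bins are ill-conditioned.

`fitBellEvans()` regresses $F^*$ on $\ln\dot F^*$ (unweighted, as is
conventional): slope $s$ gives $\Delta x = k_BT/s$ and intercept $c$
gives $k_\mathrm{off} = (\Delta x / k_BT)\,e^{-c/s}$, with delta-method
standard errors ($k_\mathrm{off}$'s multiplicative). Replicates are
aggregated as mean +/- SEM with $k_\mathrm{off}$ on the linear scale
(`aggregateReplicates()`; a geometric option exists).

### Detection-limit censoring

A $5\sigma$ detection threshold (20 pN at the default noise) censors
weak events. For the weakest construct the most probable force at the
slowest speeds lies *below* that threshold, so those histograms are
upper-tail remnants whose Gaussian "modes" reflect the detection limit,
not the bond. Two validity checks in `buildSpeedEnsembles()` keep such
artifacts out of the regression:

1. **Completeness** - within a panel all speeds share the same attempt
   statistics, so an accepted-event yield below half the panel maximum
   means the bulk of events fell below the limit;
2. **Resolution** - the fitted mode must sit at least one distribution
   width above the limit. Because the Bell-model force-distribution
   width is the same at every speed while censoring only shrinks
   observed widths, the panel *maximum* of the per-speed sample sds is
   used as the width estimate.

Flagged ensembles keep their data (and are reported) but do not enter
the fit. Without these checks the recovered $\Delta x$ of the
3.5-heptad construct is inflated by 10-30%; with them all three
constructs are recovered within ~7% across seeds. Under heavy
censoring no estimator of the most probable force is trustworthy -
exclusion, not correction, is the defensible treatment.

## Numerical choices and degenerate inputs

* Series-circuit root solve: bracketed, damped Newton; residual
  tolerance $10^{-9}$ nm; the residual is strictly monotone so
  bracketing is safe.
* Gaussian histogram fits: Gauss-Newton (`nls`, port) with restarts
  over the width start value, then a Nelder-Mead least-squares
  fallback; all-equal samples and fits that still fail raise errors
  with histogram diagnostics.
* Sub-threshold loading rates clamp `bellEvansMode()` at zero;
  $\Delta x = 0$ degenerates the rupture law to the exponential
  distribution and makes the mode undefined (error).
* A bond surviving to the end of the simulated ramp (force cap 200 pN
  or spacer extension 0.999 L) yields a truth record flagged
  truncated: "no rupture within range".
* Two-point Bell-Evans fits are permitted with a warning (exact line,
  no error estimates); nonpositive slopes raise "no Bell-Evans
  regime".
* All randomness flows from explicit integer seeds; per-curve seeds
  are derived deterministically from the master seed, and a run
  manifest replays byte-identically (`runFromManifest()`).

## Known limitations

* The Bell-Evans parameters recovered from, or fitted to, data in the
  20-7500 pN/s range describe the force-driven strand-separation
  pathway only; extrapolating them to zero force is not meaningful,
  and the package deliberately reports the equilibrium-based
  $k_\mathrm{off}$ bound separately.
* $k_\mathrm{off}$ from the regression intercept is exponentially
  sensitive to mode and loading-rate biases; replicate recovery is
  accurate to a factor ~2, comparable to the replicate SEMs such
  experiments report. $\Delta x$ is the robust parameter.
* The simulator's single-bond, white-noise world understates real
  curve pathology (multiple tethers, drift, nonspecific adhesion);
  the ambiguous-drop exclusion and the linear baseline mode are only
  first-order defenses.
* Loading rates from the 5 nm chord slope inherit the bias discussed
  above; the window is a configuration knob (`slopeWindow`) recorded
  in the manifest.

## A worked run

```{r, eval = FALSE}
run <- runDFSPipeline("A4B4", nCurvesPerSpeed = 350, seed = 42)
run          # per-speed table, Bell-Evans parameters, filter tallies
deltaX(run@fit)   # ~1.3 nm
koff(run@fit)     # ~3e-4 1/s
```

The same pipeline is scriptable from a shell through the thin wrapper
in `inst/scripts/ccdfs` (subcommands `simulate`, `analyze`, `dfs-fit`,
`plateau`, `report`), and `scripts/acceptance.R` recomputes the
package's headline quantities end to end from a single master seed.
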