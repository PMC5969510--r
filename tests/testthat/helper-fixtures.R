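# Shared fixtures, memoised so expensive simulations run once per session.
.fixtureCache <- new.env(parent = emptyenv())

memoise1 <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

# Full 8-speed panel run for one construct (used by the acceptance tests
# and by the per-speed monotonicity checks).
getPanelRun <- function(construct, seed = 42L, nCurvesPerSpeed = 350L) {
  memoise1(sprintf("panel-%s-%d-%d", construct, seed, nCurvesPerSpeed),
           runDFSPipeline(construct, nCurvesPerSpeed = nCurvesPerSpeed,
                          seed = seed))
}

# 400 nm/s A4B4 ensemble of >= 300 curves, analyzed (acceptance t1).
getT1Results <- function() {
  memoise1("t1", {
    g <- PullingGeometry(retractSpeed = 400)
    ens <- simulateEnsemble(g, WLCModel(), ccConstruct("A4B4"),
                            nCurves = 450, blankFraction = 0.3, seed = 1)
    analyzeCurves(ens)
  })
}

# Modest noisy A4B4 ensemble with truth records, analyzed (detection /
# WLC / loading-rate recovery tests).
getNoisyEnsemble <- function() {
  memoise1("noisy150", {
    g <- PullingGeometry(retractSpeed = 400)
    ens <- simulateEnsemble(g, WLCModel(), ccConstruct("A4B4"),
                            nCurves = 150, blankFraction = 0, seed = 7)
    list(sims = ens, results = analyzeCurves(ens))
  })
}

# Noiseless 2000-curve circuit ensemble (distributional oracles).
getNoiselessBigEnsemble <- function() {
  memoise1("noiseless2000", {
    g <- PullingGeometry(retractSpeed = 400, noiseSigma = 0)
    simulateEnsemble(g, WLCModel(), ccConstruct("A4B4"),
                     nCurves = 2000, blankFraction = 0, seed = 5)
  })
}

# Closed-form survival-based CDF of the linear-loading rupture law.
linearLoadingCdf <- function(F, bellKoff, bellDx, kBT, rate) {
  if (bellDx == 0) return(1 - exp(-bellKoff * F / rate))
  a <- bellDx / kBT
  b <- bellKoff * kBT / (rate * bellDx)
  1 - exp(-b * expm1(a * F))
}

# A clean synthetic ramp-and-drop curve for detection unit tests.
rampStepCurve <- function(peak = 50, noise = 1, n = 2000, seed = 99,
                          retractSpeed = 400) {
  x <- seq(0, 120, length.out = n)
  f <- ifelse(x <= 100, peak * x / 100, 0)
  set.seed(seed)
  ForceCurve(extension = x, force = f + rnorm(n, 0, noise),
             retractSpeed = retractSpeed, curveId = "ramp")
}
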