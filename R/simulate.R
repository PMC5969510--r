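# Seeded evaluation that restores the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-curve seed derived from a master seed (kept < 2^31).
childSeed <- function(master, i) {
  s <- (as.double(master) %% 2147483629) * 48271 + as.double(i) * 30269
  as.integer(s %% 2147483629 + 1)
}

# Noiseless mechanical trace of one constant-speed retract: base
# displacement grid D = v * t from 0 to the displacement where the
# noiseless force reaches fMax (capped at spacer extension 0.999 L),
# with the equilibrium force, spacer extension and series stiffness.
pullingTrace <- function(geom, model, minPoints = 2600L, fMax = 200) {
  stopifnot(is(geom, "PullingGeometry"), is(model, "WLCModel"))
  zCap <- 0.999 * model@L
  fCap <- wlcForce(zCap, model)
  fEnd <- min(fMax, fCap)
  # invert the WLC law at fEnd for the end-of-range spacer extension
  zEnd <- stats::uniroot(function(z) wlcForce(z, model) - fEnd,
                         lower = 0, upper = zCap, tol = 1e-10)$root
  dEnd <- zEnd + fEnd / geom@cantileverStiffness
  v <- geom@retractSpeed
  duration <- dEnd / v
  if (is.na(geom@samplingRate)) {
    n <- as.integer(minPoints)
    rate <- (n - 1) / duration
  } else {
    rate <- geom@samplingRate
    n <- floor(duration * rate) + 1L
    if (n < 2000L)
      stop(sprintf(paste0("sampling rate %.3g Hz yields only %d points ",
                          "before full extension (need >= 2000)"), rate, n))
  }
  tt <- seq(0, duration, length.out = n)
  D <- v * tt
  eq <- seriesEquilibrium(D, geom, model)
  list(time = tt, D = D, z = eq$extension, force = eq$force,
       kS = seriesStiffness(eq$extension, geom, model),
       samplingRate = rate, v = v)
}

# Exact cumulative hazard of a Bell bond along a piecewise-linear force
# schedule F(t): each interval has the closed-form primitive
# int koff e^{aF} dt = koff/(a Fdot) (e^{aF2} - e^{aF1}).
cumulativeHazard <- function(trace, bell) {
  a <- bell@deltaX / bell@kBT
  f1 <- trace$force[-length(trace$force)]
  f2 <- trace$force[-1]
  dt <- diff(trace$time)
  if (a == 0) {
    dH <- bell@koff * dt
  } else {
    s <- (f2 - f1) / dt
    flat <- abs(f2 - f1) < 1e-12
    dH <- ifelse(flat,
                 bell@koff * dt * exp(a * f1),
                 bell@koff / (a * s) * (exp(a * f2) - exp(a * f1)))
  }
  c(0, cumsum(dH))
}

# Solve the exact rupture force/time within the interval where the
# cumulative hazard crosses the unit-exponential draw u.
solveRupture <- function(trace, bell, H, u) {
  i <- findInterval(u, H, rightmost.closed = FALSE)  # H[i] <= u < H[i+1]
  a <- bell@deltaX / bell@kBT
  t1 <- trace$time[i]; t2 <- trace$time[i + 1]
  f1 <- trace$force[i]; f2 <- trace$force[i + 1]
  du <- u - H[i]
  if (a == 0) {
    tr <- t1 + du / bell@koff
    fr <- f1 + (f2 - f1) * (tr - t1) / (t2 - t1)
  } else if (abs(f2 - f1) < 1e-12) {
    tr <- t1 + du / (bell@koff * exp(a * f1))
    fr <- f1
  } else {
    s <- (f2 - f1) / (t2 - t1)
    fr <- log(exp(a * f1) + du * a * s / bell@koff) / a
    tr <- t1 + (fr - f1) / s
  }
  list(time = tr, force = fr)
}

#' Simulate one force-extension retract curve
#'
#' Generates a single constant-speed retract trace through the full
#' mechanical circuit: the noiseless force follows the WLC-spacer /
#' cantilever series equilibrium at base displacement `D(t) = v t`; the
#' bond's rupture time is sampled by inverse transform of the cumulative
#' Bell hazard `H(t) = int k(F(t')) dt'` (integrated in closed form over
#' each sampling interval) against a unit-exponential draw; after rupture
#' the reported force is baseline. Gaussian noise of sd `noiseSigma` is
#' added to the reported force only - the hazard always uses the noiseless
#' force. Identical seeds give identical output.
#'
#' The reported extension coordinate is the retract distance `v t`, so the
#' slope of the curve at rupture is the series stiffness of the circuit
#' and "slope times retract speed" recovers dF/dt exactly.
#'
#' @param geom a [PullingGeometry-class].
#' @param model a [WLCModel-class] for the spacers.
#' @param bell a [BellParameters-class] for the bond.
#' @param seed integer seed.
#' @param curveId,replicateId labels for the curve.
#' @param trace optional precomputed noiseless trace (internal use by
#'   [simulateEnsemble()]; must come from the same `geom`/`model`).
#' @return A list with elements `curve` ([ForceCurve-class]) and `truth`
#'   ([RuptureTruth-class]). If the bond survives to the end of the
#'   simulated range, the truth record is flagged `truncated` ("no rupture
#'   within range").
#' @examples
#' sim <- simulateCurve(PullingGeometry(retractSpeed = 400), WLCModel(),
#'                      ccConstruct("A4B4"), seed = 1)
#' sim$truth
#' @export
simulateCurve <- function(geom, model, bell, seed,
                          curveId = sprintf("curve-%d", seed),
                          replicateId = "rep1", trace = NULL) {
  stopifnot(is(bell, "BellParameters"))
  if (is.null(trace)) trace <- pullingTrace(geom, model)
  H <- cumulativeHazard(trace, bell)
  n <- length(trace$time)
  withSeed(seed, {
    u <- stats::rexp(1)
    noise <- if (geom@noiseSigma > 0)
      stats::rnorm(n, 0, geom@noiseSigma) else numeric(n)
  })
  if (u < H[n]) {
    rup <- solveRupture(trace, bell, H, u)
    zr <- stats::approx(trace$force, trace$z, xout = rup$force,
                        rule = 2)$y
    truth <- new("RuptureTruth", ruptured = TRUE, force = rup$force,
                 time = rup$time,
                 loadingRate = seriesStiffness(zr, geom, model) * trace$v,
                 truncated = FALSE)
    f <- ifelse(trace$time < rup$time, trace$force, 0)
  } else {
    truth <- new("RuptureTruth", ruptured = FALSE, truncated = TRUE)
    f <- trace$force
  }
  curve <- ForceCurve(extension = trace$D, force = f + noise,
                      retractSpeed = trace$v, curveId = curveId,
                      replicateId = replicateId, seed = seed,
                      samplingRate = trace$samplingRate)
  list(curve = curve, truth = truth)
}

#' Simulate an ensemble of retract curves at one speed
#'
#' Emulates several hundred approach-retract cycles at a fixed retract
#' speed: a fraction `blankFraction` of the records are blank curves
#' (baseline noise only, no tether picked up), the rest are
#' [simulateCurve()] outputs with per-curve seeds derived from the master
#' seed. Fully reproducible under a fixed master seed.
#'
#' @inheritParams simulateCurve
#' @param nCurves number of curves (>= 1).
#' @param replicateId replicate label attached to every curve.
#' @param blankFraction fraction of blank (no-event) curves in `[0, 1)`;
#'   default 0.3.
#' @param idPrefix prefix for curve ids.
#' @return A list of `nCurves` elements, each a list with `curve` and
#'   `truth` as in [simulateCurve()]; blank curves carry a truth record
#'   with `ruptured = FALSE`, `truncated = FALSE`.
#' @export
simulateEnsemble <- function(geom, model, bell, nCurves,
                             blankFraction = 0.3, seed,
                             replicateId = "rep1",
                             idPrefix = sprintf("v%g", geom@retractSpeed)) {
  stopifnot(nCurves >= 1, blankFraction >= 0, blankFraction < 1)
  trace <- pullingTrace(geom, model)
  nBlank <- round(blankFraction * nCurves)
  blanks <- withSeed(seed, sample.int(nCurves, nBlank))
  isBlank <- logical(nCurves)
  isBlank[blanks] <- TRUE
  n <- length(trace$time)
  out <- vector("list", nCurves)
  for (i in seq_len(nCurves)) {
    cid <- sprintf("%s-%s-%04d", idPrefix, replicateId, i)
    si <- childSeed(seed, i)
    if (isBlank[i]) {
      noise <- withSeed(si, if (geom@noiseSigma > 0)
        stats::rnorm(n, 0, geom@noiseSigma) else numeric(n))
      curve <- ForceCurve(extension = trace$D, force = noise,
                          retractSpeed = trace$v, curveId = cid,
                          replicateId = replicateId, seed = si,
                          samplingRate = trace$samplingRate)
      out[[i]] <- list(curve = curve,
                       truth = new("RuptureTruth", ruptured = FALSE,
                                   truncated = FALSE))
    } else {
      out[[i]] <- simulateCurve(geom, model, bell, seed = si,
                                curveId = cid, replicateId = replicateId,
                                trace = trace)
    }
  }
  out
}

#' Sample rupture forces under idealized constant loading rate
#'
#' Draws i.i.d. rupture forces from the closed-form linear-loading law
#' (see [ruptureForceDensity()]) by inverse transform, bypassing the
#' mechanical circuit. Used as an analytic oracle for the full simulator.
#'
#' @param bell a [BellParameters-class].
#' @param loadingRate constant loading rate, pN/s.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of `n` rupture forces (pN).
#' @export
simulateLinearLoadingEvents <- function(bell, loadingRate, n, seed) {
  stopifnot(n >= 1, loadingRate > 0)
  u <- withSeed(seed, stats::runif(n))
  ruptureForceQuantile(bell, loadingRate, u)
}

#' Simulate a rise-then-plateau force-extension curve
#'
#' Phenomenological stand-in for steered-molecular-dynamics style traces
#' of coiled-coil shearing: an initial linear force rise of stiffness
#' `riseStiffness` (phase I) transitioning into a constant-force plateau
#' (phase II, helix uncoiling) of length `plateauSpan`, with optional
#' Gaussian noise. The noiseless force is
#' `min(riseStiffness * x, plateauForce)`.
#'
#' @param riseStiffness initial slope k_I (pN/nm).
#' @param plateauForce plateau force (pN).
#' @param plateauSpan plateau length beyond the transition (nm).
#' @param noiseSigma force noise sd (pN).
#' @param seed integer seed.
#' @param nPoints number of samples.
#' @param retractSpeed nominal retract speed (nm/s); defaults to the
#'   SMD-like 1e6.
#' @return A [ForceCurve-class].
#' @examples
#' pc <- simulatePlateauCurve(40, 60, 5, noiseSigma = 0, seed = 1)
#' plateauForce(pc, c(2, 6))  # 60
#' @export
simulatePlateauCurve <- function(riseStiffness, plateauForce, plateauSpan,
                                 noiseSigma = 0, seed = 1, nPoints = 4000L,
                                 retractSpeed = 1e6) {
  stopifnot(riseStiffness > 0, plateauForce > 0, plateauSpan > 0)
  transition <- plateauForce / riseStiffness
  x <- seq(0, transition + plateauSpan, length.out = nPoints)
  f <- pmin(riseStiffness * x, plateauForce)
  noise <- withSeed(seed, if (noiseSigma > 0)
    stats::rnorm(nPoints, 0, noiseSigma) else numeric(nPoints))
  ForceCurve(extension = x, force = f + noise, retractSpeed = retractSpeed,
             curveId = sprintf("plateau-%g", seed), seed = seed,
             samplingRate = retractSpeed / (x[2] - x[1]))
}
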