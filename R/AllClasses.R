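#' @import methods
NULL

#' Worm-like chain model of an entropic polymer spacer
#'
#' Parameterizes the Marko-Siggia interpolation of the worm-like chain
#' (WLC) force law used to describe PEG spacer elasticity at forces below
#' ~100 pN: a persistence length `p` (nm), a contour length `L` (nm) and
#' the thermal energy `kBT` (pN nm).
#'
#' @slot p persistence length in nm (> 0).
#' @slot L contour length in nm (> 0).
#' @slot kBT thermal energy in pN nm (> 0); 4.114 pN nm at 298.15 K.
#'
#' @seealso [wlcForce()], [wlcStiffness()]
#' @export
setClass("WLCModel",
  representation(p = "numeric", L = "numeric", kBT = "numeric"),
  prototype(p = 0.38, L = 160, kBT = 4.114))

setValidity("WLCModel", function(object) {
  msg <- character()
  for (s in c("p", "L", "kBT")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a worm-like chain model
#'
#' @param p persistence length (nm). Default 0.38 nm, a literature-typical
#'   value for PEG (the underlying experiments do not report one).
#' @param L contour length (nm). Default 160 nm: two ~80 nm PEG spacers in
#'   series.
#' @param kBT thermal energy (pN nm). Default 4.114 (room temperature,
#'   298.15 K).
#' @return A [WLCModel-class] object.
#' @examples
#' wlcForce(80, WLCModel())
#' @export
WLCModel <- function(p = 0.38, L = 160, kBT = 4.114) {
  new("WLCModel", p = p, L = L, kBT = kBT)
}

setMethod("show", "WLCModel", function(object) {
  cat(sprintf("WLCModel: p = %.3g nm, L = %.4g nm, kBT = %.4g pN nm\n",
              object@p, object@L, object@kBT))
})

#' Bell two-state escape parameters
#'
#' The single-barrier Bell model of forced bond dissociation: escape rate
#' `k(F) = koff * exp(F * deltaX / kBT)`. `koff` is the force-free
#' dissociation rate (1/s) and `deltaX` the potential width (nm), i.e. the
#' distance from the bound state to the transition state along the pulling
#' coordinate.
#'
#' @slot koff force-free dissociation rate (1/s, >= 0).
#' @slot deltaX potential width (nm, >= 0).
#' @slot kBT thermal energy (pN nm, > 0).
#'
#' @seealso [bellRate()], [bellEvansMode()], [ccConstruct()]
#' @export
setClass("BellParameters",
  representation(koff = "numeric", deltaX = "numeric", kBT = "numeric"),
  prototype(koff = 1e-3, deltaX = 1, kBT = 4.114))

setValidity("BellParameters", function(object) {
  msg <- character()
  if (length(object@koff) != 1L || !is.finite(object@koff) || object@koff < 0)
    msg <- c(msg, "'koff' must be a single nonnegative finite number")
  if (length(object@deltaX) != 1L || !is.finite(object@deltaX) || object@deltaX < 0)
    msg <- c(msg, "'deltaX' must be a single nonnegative finite number")
  if (length(object@kBT) != 1L || !is.finite(object@kBT) || object@kBT <= 0)
    msg <- c(msg, "'kBT' must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Construct Bell escape parameters
#'
#' @param koff force-free dissociation rate (1/s).
#' @param deltaX potential width (nm).
#' @param kBT thermal energy (pN nm).
#' @return A [BellParameters-class] object.
#' @examples
#' bellRate(44, BellParameters(3.2e-4, 1.29))
#' @export
BellParameters <- function(koff, deltaX, kBT = 4.114) {
  new("BellParameters", koff = koff, deltaX = deltaX, kBT = kBT)
}

setMethod("show", "BellParameters", function(object) {
  cat(sprintf("BellParameters: koff = %.3g 1/s, deltaX = %.3g nm, kBT = %.4g pN nm\n",
              object@koff, object@deltaX, object@kBT))
})

#' Mechanical circuit of a constant-speed AFM retract
#'
#' Describes the pulling geometry of the SMFS experiment: the bond is held
#' between two PEG spacers (modelled as one WLC of total contour length
#' `spacerContourTotal`) in series with a Hookean cantilever of stiffness
#' `cantileverStiffness`, retracted at constant speed `retractSpeed`.
#' White Gaussian force noise of standard deviation `noiseSigma` is added
#' to reported forces. `samplingRate` may be `NA`, in which case the
#' simulator chooses a rate giving at least `minPoints` samples over the
#' simulated ramp (see [simulateCurve()]).
#'
#' @slot spacerContourTotal total spacer contour length (nm).
#' @slot spacerPersistence spacer persistence length (nm).
#' @slot cantileverStiffness cantilever spring constant (pN/nm);
#'   0.016-0.023 N/m = 16-23 pN/nm for the levers emulated here.
#' @slot retractSpeed retract speed (nm/s).
#' @slot noiseSigma force noise standard deviation (pN, >= 0).
#' @slot samplingRate sampling rate (1/s) or `NA` for automatic.
#'
#' @seealso [seriesEquilibrium()], [simulateCurve()]
#' @export
setClass("PullingGeometry",
  representation(spacerContourTotal = "numeric", spacerPersistence = "numeric",
                 cantileverStiffness = "numeric", retractSpeed = "numeric",
                 noiseSigma = "numeric", samplingRate = "numeric"),
  prototype(spacerContourTotal = 160, spacerPersistence = 0.38,
            cantileverStiffness = 20, retractSpeed = 400,
            noiseSigma = 4, samplingRate = NA_real_))

setValidity("PullingGeometry", function(object) {
  msg <- character()
  for (s in c("spacerContourTotal", "spacerPersistence",
              "cantileverStiffness", "retractSpeed")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(object@noiseSigma) != 1L || !is.finite(object@noiseSigma) ||
      object@noiseSigma < 0)
    msg <- c(msg, "'noiseSigma' must be a single nonnegative finite number")
  sr <- object@samplingRate
  if (length(sr) != 1L || (!is.na(sr) && (!is.finite(sr) || sr <= 0)))
    msg <- c(msg, "'samplingRate' must be NA or a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a pulling geometry
#'
#' @param spacerContourTotal total spacer contour length (nm); default
#'   160 = two 80 nm PEG spacers in series.
#' @param spacerPersistence spacer persistence length (nm); default 0.38.
#' @param cantileverStiffness cantilever spring constant (pN/nm); default
#'   20 (0.020 N/m, the middle of the calibrated 0.016-0.023 N/m range).
#' @param retractSpeed retract speed (nm/s); default 400.
#' @param noiseSigma force noise sd (pN); default 4.
#' @param samplingRate sampling rate (Hz); `NA` (default) lets the
#'   simulator pick a rate yielding at least 2600 samples per ramp.
#' @return A [PullingGeometry-class] object.
#' @examples
#' PullingGeometry(retractSpeed = 400)
#' @export
PullingGeometry <- function(spacerContourTotal = 160, spacerPersistence = 0.38,
                            cantileverStiffness = 20, retractSpeed = 400,
                            noiseSigma = 4, samplingRate = NA_real_) {
  new("PullingGeometry", spacerContourTotal = spacerContourTotal,
      spacerPersistence = spacerPersistence,
      cantileverStiffness = cantileverStiffness, retractSpeed = retractSpeed,
      noiseSigma = noiseSigma, samplingRate = samplingRate)
}

setMethod("show", "PullingGeometry", function(object) {
  cat(sprintf(paste0("PullingGeometry: spacer L = %.4g nm (p = %.3g nm), ",
                     "k_c = %.3g pN/nm, v = %.4g nm/s, noise sd = %.3g pN\n"),
              object@spacerContourTotal, object@spacerPersistence,
              object@cantileverStiffness, object@retractSpeed,
              object@noiseSigma))
})

#' Kinetic bound on the force-free off-rate
#'
#' Combines an upper bound on the equilibrium dissociation constant with an
#' upper bound on the association rate into an upper bound on the thermal
#' off-rate, `koffMax = KDMax * konMax`.
#'
#' @slot KDMax upper bound on K_D (M).
#' @slot konMax upper bound on k_on (1/(M s)).
#' @slot koffMax implied upper bound on k_off (1/s); always the product of
#'   the other two slots.
#'
#' @seealso [koffUpperBound()]
#' @export
setClass("KineticBound",
  representation(KDMax = "numeric", konMax = "numeric", koffMax = "numeric"))

setValidity("KineticBound", function(object) {
  msg <- character()
  if (object@KDMax < 0 || object@konMax < 0)
    msg <- c(msg, "'KDMax' and 'konMax' must be nonnegative")
  if (!isTRUE(all.equal(object@koffMax, object@KDMax * object@konMax)))
    msg <- c(msg, "'koffMax' must equal KDMax * konMax")
  if (length(msg)) msg else TRUE
})

#' Construct a kinetic off-rate bound
#'
#' @param KDMax upper bound on the dissociation constant (M).
#' @param konMax upper bound on the on-rate (1/(M s)).
#' @return A [KineticBound-class] with `koffMax` filled in.
#' @examples
#' koffUpperBound(KineticBound(1e-10, 1e6))  # 1e-4 / s
#' @export
KineticBound <- function(KDMax, konMax) {
  new("KineticBound", KDMax = KDMax, konMax = konMax, koffMax = KDMax * konMax)
}

#' A single force-extension retract trace
#'
#' One AFM retract record: tip-sample separation (`extension`, nm, strictly
#' increasing) against force (`force`, pN), with the acquisition metadata
#' needed downstream. The extension coordinate is the retract distance
#' `v * t` measured from force onset; forces are positive in tension.
#'
#' @slot extension numeric vector, nm, strictly increasing, length >= 2.
#' @slot force numeric vector, pN, same length as `extension`.
#' @slot retractSpeed retract speed (nm/s).
#' @slot curveId character label.
#' @slot replicateId character label (cantilever/surface replicate).
#' @slot seed integer seed the curve was simulated with (NA for imported
#'   curves).
#' @slot samplingRate sampling rate (Hz).
#' @slot baselineCorrected logical; set by [correctBaseline()].
#'
#' @export
setClass("ForceCurve",
  representation(extension = "numeric", force = "numeric",
                 retractSpeed = "numeric", curveId = "character",
                 replicateId = "character", seed = "integer",
                 samplingRate = "numeric", baselineCorrected = "logical"),
  prototype(curveId = "curve", replicateId = "rep1", seed = NA_integer_,
            samplingRate = NA_real_, baselineCorrected = FALSE))

setValidity("ForceCurve", function(object) {
  msg <- character()
  n <- length(object@extension)
  if (n < 2L) msg <- c(msg, "need at least 2 samples")
  if (length(object@force) != n)
    msg <- c(msg, "'extension' and 'force' must have equal length")
  if (n >= 2L && any(diff(object@extension) <= 0))
    msg <- c(msg, "'extension' must be strictly increasing")
  if (length(object@retractSpeed) != 1L || !is.finite(object@retractSpeed) ||
      object@retractSpeed <= 0)
    msg <- c(msg, "'retractSpeed' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a force curve
#'
#' @param extension tip-sample separations (nm), strictly increasing.
#' @param force forces (pN), same length.
#' @param retractSpeed retract speed (nm/s).
#' @param curveId,replicateId labels.
#' @param seed integer seed (or NA).
#' @param samplingRate sampling rate (Hz, or NA).
#' @param baselineCorrected logical flag.
#' @return A [ForceCurve-class] object.
#' @export
ForceCurve <- function(extension, force, retractSpeed,
                       curveId = "curve", replicateId = "rep1",
                       seed = NA_integer_, samplingRate = NA_real_,
                       baselineCorrected = FALSE) {
  new("ForceCurve", extension = as.numeric(extension),
      force = as.numeric(force), retractSpeed = retractSpeed,
      curveId = as.character(curveId), replicateId = as.character(replicateId),
      seed = as.integer(seed), samplingRate = as.numeric(samplingRate),
      baselineCorrected = baselineCorrected)
}

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf(paste0("ForceCurve '%s' (%s): %d samples, extension ",
                     "%.3g-%.4g nm, v = %.4g nm/s\n"),
              object@curveId, object@replicateId, length(object@extension),
              min(object@extension), max(object@extension),
              object@retractSpeed))
})

#' @describeIn ForceCurve-class number of samples in the trace.
#' @param x a `ForceCurve`.
setMethod("length", "ForceCurve", function(x) length(x@extension))

#' Ground truth of a simulated rupture
#'
#' Carried alongside every simulated [ForceCurve-class] so detection and
#' loading-rate estimators can be scored against the generating process.
#' The kinetic fields are defined only when `ruptured` is `TRUE`.
#'
#' @slot ruptured logical; did the bond fail within the simulated ramp?
#' @slot force true (noiseless) rupture force, pN.
#' @slot time true rupture time, s.
#' @slot loadingRate true loading rate dF/dt at rupture, pN/s (series
#'   stiffness at the rupture force times the retract speed).
#' @slot truncated logical; `TRUE` when the bond survived to the end of
#'   the simulated range ("no rupture within range").
#' @export
setClass("RuptureTruth",
  representation(ruptured = "logical", force = "numeric", time = "numeric",
                 loadingRate = "numeric", truncated = "logical"),
  prototype(ruptured = FALSE, force = NA_real_, time = NA_real_,
            loadingRate = NA_real_, truncated = FALSE))

setMethod("show", "RuptureTruth", function(object) {
  if (object@ruptured)
    cat(sprintf("RuptureTruth: F = %.4g pN at t = %.4g s, dF/dt = %.4g pN/s\n",
                object@force, object@time, object@loadingRate))
  else if (object@truncated)
    cat("RuptureTruth: no rupture within range (truncated)\n")
  else
    cat("RuptureTruth: no rupture (blank)\n")
})

#' A detected rupture event
#'
#' @slot force rupture force (pN), pre-drop force relative to baseline.
#' @slot extension extension at rupture (nm).
#' @slot slope slope k_S of the force-extension curve at rupture (pN/nm).
#' @slot loadingRate loading rate (pN/s) = k_S x retract speed.
#' @slot curveId label of the parent curve.
#' @slot retractSpeed retract speed of the parent curve (nm/s).
#' @slot status "ok" or "ambiguous" (several comparable drops).
#' @export
setClass("RuptureEvent",
  representation(force = "numeric", extension = "numeric", slope = "numeric",
                 loadingRate = "numeric", curveId = "character",
                 retractSpeed = "numeric", status = "character"),
  prototype(slope = NA_real_, loadingRate = NA_real_, curveId = "curve",
            retractSpeed = NA_real_, status = "ok"))

setMethod("show", "RuptureEvent", function(object) {
  cat(sprintf(paste0("RuptureEvent [%s] '%s': F = %.4g pN at %.4g nm",
                     "%s\n"),
              object@status, object@curveId, object@force, object@extension,
              if (is.finite(object@loadingRate))
                sprintf(", k_S = %.3g pN/nm, dF/dt = %.4g pN/s",
                        object@slope, object@loadingRate) else ""))
})

#' A worm-like chain fit to one curve
#'
#' @slot p fitted persistence length (nm).
#' @slot L fitted contour length (nm).
#' @slot r2 goodness of fit between 0 and 1, computed on bin-averaged data so
#'   that white sensor noise does not mask systematic misfit.
#' @slot window extension interval (nm, length 2) the fit used.
#' @slot valid logical; `FALSE` when the fit did not converge.
#' @export
setClass("WLCFit",
  representation(p = "numeric", L = "numeric", r2 = "numeric",
                 window = "numeric", valid = "logical"),
  prototype(p = NA_real_, L = NA_real_, r2 = 0,
            window = c(NA_real_, NA_real_), valid = FALSE))

setMethod("show", "WLCFit", function(object) {
  cat(sprintf("WLCFit%s: p = %.3g nm, L = %.4g nm, R2 = %.4f\n",
              if (object@valid) "" else " [invalid]",
              object@p, object@L, object@r2))
})

#' A Gaussian fit to a histogram
#'
#' Encodes the most probable value of a rupture-force or loading-rate
#' histogram. When `logDomain` is `TRUE`, the histogram was built on the
#' natural logs of the values and `mode` is reported back-transformed to
#' linear units; `sd` then refers to the log scale.
#'
#' @slot mode most probable value, in data units.
#' @slot sd Gaussian width (data units, or log units when `logDomain`).
#' @slot amplitude fitted peak height (counts).
#' @slot logDomain logical.
#' @slot nBins number of histogram bins used.
#' @export
setClass("GaussianFit",
  representation(mode = "numeric", sd = "numeric", amplitude = "numeric",
                 logDomain = "logical", nBins = "integer"),
  prototype(logDomain = FALSE, nBins = 18L))

setValidity("GaussianFit", function(object) {
  if (length(object@sd) == 1L && is.finite(object@sd) && object@sd <= 0)
    "'sd' must be positive" else TRUE
})

setClassUnion("GaussianFitOrNULL", c("GaussianFit", "NULL"))

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit%s: mode = %.4g, sd = %.3g, amplitude = %.3g\n",
              if (object@logDomain) " (log domain)" else "",
              object@mode, object@sd, object@amplitude))
})

#' Per-speed rupture ensemble
#'
#' All accepted rupture events recorded at one retract speed, together with
#' the Gaussian most-probable rupture force (fitted on the linear scale)
#' and most-probable loading rate (fitted in natural-log space). Fits are
#' only present when `nEvents` reaches the minimum (default 30); otherwise
#' the ensemble is `flagged` and carries `NULL` fits.
#'
#' @slot retractSpeed retract speed (nm/s).
#' @slot ruptureForces rupture forces (pN).
#' @slot loadingRates loading rates (pN/s).
#' @slot FStar [GaussianFit-class] for the forces, or `NULL`.
#' @slot rStar [GaussianFit-class] for the loading rates, or `NULL`.
#' @slot nEvents number of events.
#' @slot flagged logical; `TRUE` when the ensemble must not enter the
#'   Bell-Evans regression (too few events, or the force histogram's peak
#'   is not resolved above the detection limit).
#' @slot flagReason character; why the ensemble was flagged (`""` when
#'   not flagged).
#' @export
setClass("SpeedEnsemble",
  representation(retractSpeed = "numeric", ruptureForces = "numeric",
                 loadingRates = "numeric", FStar = "GaussianFitOrNULL",
                 rStar = "GaussianFitOrNULL", nEvents = "integer",
                 flagged = "logical", flagReason = "character"),
  prototype(FStar = NULL, rStar = NULL, flagged = FALSE, flagReason = ""))

setValidity("SpeedEnsemble", function(object) {
  msg <- character()
  if (length(object@ruptureForces) != object@nEvents ||
      length(object@loadingRates) != object@nEvents)
    msg <- c(msg, "'nEvents' must equal the array lengths")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpeedEnsemble", function(object) {
  cat(sprintf("SpeedEnsemble at v = %.4g nm/s: %d events%s",
              object@retractSpeed, object@nEvents,
              if (object@flagged)
                sprintf(" [flagged: %s]\n", object@flagReason) else ""))
  if (!object@flagged && !is.null(object@FStar))
    cat(sprintf(": F* = %.4g pN, r* = %.4g pN/s\n",
                object@FStar@mode, object@rStar@mode))
})

#' A Bell-Evans fit
#'
#' Result of regressing most probable rupture forces on the natural log of
#' the most probable loading rates: slope `kBT/deltaX` and intercept
#' encoding `koff`. `seKoff` is a multiplicative standard error (delta
#' method on the log scale): the 1-SE interval is
#' `koff / seKoff` to `koff * seKoff`.
#'
#' @slot koff extrapolated force-free dissociation rate (1/s).
#' @slot deltaX potential width (nm).
#' @slot seKoff multiplicative standard error of `koff` (>= 1, or NA).
#' @slot seDeltaX standard error of `deltaX` (nm, or NA).
#' @slot nPoints number of (F*, r*) points fitted.
#' @slot kBT thermal energy used (pN nm).
#' @slot slope regression slope (pN per ln(pN/s)).
#' @slot intercept regression intercept (pN).
#' @export
setClass("BellEvansFit",
  representation(koff = "numeric", deltaX = "numeric", seKoff = "numeric",
                 seDeltaX = "numeric", nPoints = "integer", kBT = "numeric",
                 slope = "numeric", intercept = "numeric"),
  prototype(seKoff = NA_real_, seDeltaX = NA_real_))

setValidity("BellEvansFit", function(object) {
  msg <- character()
  if (object@koff <= 0) msg <- c(msg, "'koff' must be positive")
  if (object@deltaX <= 0) msg <- c(msg, "'deltaX' must be positive")
  if (object@nPoints < 2L) msg <- c(msg, "'nPoints' must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BellEvansFit", function(object) {
  cat(sprintf(paste0("BellEvansFit (%d points): koff = %.3g 1/s (x/ %.3g), ",
                     "deltaX = %.3g nm (+/- %.2g)\n"),
              object@nPoints, object@koff, object@seKoff,
              object@deltaX, object@seDeltaX))
})
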