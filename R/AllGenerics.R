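#' Accessor generics
#'
#' Small accessor family for the value classes of the package; prefer
#' these over direct slot access.
#'
#' @param x an object of the documented classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("extension", function(x) standardGeneric("extension"))
#' @rdname accessors
#' @export
setGeneric("force", function(x) standardGeneric("force"))
#' @rdname accessors
#' @export
setGeneric("retractSpeed", function(x) standardGeneric("retractSpeed"))
#' @rdname accessors
#' @export
setGeneric("curveId", function(x) standardGeneric("curveId"))
#' @rdname accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
#' @rdname accessors
#' @export
setGeneric("persistenceLength", function(x) standardGeneric("persistenceLength"))
#' @rdname accessors
#' @export
setGeneric("contourLength", function(x) standardGeneric("contourLength"))
#' @rdname accessors
#' @export
setGeneric("thermalEnergy", function(x) standardGeneric("thermalEnergy"))
#' @rdname accessors
#' @export
setGeneric("koff", function(x) standardGeneric("koff"))
#' @rdname accessors
#' @export
setGeneric("deltaX", function(x) standardGeneric("deltaX"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("fittedMode", function(x) standardGeneric("fittedMode"))
#' @rdname accessors
#' @export
setGeneric("ruptureForce", function(x) standardGeneric("ruptureForce"))
#' @rdname accessors
#' @export
setGeneric("loadingRate", function(x) standardGeneric("loadingRate"))

#' @rdname accessors
#' @export
setMethod("extension", "ForceCurve", function(x) x@extension)
#' @rdname accessors
#' @export
setMethod("force", "ForceCurve", function(x) x@force)
#' @rdname accessors
#' @export
setMethod("retractSpeed", "ForceCurve", function(x) x@retractSpeed)
#' @rdname accessors
#' @export
setMethod("retractSpeed", "PullingGeometry", function(x) x@retractSpeed)
#' @rdname accessors
#' @export
setMethod("retractSpeed", "SpeedEnsemble", function(x) x@retractSpeed)
#' @rdname accessors
#' @export
setMethod("curveId", "ForceCurve", function(x) x@curveId)
#' @rdname accessors
#' @export
setMethod("curveId", "RuptureEvent", function(x) x@curveId)
#' @rdname accessors
#' @export
setMethod("replicateId", "ForceCurve", function(x) x@replicateId)
#' @rdname accessors
#' @export
setMethod("persistenceLength", "WLCModel", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("persistenceLength", "WLCFit", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("contourLength", "WLCModel", function(x) x@L)
#' @rdname accessors
#' @export
setMethod("contourLength", "WLCFit", function(x) x@L)
#' @rdname accessors
#' @export
setMethod("thermalEnergy", "WLCModel", function(x) x@kBT)
#' @rdname accessors
#' @export
setMethod("thermalEnergy", "BellParameters", function(x) x@kBT)
#' @rdname accessors
#' @export
setMethod("thermalEnergy", "BellEvansFit", function(x) x@kBT)
#' @rdname accessors
#' @export
setMethod("koff", "BellParameters", function(x) x@koff)
#' @rdname accessors
#' @export
setMethod("koff", "BellEvansFit", function(x) x@koff)
#' @rdname accessors
#' @export
setMethod("deltaX", "BellParameters", function(x) x@deltaX)
#' @rdname accessors
#' @export
setMethod("deltaX", "BellEvansFit", function(x) x@deltaX)
#' @rdname accessors
#' @export
setMethod("nEvents", "SpeedEnsemble", function(x) x@nEvents)
#' @rdname accessors
#' @export
setMethod("fittedMode", "GaussianFit", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("ruptureForce", "RuptureEvent", function(x) x@force)
#' @rdname accessors
#' @export
setMethod("ruptureForce", "RuptureTruth", function(x) x@force)
#' @rdname accessors
#' @export
setMethod("loadingRate", "RuptureEvent", function(x) x@loadingRate)
#' @rdname accessors
#' @export
setMethod("loadingRate", "RuptureTruth", function(x) x@loadingRate)
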