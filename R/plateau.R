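#' Average plateau force over an extension window
#'
#' Arithmetic mean of the force samples whose extension lies strictly
#' inside the window, the standard way of reading the phase-II plateau of
#' a rise-then-plateau trace (window (2, 6) nm at the two fastest retract
#' speeds, (2, 4) nm otherwise).
#'
#' @param curve a [ForceCurve-class].
#' @param window numeric length-2 open extension interval (nm).
#' @return Mean force in pN.
#' @examples
#' pc <- simulatePlateauCurve(40, 60, 5, noiseSigma = 0)
#' plateauForce(pc, c(2, 6))
#' @export
plateauForce <- function(curve, window) {
  stopifnot(is(curve, "ForceCurve"), length(window) == 2L,
            window[1] < window[2])
  x <- curve@extension
  if (min(x) > window[1] || max(x) < window[2])
    stop("curve does not span the averaging window")
  inside <- x > window[1] & x < window[2]
  if (!any(inside)) stop("no samples inside the averaging window")
  mean(curve@force[inside])
}

#' Convert a retract speed into a loading rate
#'
#' `dF/dt = k_L * v`, with `k_L` the proportionality constant estimated
#' from the phase-I slope of a force-extension trace (40 pN/nm for the
#' coiled-coil plateau branch: retract speeds of 1e6-1e9 nm/s map to
#' loading rates of 4e7-4e10 pN/s).
#'
#' @param v retract speed(s), nm/s (>= 0).
#' @param kL proportionality constant, pN/nm (> 0).
#' @return Loading rate(s), pN/s.
#' @examples
#' speedToLoadingRate(1e6, 40)  # 4e7 pN/s
#' @export
speedToLoadingRate <- function(v, kL) {
  if (any(v < 0)) stop("'v' must be nonnegative")
  if (kL <= 0) stop("'kL' must be positive")
  kL * v
}

#' Estimate k_L from a rise-then-plateau trace
#'
#' Crude estimate of the speed-to-loading-rate constant from the phase-I
#' chord of a force-extension plot: the plateau level divided by the
#' extension at the phase I to phase II transition. A plateau is required:
#' at least 2 nm of trace whose local slope is below 10% of the initial
#' slope; otherwise an error is raised.
#'
#' @param curve a [ForceCurve-class] with a rise-then-plateau shape.
#' @param minPlateauSpan minimum plateau length (nm).
#' @return `k_L` in pN/nm.
#' @examples
#' estimateKL(simulatePlateauCurve(40, 40, 5, noiseSigma = 0))  # 40
#' @export
estimateKL <- function(curve, minPlateauSpan = 2) {
  stopifnot(is(curve, "ForceCurve"))
  x <- curve@extension
  f <- curve@force
  n <- length(x)
  sm <- stats::runmed(f, k = min(31L, (n - 1L) %/% 2L * 2L + 1L))
  # initial slope from the first 20% of the rise (up to half maximum)
  half <- which(sm >= max(sm) / 2)[1]
  if (is.na(half) || half < 3L) half <- max(3L, n %/% 10L)
  cf0 <- stats::lm.fit(cbind(1, x[seq_len(half)]), f[seq_len(half)])
  k0 <- cf0$coefficients[2]
  if (!is.finite(k0) || k0 <= 0) stop("no initial force rise found")
  # local slope over ~0.5 nm spans
  dx <- stats::median(diff(x))
  lag <- max(1L, ceiling(0.5 / dx))
  slope <- (sm[seq_len(n - lag) + lag] - sm[seq_len(n - lag)]) / (lag * dx)
  flat <- slope < 0.1 * k0
  # longest run of flat slope
  r <- rle(flat)
  spans <- r$lengths * dx
  good <- which(r$values & spans >= minPlateauSpan)
  if (!length(good)) stop("no plateau detected (no >= 2 nm flat region)")
  iStart <- sum(r$lengths[seq_len(good[1] - 1L)]) + 1L
  iEnd <- iStart + r$lengths[good[1]] - 1L + lag
  plateau <- stats::median(sm[iStart:min(iEnd, n)])
  onset <- which(sm >= plateau * (1 - 1e-9))[1]
  if (is.na(onset)) onset <- iStart
  x0 <- x[onset]
  if (x0 <= 0) stop("degenerate plateau onset")
  unname(plateau / x0)
}
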