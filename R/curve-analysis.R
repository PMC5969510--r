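# Trailing-baseline window indices: the last max(50, 10%) samples.
baselineWindow <- function(curve) {
  n <- length(curve@extension)
  m <- max(50L, ceiling(0.1 * n))
  if (m >= n) stop("trace too short for baseline estimation")
  seq.int(n - m + 1L, n)
}

#' Baseline-correct a force curve
#'
#' Zero-force referencing: subtracts the median force of the trailing 10%
#' of the trace (at least 50 samples), which lies beyond the rupture for
#' any curve with an event. In `"linear"` mode a least-squares line fitted
#' to the trailing window is subtracted instead, removing an instrumental
#' baseline tilt.
#'
#' @param curve a [ForceCurve-class].
#' @param mode `"offset"` (default) or `"linear"`.
#' @return The corrected [ForceCurve-class] with `baselineCorrected = TRUE`.
#' @export
correctBaseline <- function(curve, mode = c("offset", "linear")) {
  mode <- match.arg(mode)
  stopifnot(is(curve, "ForceCurve"))
  idx <- baselineWindow(curve)
  f <- curve@force
  if (mode == "offset") {
    f <- f - stats::median(f[idx])
  } else {
    fit <- stats::lm.fit(cbind(1, curve@extension[idx]), f[idx])
    f <- f - (fit$coefficients[1] + fit$coefficients[2] * curve@extension)
  }
  initialize(curve, force = f, baselineCorrected = TRUE)
}

#' Estimate the force-noise level of a curve
#'
#' Robust per-sample noise sd from the trailing baseline: 1.4826 times the
#' median absolute deviation of the trailing 10% of the force samples.
#'
#' @param curve a [ForceCurve-class].
#' @return Estimated noise sd in pN.
#' @export
estimateNoiseSigma <- function(curve) {
  idx <- baselineWindow(curve)
  stats::mad(curve@force[idx])
}

#' Detect the rupture event of a retract curve
#'
#' Scans a baseline-corrected curve for the largest force drop completed
#' within a window of at most 2 nm of extension. A drop qualifies when it
#' exceeds `5 * noiseSigmaEst`. The drop profile is computed on a running
#' median of the force (robust to single outliers); the rupture force is
#' the pre-drop force relative to the (zeroed) baseline, read from a short
#' linear fit extrapolated to the drop point so that a loading ramp does
#' not bias it downward.
#'
#' If a second, well-separated drop comes within 20% of the largest one,
#' the curve cannot be attributed to a single bond and the event is
#' returned with `status = "ambiguous"`; such curves are excluded by
#' [filterEvents()].
#'
#' @param curve a [ForceCurve-class]; baseline-corrected (if not, it is
#'   corrected internally first).
#' @param noiseSigmaEst per-sample noise sd (pN); estimated from the
#'   trailing baseline when `NULL`.
#' @return A [RuptureEvent-class] (with `slope`/`loadingRate` still `NA`;
#'   see [loadingRateOfEvent()]) or `NULL` when no qualifying drop exists
#'   (blank curve).
#' @export
detectRupture <- function(curve, noiseSigmaEst = NULL) {
  stopifnot(is(curve, "ForceCurve"))
  if (!curve@baselineCorrected) curve <- correctBaseline(curve)
  if (is.null(noiseSigmaEst)) noiseSigmaEst <- estimateNoiseSigma(curve)
  x <- curve@extension
  f <- curve@force
  n <- length(x)
  dx <- stats::median(diff(x))
  sm <- stats::runmed(f, k = min(15L, (n - 1L) %/% 2L * 2L + 1L))
  lag <- max(1L, min(n - 1L, ceiling(1.2 / dx)))
  drop <- sm[seq_len(n - lag)] - sm[seq_len(n - lag) + lag]
  threshold <- 5 * noiseSigmaEst
  iMax <- which.max(drop)
  if (!length(iMax) || drop[iMax] <= threshold) return(NULL)
  # competing, well-separated drops of comparable size -> ambiguous
  comparable <- which(drop >= max(threshold, 0.8 * drop[iMax]))
  status <- if (any(abs(comparable - iMax) > 3L * lag)) "ambiguous" else "ok"
  # locate the drop point: last index (around iMax) still at the pre level
  w1 <- max(1L, iMax - lag); w2 <- min(n, iMax + 2L * lag)
  mid <- (sm[iMax] + sm[min(n, iMax + lag)]) / 2
  above <- which(sm[w1:w2] >= mid)
  j <- if (length(above)) w1 + above[length(above)] - 1L else iMax
  j <- min(j, n - 1L)
  # refine to the raw single-step drop (running-median crossings lag by
  # up to half the smoothing window)
  r1 <- max(1L, j - 7L); r2 <- min(n - 1L, j + lag)
  j <- r1 + which.max(f[r1:r2] - f[(r1 + 1L):(r2 + 1L)]) - 1L
  # pre-drop force from a short linear fit, evaluated at the drop point
  m <- max(5L, min(15L, j))
  pre <- seq.int(j - m + 1L, j)
  cf <- stats::lm.fit(cbind(1, x[pre]), f[pre])$coefficients
  fRup <- unname(cf[1] + cf[2] * x[j])
  new("RuptureEvent", force = fRup, extension = x[j],
      curveId = curve@curveId, retractSpeed = curve@retractSpeed,
      status = status)
}

#' Fit the worm-like chain model to the stretch region of a curve
#'
#' Nonlinear least squares of [wlcForce()] against the stretch region of
#' the curve, from the 5 pN crossing up to 95% of the rupture force.
#' Goodness of fit is reported as R-squared computed on bin-averaged data
#' (up to 50 equal-size bins over the fit window): averaging suppresses
#' white sensor noise so that the statistic measures systematic deviation
#' from the WLC shape, which is what the acceptance filter is meant to
#' catch.
#'
#' @param curve a baseline-corrected [ForceCurve-class].
#' @param event the curve's [RuptureEvent-class].
#' @param kBT thermal energy (pN nm).
#' @param onsetForce lower force bound of the fit window (pN).
#' @param upperFrac upper bound as a fraction of the rupture force.
#' @return A [WLCFit-class]; when the optimizer fails to converge the fit
#'   is returned invalid with `r2 = 0`.
#' @export
fitWLC <- function(curve, event, kBT = 4.114, onsetForce = 5,
                   upperFrac = 0.95) {
  stopifnot(is(curve, "ForceCurve"), is(event, "RuptureEvent"))
  x <- curve@extension
  f <- curve@force
  n <- length(x)
  sm <- stats::runmed(f, k = min(15L, (n - 1L) %/% 2L * 2L + 1L))
  jEnd <- which(x >= event@extension)[1] - 1L
  if (is.na(jEnd)) jEnd <- n
  upper <- upperFrac * event@force
  start <- which(sm[seq_len(jEnd)] >= onsetForce)[1]
  if (is.na(start)) stop("no force onset found below the rupture")
  ws <- which(sm[start:jEnd] <= upper)
  if (!length(ws)) stop("empty fit window below the rupture force")
  end <- start + max(ws) - 1L
  idx <- start:end
  if (length(idx) < 100L)
    stop("need >= 100 points between force onset and rupture")
  xw <- x[idx]; fw <- f[idx]
  xEnd <- xw[length(xw)]
  fEnd <- max(sm[end], onsetForce)
  p0 <- 0.4
  L0 <- xEnd / max(0.2, min(0.98, 1 - sqrt(kBT / (4 * p0 * fEnd))))
  fit <- tryCatch(
    stats::nls(fw ~ (kBT / p) * (0.25 / (1 - xw / L)^2 - 0.25 + xw / L),
               start = list(p = p0, L = L0), algorithm = "port",
               lower = c(p = 1e-3, L = xEnd * 1.001),
               upper = c(p = 100, L = 100 * xEnd),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("WLCFit", window = range(xw), valid = FALSE, r2 = 0))
  cf <- stats::coef(fit)
  mdl <- WLCModel(p = unname(cf["p"]), L = unname(cf["L"]), kBT = kBT)
  nb <- max(5L, min(50L, length(idx) %/% 4L))
  bins <- cut(seq_along(idx), nb, labels = FALSE)
  bx <- tapply(xw, bins, mean)
  bf <- tapply(fw, bins, mean)
  pred <- wlcForce(pmin(as.numeric(bx), mdl@L * (1 - 1e-9)), mdl)
  ssRes <- sum((as.numeric(bf) - pred)^2)
  ssTot <- sum((as.numeric(bf) - mean(bf))^2)
  r2 <- if (ssTot > 0) max(0, min(1, 1 - ssRes / ssTot)) else 0
  new("WLCFit", p = unname(cf["p"]), L = unname(cf["L"]), r2 = r2,
      window = range(xw), valid = TRUE)
}

#' Slope at rupture and loading rate of an event
#'
#' Ordinary least squares slope `k_S` of the force-extension curve over
#' the last `window` nm before the rupture; the loading rate is
#' `k_S` times the retract speed of the parent curve (dF/dt = dF/dx * v).
#'
#' @param curve a baseline-corrected [ForceCurve-class].
#' @param event the curve's [RuptureEvent-class].
#' @param window extension window before the rupture (nm); default 5.
#' @return The [RuptureEvent-class] with `slope` (pN/nm) and
#'   `loadingRate` (pN/s) filled in.
#' @export
loadingRateOfEvent <- function(curve, event, window = 5) {
  stopifnot(is(curve, "ForceCurve"), is(event, "RuptureEvent"))
  x <- curve@extension
  idx <- which(x >= event@extension - window & x <= event@extension)
  if (length(idx) < 10L)
    stop("need >= 10 points in the pre-rupture slope window")
  cf <- stats::lm.fit(cbind(1, x[idx]), curve@force[idx])$coefficients
  kS <- unname(cf[2])
  initialize(event, slope = kS, loadingRate = kS * curve@retractSpeed)
}

#' Apply the event acceptance filters
#'
#' Keeps detected, unambiguous events whose WLC fit has a contour length
#' above `minL` (default 100 nm, the published acceptance rule for curves
#' stretching both PEG spacers) and goodness `r2 >= minR2` (default 0.95,
#' the reproducible surrogate for "fitted well by visual inspection").
#' Input order is preserved and every record receives an explicit
#' acceptance reason, so the log partitions the input exactly; the filter
#' is idempotent.
#'
#' @param results a per-curve results data.frame from [analyzeCurves()]
#'   (columns `detected`, `status`, `wlc_valid`, `wlc_L`, `wlc_r2`).
#' @param minL minimum contour length (nm).
#' @param minR2 minimum goodness of fit.
#' @return The data.frame with columns `accepted` (logical) and `reason`
#'   (character, `"accepted"` for kept records) rewritten.
#' @export
filterEvents <- function(results, minL = 100, minR2 = 0.95) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) {
    results$accepted <- logical(0)
    results$reason <- character(0)
    return(results)
  }
  reason <- rep("accepted", nrow(results))
  reason[!results$detected] <- "no event detected"
  amb <- results$detected & results$status == "ambiguous"
  reason[amb] <- "ambiguous: multiple comparable drops"
  bad <- results$detected & !amb & !results$wlc_valid
  reason[bad] <- "invalid WLC fit"
  shortL <- results$detected & !amb & results$wlc_valid &
    results$wlc_L <= minL
  reason[shortL] <- sprintf("contour length <= %g nm", minL)
  lowR2 <- results$detected & !amb & results$wlc_valid &
    results$wlc_L > minL & results$wlc_r2 < minR2
  reason[lowR2] <- sprintf("R2 < %g", minR2)
  results$accepted <- reason == "accepted"
  results$reason <- reason
  results
}

#' Run the per-curve analysis over an ensemble
#'
#' Baseline correction, rupture detection, WLC fitting, slope-at-rupture
#' and acceptance filtering for a batch of curves. This is the per-curve
#' stage of the pipeline; its output feeds [buildSpeedEnsembles()].
#'
#' @param curves a list of [ForceCurve-class] objects, or a list of
#'   `list(curve =, truth =)` pairs as returned by [simulateEnsemble()]
#'   (truth columns are then carried through for validation).
#' @param minL,minR2 acceptance thresholds, see [filterEvents()].
#' @param slopeWindow pre-rupture slope window (nm).
#' @param kBT thermal energy for the WLC fits (pN nm).
#' @param baselineMode passed to [correctBaseline()].
#' @return A data.frame with one row per curve: identifiers, detection
#'   results, WLC fit parameters, loading rates, acceptance flags and
#'   (when available) simulation ground truth.
#' @export
analyzeCurves <- function(curves, minL = 100, minR2 = 0.95, slopeWindow = 5,
                          kBT = 4.114, baselineMode = "offset") {
  hasTruth <- length(curves) > 0L && is.list(curves[[1]]) &&
    !is(curves[[1]], "ForceCurve")
  rows <- lapply(curves, function(el) {
    curve <- if (hasTruth) el$curve else el
    truth <- if (hasTruth) el$truth else NULL
    curve <- correctBaseline(curve, mode = baselineMode)
    sigma <- estimateNoiseSigma(curve)
    event <- detectRupture(curve, noiseSigmaEst = sigma)
    row <- data.frame(
      curve_id = curve@curveId, replicate_id = curve@replicateId,
      retract_speed = curve@retractSpeed, noise_sigma_est = sigma,
      detected = !is.null(event), status = NA_character_,
      rupture_force = NA_real_, rupture_extension = NA_real_,
      slope = NA_real_, loading_rate = NA_real_,
      wlc_valid = FALSE, wlc_p = NA_real_, wlc_L = NA_real_, wlc_r2 = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(event)) {
      event <- tryCatch(loadingRateOfEvent(curve, event, window = slopeWindow),
                        error = function(e) event)
      fit <- tryCatch(fitWLC(curve, event, kBT = kBT),
                      error = function(e)
                        new("WLCFit", valid = FALSE, r2 = 0,
                            window = c(NA_real_, NA_real_)))
      row$status <- event@status
      row$rupture_force <- event@force
      row$rupture_extension <- event@extension
      row$slope <- event@slope
      row$loading_rate <- event@loadingRate
      row$wlc_valid <- fit@valid
      row$wlc_p <- fit@p
      row$wlc_L <- fit@L
      row$wlc_r2 <- fit@r2
    }
    if (!is.null(truth)) {
      row$true_ruptured <- truth@ruptured
      row$true_force <- truth@force
      row$true_loading_rate <- truth@loadingRate
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  filterEvents(out, minL = minL, minR2 = minR2)
}
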