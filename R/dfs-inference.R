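#' Most probable value of a sample via a Gaussian histogram fit
#'
#' Builds a histogram of the values (or of their natural logs when
#' `logDomain = TRUE`, the standard treatment for loading rates) and fits
#' a Gaussian `A exp(-(x - mu)^2 / (2 s^2))` to the bin centers and counts
#' by nonlinear least squares. The fitted `mu` is the most probable value;
#' it is back-transformed with `exp()` when fitting in log space.
#'
#' @param values numeric sample (>= 30 values).
#' @param logDomain fit the histogram of `log(values)`?
#' @param nBins number of histogram bins (default 18).
#' @return A [GaussianFit-class].
#' @examples
#' x <- rnorm(1000, 44, 6)
#' fittedMode(gaussianMostProbable(x))
#' @export
gaussianMostProbable <- function(values, logDomain = FALSE, nBins = 18L) {
  if (length(values) < 30L) stop("need at least 30 values")
  if (logDomain && any(values <= 0))
    stop("nonpositive values in log domain")
  x <- if (logDomain) log(values) else values
  if (any(!is.finite(x))) stop("non-finite values")
  if (diff(range(x)) == 0) stop("degenerate histogram: all values identical")
  breaks <- seq(min(x), max(x), length.out = nBins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  xc <- h$mids
  ct <- h$counts
  mu0 <- xc[which.max(ct)]
  s0 <- max(stats::sd(x), diff(breaks[1:2]))
  a0 <- max(ct)
  binW <- diff(breaks[1:2])
  cf <- NULL
  for (sTry in c(1, 0.5, 2)) {
    fit <- tryCatch(
      stats::nls(ct ~ A * exp(-(xc - mu)^2 / (2 * s^2)),
                 start = list(A = a0, mu = mu0, s = s0 * sTry),
                 algorithm = "port",
                 lower = c(A = 1e-8, mu = mu0 - 10 * s0, s = binW / 4),
                 upper = c(A = 10 * a0, mu = mu0 + 10 * s0, s = 20 * s0),
                 control = stats::nls.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) { cf <- stats::coef(fit); break }
  }
  if (is.null(cf)) {
    # Nelder-Mead least squares; robust when Gauss-Newton steps fail on
    # strongly skewed histograms
    obj <- function(par) sum((ct - par[1] *
                                exp(-(xc - par[2])^2 / (2 * par[3]^2)))^2)
    opt <- stats::optim(c(a0, mu0, s0), obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (opt$convergence != 0 || opt$par[3] <= 0 ||
        !all(is.finite(opt$par)))
      stop(sprintf(paste0("Gaussian histogram fit did not converge ",
                          "(%d bins, counts %s)"), nBins,
                   paste(ct, collapse = ",")))
    cf <- c(A = opt$par[1], mu = opt$par[2], s = abs(opt$par[3]))
  }
  mode <- if (logDomain) exp(unname(cf["mu"])) else unname(cf["mu"])
  new("GaussianFit", mode = mode, sd = unname(cf["s"]),
      amplitude = unname(cf["A"]), logDomain = logDomain,
      nBins = as.integer(nBins))
}

#' Group accepted events into per-speed ensembles
#'
#' One [SpeedEnsemble-class] per retract speed, with the Gaussian most
#' probable rupture force (linear scale) and most probable loading rate
#' (natural-log scale, back-transformed). Speeds with fewer than
#' `minEvents` accepted events are emitted flagged, without fits.
#'
#' Rupture detection censors events below its threshold (5x the noise
#' sd), so at speeds where the bond breaks near that limit the
#' rupture-force histogram is left-truncated and its Gaussian "mode" is an
#' artifact of the detection limit, not a most probable force. Two
#' validity checks guard against this. (1) Completeness: within a panel
#' all speeds share the same attempt statistics, so an ensemble whose
#' accepted-event count falls below `minYield` times the panel's maximum
#' has lost the bulk of its events below the detection limit and is
#' flagged `"low event yield (detection-limit censoring)"`. (2)
#' Resolution: an ensemble whose fitted mode minus `censorMargin`
#' Gaussian widths falls below the median detection threshold is flagged
#' `"mode not resolved above detection limit"`. Under the Bell model the
#' rupture-force distribution width is the same at every speed
#' (proportional to `kBT/deltaX`), while censoring only ever shrinks the
#' observed width; the panel maximum of the per-speed sample sds is
#' therefore the estimate of the uncensored width used for this check
#' (it requires a `noise_sigma_est` column and is skipped without one). Flagged
#' ensembles keep their data but are excluded from the Bell-Evans
#' regression.
#'
#' @param results per-curve results data.frame from [analyzeCurves()]
#'   (only rows with `accepted == TRUE` are used), or any data.frame with
#'   columns `retract_speed`, `rupture_force`, `loading_rate` (and
#'   optionally `noise_sigma_est`).
#' @param minEvents minimum events per speed for fitting (default 30).
#' @param nBins histogram bins for the Gaussian fits.
#' @param censorMargin how many fitted Gaussian widths the mode must sit
#'   above the detection threshold to count as resolved (default 1).
#' @param minYield minimum accepted-event yield relative to the panel's
#'   best-sampled speed (default 0.5).
#' @return A list of [SpeedEnsemble-class], ordered by retract speed.
#' @export
buildSpeedEnsembles <- function(results, minEvents = 30L, nBins = 18L,
                                censorMargin = 1, minYield = 0.5) {
  stopifnot(is.data.frame(results))
  if ("accepted" %in% names(results)) results <- results[results$accepted, ]
  speeds <- sort(unique(results$retract_speed))
  yields <- vapply(speeds, function(v)
    sum(results$retract_speed == v), numeric(1))
  yieldCut <- minYield * max(yields)
  # first pass: Gaussian fits per speed
  ens <- lapply(speeds, function(v) {
    sub <- results[results$retract_speed == v, ]
    forces <- sub$rupture_force
    rates <- sub$loading_rate
    ok <- is.finite(forces) & is.finite(rates) & rates > 0
    forces <- forces[ok]; rates <- rates[ok]
    nev <- length(forces)
    if (nev < minEvents)
      return(new("SpeedEnsemble", retractSpeed = v, ruptureForces = forces,
                 loadingRates = rates, FStar = NULL, rStar = NULL,
                 nEvents = nev, flagged = TRUE,
                 flagReason = sprintf("fewer than %d events", minEvents)))
    fStar <- gaussianMostProbable(forces, logDomain = FALSE, nBins = nBins)
    rStar <- gaussianMostProbable(rates, logDomain = TRUE, nBins = nBins)
    limit <- if ("noise_sigma_est" %in% names(sub))
      5 * stats::median(sub$noise_sigma_est[ok]) else NA_real_
    e <- new("SpeedEnsemble", retractSpeed = v, ruptureForces = forces,
             loadingRates = rates, FStar = fStar, rStar = rStar,
             nEvents = nev, flagged = FALSE, flagReason = "")
    attr(e, "detectionLimit") <- limit
    e
  })
  # second pass: validity flags; the Bell-model force-distribution width
  # is speed-invariant and censoring only shrinks it, so the panel max
  # of the sample sds estimates the uncensored width
  sdRef <- max(vapply(Filter(function(e) !is.null(e@FStar), ens),
                      function(e) stats::sd(e@ruptureForces),
                      numeric(1)))
  lapply(ens, function(e) {
    if (e@flagged || is.null(e@FStar)) return(e)
    limit <- attr(e, "detectionLimit")
    attr(e, "detectionLimit") <- NULL
    if (e@nEvents < yieldCut)
      return(initialize(e, flagged = TRUE,
        flagReason = "low event yield (detection-limit censoring)"))
    width <- max(e@FStar@sd, sdRef)
    if (is.finite(limit) && e@FStar@mode - censorMargin * width < limit)
      return(initialize(e, flagged = TRUE,
        flagReason = "mode not resolved above detection limit"))
    e
  })
}

#' Bell-Evans regression of most probable force on log loading rate
#'
#' Ordinary least squares of `F*` on `ln(r*)`. The slope `s` gives the
#' potential width `deltaX = kBT / s`; the intercept `c` gives the
#' force-free dissociation rate `koff = (deltaX / kBT) * exp(-c / s)`.
#' Standard errors come from the regression covariance by the delta
#' method; the `koff` error is multiplicative (symmetric on the log
#' scale).
#'
#' @param FStar most probable rupture forces (pN), one per speed.
#' @param rStar most probable loading rates (pN/s), same length. Instead
#'   of two vectors, a list of [SpeedEnsemble-class] (unflagged ones are
#'   used) may be given as `FStar`.
#' @param kBT thermal energy (pN nm).
#' @return A [BellEvansFit-class].
#' @examples
#' bell <- ccConstruct("A4B4")
#' r <- 10^(1:4)
#' fit <- fitBellEvans(bellEvansMode(bell, r), r)
#' c(koff(fit), deltaX(fit))
#' @export
fitBellEvans <- function(FStar, rStar = NULL, kBT = 4.114) {
  if (is.list(FStar) && is.null(rStar)) {
    ens <- Filter(function(e) !e@flagged, FStar)
    rStar <- vapply(ens, function(e) e@rStar@mode, numeric(1))
    FStar <- vapply(ens, function(e) e@FStar@mode, numeric(1))
  }
  stopifnot(length(FStar) == length(rStar), all(rStar > 0))
  keep <- !duplicated(rStar)
  nDistinct <- sum(keep)
  if (nDistinct < 2L) stop("need at least 2 distinct loading rates")
  if (nDistinct == 2L)
    warning("Bell-Evans fit to only 2 points: exact line, no error estimate")
  lr <- log(rStar)
  fit <- stats::lm(FStar ~ lr)
  s <- unname(stats::coef(fit)[2])
  cc <- unname(stats::coef(fit)[1])
  if (!is.finite(s) || s <= 0)
    stop("no Bell-Evans regime: nonpositive slope of F* vs ln(loading rate)")
  dx <- kBT / s
  koff <- (dx / kBT) * exp(-cc / s)
  seDx <- NA_real_; seK <- NA_real_
  if (length(FStar) > 2L) {
    # suppress the "essentially perfect fit" note on collinear input
    V <- suppressWarnings(stats::vcov(fit))
    seS <- sqrt(V[2, 2])
    seDx <- kBT / s^2 * seS
    # g = ln koff = -ln s - c/s ; grad = (dg/dc, dg/ds)
    grad <- c(-1 / s, -1 / s + cc / s^2)
    vG <- drop(t(grad) %*% V[c(1, 2), c(1, 2)] %*% grad)
    seK <- exp(sqrt(max(vG, 0)))
  }
  new("BellEvansFit", koff = koff, deltaX = dx, seKoff = seK,
      seDeltaX = seDx, nPoints = length(FStar), kBT = kBT,
      slope = s, intercept = cc)
}

#' Aggregate Bell-Evans fits across replicates
#'
#' Arithmetic mean and standard error of the mean of `deltaX` and `koff`
#' across independent cantilever/surface replicates; `koff` is aggregated
#' on the linear scale (matching the conventional mean +/- SEM reporting),
#' with a geometric-mean alternative available.
#'
#' @param fits a list of [BellEvansFit-class].
#' @param koffScale `"linear"` (default) or `"geometric"`.
#' @return A data.frame with rows `koff` and `deltaX` and columns `mean`,
#'   `sem` (NA for a single fit) and `n`.
#' @export
aggregateReplicates <- function(fits, koffScale = c("linear", "geometric")) {
  koffScale <- match.arg(koffScale)
  stopifnot(length(fits) >= 1L)
  ks <- vapply(fits, function(f) f@koff, numeric(1))
  dxs <- vapply(fits, function(f) f@deltaX, numeric(1))
  n <- length(fits)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  kMean <- if (koffScale == "linear") mean(ks) else exp(mean(log(ks)))
  kSem <- if (koffScale == "linear") sem(ks)
          else if (n > 1L) kMean * stats::sd(log(ks)) / sqrt(n) else NA_real_
  data.frame(parameter = c("koff", "deltaX"),
             mean = c(kMean, mean(dxs)),
             sem = c(kSem, sem(dxs)),
             n = n,
             stringsAsFactors = FALSE)
}
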