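test_that("Gaussian histogram fits locate the most probable value", {
  set.seed(10)
  x <- rnorm(1e4, 44, 6)
  gf <- gaussianMostProbable(x)
  expect_equal(fittedMode(gf), 44, tolerance = 0.2 / 44)
  expect_equal(gf@sd, 6, tolerance = 0.05)
  # loading rates: fit in log space, mode back-transformed
  set.seed(11)
  y <- rlnorm(1e4, log(600), 0.4)
  gfy <- gaussianMostProbable(y, logDomain = TRUE)
  expect_true(gfy@logDomain)
  expect_equal(fittedMode(gfy), 600, tolerance = 0.05)
  # error contracts
  expect_error(gaussianMostProbable(rep(5, 100)), "degenerate")
  expect_error(gaussianMostProbable(rnorm(10)), "at least 30")
  expect_error(gaussianMostProbable(c(-1, rlnorm(99)), logDomain = TRUE),
               "nonpositive")
})

test_that("per-speed ensembles are built with fits, flags and monotone rates", {
  set.seed(12)
  mk <- function(v, n) data.frame(
    retract_speed = v, rupture_force = rnorm(n, 40, 5),
    loading_rate = rlnorm(n, log(1.6 * v), 0.3),
    noise_sigma_est = 4, accepted = TRUE)
  ens <- buildSpeedEnsembles(rbind(mk(200, 100), mk(800, 100)))
  expect_length(ens, 2L)
  expect_false(any(vapply(ens, function(e) e@flagged, logical(1))))
  expect_s4_class(ens[[1]]@FStar, "GaussianFit")
  expect_s4_class(ens[[1]]@rStar, "GaussianFit")
  expect_identical(nEvents(ens[[1]]), 100L)
  # a sparse speed is flagged without fits
  ens2 <- buildSpeedEnsembles(rbind(mk(200, 100), mk(800, 10)))
  expect_true(ens2[[2]]@flagged)
  expect_match(ens2[[2]]@flagReason, "fewer than")
  expect_null(ens2[[2]]@FStar)
  # full simulated panel: most probable loading rates increase with speed
  run <- getPanelRun("A4B4")
  fitted <- Filter(function(e) !e@flagged, run@ensembles)
  rStars <- vapply(fitted, function(e) fittedMode(e@rStar), numeric(1))
  expect_length(fitted, 8L)
  expect_true(all(diff(rStars) > 0))
})

test_that("detection-limit censored ensembles are flagged out of the regression", {
  run <- getPanelRun("A4B3.5")
  flags <- vapply(run@ensembles, function(e) e@flagged, logical(1))
  vs <- vapply(run@ensembles, retractSpeed, numeric(1))
  # censoring hits the slowest speeds: the flagged set is a nonempty
  # prefix of the speed panel that includes 50 and 100 nm/s, and most of
  # the panel stays in the regression
  expect_true(all(vs[flags] <= 200))
  expect_true(all(c(50, 100) %in% vs[flags]))
  expect_gte(sum(!flags), 5L)
  flagged <- run@ensembles[flags]
  expect_true(all(grepl("yield|detection limit",
                        vapply(flagged, function(e) e@flagReason,
                               character(1)))))
  # the weakest construct ruptures near the 5-sigma = 20 pN limit at
  # slow speeds; its surviving histograms there are upper-tail remnants
  expect_lt(nEvents(flagged[[1]]), 0.5 * max(vapply(run@ensembles,
                                                    nEvents, integer(1))))
})

test_that("Bell-Evans regression inverts the mode law and propagates errors", {
  b <- ccConstruct("A4B4")
  r <- c(10, 100, 1000, 10000)
  fit <- fitBellEvans(bellEvansMode(b, r), r)
  expect_equal(deltaX(fit), 1.29, tolerance = 1e-9)
  expect_equal(koff(fit), 3.2e-4, tolerance = 1e-8)
  expect_equal(fit@slope, 4.114 / 1.29, tolerance = 1e-10)
  # noiseless collinear points leave (numerically) no residual error
  expect_lt(fit@seDeltaX, 1e-6)
  # 0.5 pN perturbations: median deltaX within 5% over 100 replicates
  set.seed(13)
  dxs <- replicate(100, {
    f <- fitBellEvans(bellEvansMode(b, r) + rnorm(4, 0, 0.5), r)
    deltaX(f)
  })
  expect_lt(abs(median(dxs) / 1.29 - 1), 0.05)
  # two points: exact line plus a warning
  expect_warning(f2 <- fitBellEvans(bellEvansMode(b, c(100, 1e4)),
                                    c(100, 1e4)), "2 points")
  expect_equal(deltaX(f2), 1.29, tolerance = 1e-9)
  expect_true(is.na(f2@seDeltaX))
  # decreasing F* with rate has no Bell-Evans interpretation
  expect_error(fitBellEvans(c(50, 40, 30), c(10, 100, 1000)),
               "no Bell-Evans regime")
  expect_error(fitBellEvans(c(40, 41), c(100, 100)), "distinct")
})

test_that("replicate aggregation reports mean and SEM on the stated scales", {
  mkFit <- function(k, dx) new("BellEvansFit", koff = k, deltaX = dx,
                               nPoints = 8L, kBT = 4.114, slope = 4.114 / dx,
                               intercept = 1)
  fits <- list(mkFit(1e-3, 1.2), mkFit(1e-3, 1.3), mkFit(1e-3, 1.4))
  agg <- aggregateReplicates(fits)
  dxRow <- agg[agg$parameter == "deltaX", ]
  expect_equal(dxRow$mean, 1.30, tolerance = 1e-12)
  expect_equal(dxRow$sem, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_identical(agg[agg$parameter == "koff", "sem"], 0)
  # single fit: mean is the value, SEM reported as absent
  agg1 <- aggregateReplicates(fits[1])
  expect_equal(agg1$mean, c(1e-3, 1.2), tolerance = 1e-12)
  expect_true(all(is.na(agg1$sem)))
  # SEM scales as 1/sqrt(n) on identically distributed fits
  set.seed(14)
  semAt <- function(n) mean(replicate(50, {
    fs <- lapply(rnorm(n, 1.3, 0.1), function(d) mkFit(1e-3, d))
    aggregateReplicates(fs)[2, "sem"]
  }))
  expect_equal(semAt(4) / semAt(16), 2, tolerance = 0.25)
  # geometric aggregation option
  aggG <- aggregateReplicates(list(mkFit(1e-4, 1), mkFit(1e-2, 1)),
                              koffScale = "geometric")
  expect_equal(aggG[1, "mean"], 1e-3, tolerance = 1e-12)
})

test_that("plateau branch: window averaging, k_L estimation and conversion", {
  pc <- simulatePlateauCurve(40, 60, 5, noiseSigma = 0)
  expect_error(plateauForce(pc, c(2, 50)), "span")
  expect_equal(estimateKL(pc), 40, tolerance = 0.01)
  expect_equal(estimateKL(simulatePlateauCurve(80, 40, 5, noiseSigma = 0)),
               80, tolerance = 0.01)
  # monotone ramp has no plateau
  ramp <- ForceCurve(seq(0, 10, length.out = 2000),
                     seq(0, 400, length.out = 2000), retractSpeed = 1e6)
  expect_error(estimateKL(ramp), "no plateau")
  # speed-to-loading-rate conversion (k_L = 40 pN/nm)
  expect_identical(speedToLoadingRate(1e6, 40), 4e7)
  expect_identical(speedToLoadingRate(1e9, 40), 4e10)
  expect_identical(speedToLoadingRate(0, 40), 0)
  expect_error(speedToLoadingRate(-1, 40), "nonnegative")
})
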