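test_that("simulation is deterministic under fixed seeds", {
  g <- PullingGeometry(retractSpeed = 400)
  m <- WLCModel(); b <- ccConstruct("A4B4")
  s1 <- simulateCurve(g, m, b, seed = 17)
  s2 <- simulateCurve(g, m, b, seed = 17)
  expect_identical(s1$curve@force, s2$curve@force)
  expect_identical(s1$truth@force, s2$truth@force)
  # ensembles: byte-identical serialized output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  e1 <- simulateEnsemble(g, m, b, nCurves = 5, blankFraction = 0.4, seed = 3)
  e2 <- simulateEnsemble(g, m, b, nCurves = 5, blankFraction = 0.4, seed = 3)
  writeForceCurves(e1, d1); writeForceCurves(e2, d2)
  for (fn in list.files(d1))
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  # blank assignment is part of the seeded state
  blank1 <- vapply(e1, function(s) !s$truth@ruptured && !s$truth@truncated,
                   logical(1))
  blank2 <- vapply(e2, function(s) !s$truth@ruptured && !s$truth@truncated,
                   logical(1))
  expect_identical(blank1, blank2)
  expect_identical(sum(blank1), 2L)  # round(0.4 * 5)
})

test_that("a bond with no escape channel never ruptures and traces the circuit", {
  g <- PullingGeometry(retractSpeed = 400, noiseSigma = 0)
  m <- WLCModel()
  s <- simulateCurve(g, m, BellParameters(0, 1.29), seed = 4)
  expect_false(s$truth@ruptured)
  expect_true(s$truth@truncated)
  D <- extension(s$curve)
  i <- c(100, 1000, 2500)
  eq <- seriesEquilibrium(D[i], g, m)
  expect_equal(force(s$curve)[i], eq$force, tolerance = 1e-9)
})

test_that("force-independent escape gives exponential rupture times", {
  # deltaX = 0, koff = 1/s: times ~ Exp(1); slow retract so the ramp
  # (15 s) far exceeds the mean lifetime
  g <- PullingGeometry(retractSpeed = 10, noiseSigma = 0)
  ens <- simulateEnsemble(g, WLCModel(), BellParameters(1, 0),
                          nCurves = 2000, blankFraction = 0, seed = 6)
  tt <- vapply(ens, function(s) s$truth@time, numeric(1))
  # scaled from the 1e4-seed design (3 sigma at n = 2000 is 0.067)
  expect_equal(mean(tt), 1, tolerance = 0.07)
})

test_that("circuit-sampled rupture forces follow the first-passage law", {
  ens <- getNoiselessBigEnsemble()
  b <- ccConstruct("A4B4")
  tf <- vapply(ens, function(s) s$truth@force, numeric(1))
  tr <- vapply(ens, function(s) s$truth@loadingRate, numeric(1))
  expect_true(all(vapply(ens, function(s) s$truth@ruptured, logical(1))))
  # exact check: PIT through the trace's cumulative hazard is uniform
  g <- PullingGeometry(retractSpeed = 400, noiseSigma = 0)
  trace <- ccDFS:::pullingTrace(g, WLCModel())
  H <- ccDFS:::cumulativeHazard(trace, b)
  tt <- vapply(ens, function(s) s$truth@time, numeric(1))
  u <- 1 - exp(-approx(trace$time, H, xout = tt)$y)
  ks <- suppressWarnings(stats::ks.test(u, stats::punif))
  expect_lt(unname(ks$statistic), 0.04)
  # approximate check: the constant-rate law at each curve's realized
  # loading rate; the rate varies along the trajectory, which alone
  # contributes ~0.06 KS at this geometry
  pit <- mapply(function(F, r) linearLoadingCdf(F, b@koff, b@deltaX,
                                                b@kBT, r), tf, tr)
  ks2 <- suppressWarnings(stats::ks.test(pit, stats::punif))
  expect_lt(unname(ks2$statistic), 0.08)
})

test_that("realized loading rate matches the analytic series stiffness at rupture", {
  g <- PullingGeometry(retractSpeed = 400, noiseSigma = 0)
  m <- WLCModel(); b <- ccConstruct("A4B4")
  for (seed in c(8, 9, 10)) {
    s <- simulateCurve(g, m, b, seed = seed)
    zr <- uniroot(function(z) wlcForce(z, m) - s$truth@force,
                  c(0, 0.999 * m@L), tol = 1e-10)$root
    expect_equal(s$truth@loadingRate,
                 seriesStiffness(zr, g, m) * 400, tolerance = 0.02)
    # and the numeric slope of the noiseless trace agrees
    D <- extension(s$curve); f <- force(s$curve)
    i <- max(which(f > 0))
    num <- (f[i - 1] - f[i - 8]) / (D[i - 1] - D[i - 8]) * 400
    expect_equal(s$truth@loadingRate, num, tolerance = 0.05)
  }
})

test_that("idealized constant-rate sampler reproduces the closed-form law", {
  # exponential limit
  f0 <- simulateLinearLoadingEvents(BellParameters(1, 0), 100, 1e4,
                                    seed = 13)
  expect_equal(mean(f0), 100, tolerance = 3 / 100)
  expect_true(all(f0 >= 0))
  # single draw contract
  f1 <- simulateLinearLoadingEvents(ccConstruct("A4B4"), 1000, 1, seed = 2)
  expect_true(is.finite(f1) && f1 >= 0)
  # kernel mode near the Bell-Evans mode (~44 pN at 1000 pN/s)
  fs <- simulateLinearLoadingEvents(ccConstruct("A4B4"), 1000, 1e4,
                                    seed = 12)
  d <- stats::density(fs)
  expect_equal(d$x[which.max(d$y)], 43.9948968044709, tolerance = 1 / 44)
  # KS < 0.05 against the closed-form CDF at three (bell, rate) settings
  settings <- list(list(b = ccConstruct("A4B4"), r = 1000),
                   list(b = ccConstruct("A4B3"), r = 200),
                   list(b = ccConstruct("A4B3.5"), r = 5000))
  for (k in seq_along(settings)) {
    b <- settings[[k]]$b; r <- settings[[k]]$r
    x <- simulateLinearLoadingEvents(b, r, 2000, seed = 20 + k)
    ks <- suppressWarnings(stats::ks.test(
      x, function(q) linearLoadingCdf(q, b@koff, b@deltaX, b@kBT, r)))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("plateau curves follow their piecewise definition", {
  pc <- simulatePlateauCurve(40, 60, 5, noiseSigma = 0, seed = 1)
  f_at <- function(curve, x0) {
    force(curve)[which.min(abs(extension(curve) - x0))]
  }
  expect_equal(f_at(pc, 1), 40, tolerance = 1e-2)
  expect_equal(f_at(pc, 3), 60, tolerance = 1e-12)
  expect_equal(plateauForce(pc, c(2, 6)), 60, tolerance = 1e-12)
  expect_equal(plateauForce(pc, c(2, 4)), 60, tolerance = 1e-12)
  # with noise, the window mean stays within 3 standard errors
  pcn <- simulatePlateauCurve(40, 60, 5, noiseSigma = 5, seed = 8,
                              nPoints = 4000L)
  inWin <- extension(pcn) > 2 & extension(pcn) < 6
  se <- 5 / sqrt(sum(inWin))
  expect_lt(abs(plateauForce(pcn, c(2, 6)) - 60), 3 * se)
})
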