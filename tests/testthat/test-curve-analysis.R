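test_that("baseline correction removes offsets and tilts and is idempotent", {
  set.seed(30)
  x <- seq(0, 100, length.out = 1500)
  f <- c(50 * seq(0, 1, length.out = 500), numeric(1000)) + 7 +
    rnorm(1500, 0, 1)
  cv <- ForceCurve(x, f, retractSpeed = 400)
  cc <- correctBaseline(cv)
  expect_true(cc@baselineCorrected)
  expect_lt(abs(median(force(cc)[1300:1500])), 0.2)
  cc2 <- correctBaseline(cc)
  expect_equal(force(cc2), force(cc), tolerance = 1e-12)
  # linear mode removes a baseline tilt: on the fitting window the
  # residual slope vanishes by least squares, and the wider tail slope
  # stays below 0.01 pN/nm at modest noise
  set.seed(35)
  ft <- c(50 * seq(0, 1, length.out = 500), numeric(1000)) +
    0.05 * x + rnorm(1500, 0, 0.2)
  ct <- correctBaseline(ForceCurve(x, ft, retractSpeed = 400),
                        mode = "linear")
  trail <- 1351:1500
  expect_lt(abs(coef(lm(force(ct)[trail] ~ x[trail]))[2]), 1e-10)
  tailIdx <- 1200:1500
  expect_lt(abs(coef(lm(force(ct)[tailIdx] ~ x[tailIdx]))[2]), 0.01)
  expect_error(correctBaseline(ForceCurve(1:20, rnorm(20), 400)),
               "too short")
})

test_that("noise estimation recovers the injected sd from the trailing baseline", {
  sims <- getNoisyEnsemble()$results
  expect_equal(median(sims$noise_sigma_est), 4, tolerance = 0.15)
})

test_that("rupture detection finds clean steps and ignores pure noise", {
  cv <- rampStepCurve(peak = 50, noise = 1)
  ev <- detectRupture(correctBaseline(cv))
  expect_s4_class(ev, "RuptureEvent")
  expect_equal(ev@force, 50, tolerance = 2.5 / 50)
  expect_identical(ev@status, "ok")
  # pure noise, sd 4 -> no event
  set.seed(31)
  noise <- ForceCurve(seq(0, 120, length.out = 2000), rnorm(2000, 0, 4),
                      retractSpeed = 400)
  expect_null(detectRupture(correctBaseline(noise)))
})

test_that("two comparable well-separated drops flag the curve ambiguous", {
  x <- seq(0, 120, length.out = 2400)
  f <- numeric(2400)
  f[x <= 40] <- 45 * x[x <= 40] / 40              # ramp to 45, drop
  f[x > 40 & x <= 60] <- 0
  ramp2 <- x > 60 & x <= 100
  f[ramp2] <- 48 * (x[ramp2] - 60) / 40           # second ramp, drop
  set.seed(32)
  cv <- ForceCurve(x, f + rnorm(2400, 0, 1), retractSpeed = 400)
  ev <- detectRupture(correctBaseline(cv), noiseSigmaEst = 1)
  expect_s4_class(ev, "RuptureEvent")
  expect_identical(ev@status, "ambiguous")
})

test_that("detected rupture forces track the simulation ground truth", {
  fix <- getNoisyEnsemble()
  res <- fix$results
  det <- res[res$detected & res$status == "ok", ]
  err <- abs(det$rupture_force - det$true_force)
  expect_gte(mean(err <= pmax(2, 2 * det$noise_sigma_est)), 0.95)
  # noiseless end-to-end: detected force within one sampling step's
  # force increment of the truth
  g0 <- PullingGeometry(retractSpeed = 400, noiseSigma = 0)
  for (seed in c(51, 52, 53)) {
    s <- simulateCurve(g0, WLCModel(), ccConstruct("A4B4"), seed = seed)
    ev <- detectRupture(correctBaseline(s$curve), noiseSigmaEst = 0.05)
    step <- s$truth@loadingRate / 400 *
      diff(extension(s$curve)[1:2])  # dF over one sample
    expect_lt(abs(ev@force - s$truth@force), 2 * step + 1e-6)
  }
})

test_that("WLC fitting recovers generating parameters", {
  # noiseless pure WLC: 1% recovery, near-perfect goodness
  m <- WLCModel(p = 0.38, L = 160)
  x <- seq(0, 140, length.out = 2000)
  cv <- ForceCurve(x, wlcForce(x, m), retractSpeed = 400,
                   baselineCorrected = TRUE)
  ev <- new("RuptureEvent", force = wlcForce(140, m), extension = 140,
            retractSpeed = 400)
  fit <- fitWLC(cv, ev)
  expect_true(fit@valid)
  expect_equal(fit@p, 0.38, tolerance = 0.01)
  expect_equal(fit@L, 160, tolerance = 0.01)
  expect_gt(fit@r2, 0.999)
  # noisy circuit curves: median contour length within 5% (the fitted L
  # absorbs the small cantilever-compliance inflation)
  res <- getNoisyEnsemble()$results
  acc <- res[res$accepted, ]
  expect_gt(nrow(acc), 100)
  expect_lt(median(abs(acc$wlc_L - 160) / 160), 0.05)
  # a random walk is not WLC-shaped: rejected by the goodness filter
  set.seed(33)
  rw <- cumsum(rnorm(2000, 0.02, 0.8))
  rw <- rw - min(rw) + 1
  cvrw <- ForceCurve(seq(0, 140, length.out = 2000), rw,
                     retractSpeed = 400, baselineCorrected = TRUE)
  evrw <- new("RuptureEvent", force = max(rw) * 0.9, extension = 139,
              retractSpeed = 400)
  fitrw <- fitWLC(cvrw, evrw)
  expect_lt(fitrw@r2, 0.95)
})

test_that("slope at rupture and loading rate obey the stated contracts", {
  # exactly linear final segment of slope 1.7 at v = 400 -> 680 pN/s
  x <- seq(0, 100, length.out = 1200)
  cv <- ForceCurve(x, 1.7 * x, retractSpeed = 400,
                   baselineCorrected = TRUE)
  ev <- new("RuptureEvent", force = 170, extension = 100,
            retractSpeed = 400)
  ev <- loadingRateOfEvent(cv, ev)
  expect_equal(ev@slope, 1.7, tolerance = 1e-9)
  expect_equal(ev@loadingRate, 680, tolerance = 1e-9)
  # doubling v with an identical trace doubles the rate exactly
  cv2 <- ForceCurve(x, 1.7 * x, retractSpeed = 800,
                    baselineCorrected = TRUE)
  ev2 <- loadingRateOfEvent(cv2, initialize(ev, retractSpeed = 800))
  expect_equal(ev2@loadingRate, 2 * ev@loadingRate, tolerance = 1e-12)
  # force rescaling by c rescales slope and rate by c
  c0 <- 2.5
  cvs <- ForceCurve(x, c0 * 1.7 * x, retractSpeed = 400,
                    baselineCorrected = TRUE)
  evs <- loadingRateOfEvent(cvs, initialize(ev, force = c0 * 170))
  expect_equal(evs@slope, c0 * 1.7, tolerance = 1e-9)
  expect_equal(evs@loadingRate, c0 * 680, tolerance = 1e-9)
  expect_error(loadingRateOfEvent(cv, ev, window = 0.1), ">= 10 points")
})

test_that("estimated loading rates track the truth up to the known chord bias", {
  # The 5 nm OLS window reads the chord slope of a convex curve, ~10-15%
  # below the instantaneous stiffness at rupture; 4 pN noise adds ~20%
  # random slope error. The bias is a near-uniform log-shift across
  # speeds, so it cancels from the Bell-Evans slope.
  res <- getNoisyEnsemble()$results
  acc <- res[res$accepted, ]
  ratio <- acc$loading_rate / acc$true_loading_rate
  expect_gt(median(ratio), 0.75)
  expect_lt(median(ratio), 1.0)
  expect_lt(median(abs(ratio - 1)), 0.25)
})

test_that("the acceptance filter applies the stated rules and partitions its input", {
  mk <- function(L, r2) data.frame(
    curve_id = "c", replicate_id = "r", retract_speed = 400,
    noise_sigma_est = 4, detected = TRUE, status = "ok",
    rupture_force = 40, rupture_extension = 120, slope = 1.6,
    loading_rate = 640, wlc_valid = TRUE, wlc_p = 0.38, wlc_L = L,
    wlc_r2 = r2, stringsAsFactors = FALSE)
  df <- rbind(mk(90, 1), mk(120, 1), mk(150, 1))
  out <- filterEvents(df)
  expect_identical(sum(out$accepted), 2L)
  expect_match(out$reason[1], "contour length")
  # all-poor fits -> none accepted
  expect_identical(sum(filterEvents(rbind(mk(120, 0.5),
                                          mk(150, 0.5)))$accepted), 0L)
  # idempotence and exact partition
  out2 <- filterEvents(out)
  expect_identical(out2$accepted, out$accepted)
  expect_identical(out2$reason, out$reason)
  expect_true(all(xor(out$accepted, out$reason != "accepted")))
  expect_identical(filterEvents(df[0, ])$accepted, logical(0))
  # bookkeeping against a simulated ensemble with blanks
  res <- getT1Results()
  expect_identical(sum(res$accepted),
                   sum(res$detected & res$status == "ok" & res$wlc_valid &
                         res$wlc_L > 100 & res$wlc_r2 >= 0.95))
  # blanks never carry an event
  blanks <- !res$true_ruptured
  expect_true(all(!res$detected[blanks]))
})
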