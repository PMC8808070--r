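test_that("alpha = F/RT evaluates correctly and scales as 1/T", {
  expect_equal(alphaFactor(298.15), 38.92174, tolerance = 1e-6)
  expect_equal(alphaFactor(2 * 298.15), alphaFactor(298.15) / 2)
  expect_error(alphaFactor(0), "temperature")
  expect_error(alphaFactor(-10), "temperature")
})

test_that("semiquinone fraction matches closed-form values and limits", {
  ## coincident couples: both exponentials are 1
  expect_equal(semiquinoneFraction(-100, -100, -100), 1 / 3)
  expect_equal(semiquinoneFraction(0, 0, 0), 1 / 3)
  ## direct evaluation at the pH 6 midpoint
  expect_equal(semiquinoneFraction(-66, -42, -90), 0.5599538,
               tolerance = 1e-6)
  ## oxidized and reduced limits
  expect_lt(semiquinoneFraction(500, -42, -90), 1e-8)
  expect_lt(semiquinoneFraction(-600, -42, -90), 1e-8)
})

test_that("bell curve is symmetric about Em and peaks at the maximal fraction", {
  e1 <- -136; e2 <- -175
  em <- midpointEm(e1, e2)
  delta <- seq(0.5, 150, length.out = 40)
  expect_equal(semiquinoneFraction(em + delta, e1, e2),
               semiquinoneFraction(em - delta, e1, e2),
               tolerance = 1e-12)
  ## peak value identity, and no grid point exceeds it
  fmax <- maxSemiquinoneFraction(e1, e2)
  expect_equal(semiquinoneFraction(em, e1, e2), fmax, tolerance = 1e-12)
  grid <- seq(-400, 100, by = 0.1)
  expect_true(all(semiquinoneFraction(grid, e1, e2) <= fmax + 1e-12))
  expect_equal(grid[which.max(semiquinoneFraction(grid, e1, e2))], em,
               tolerance = 0.1)
})

test_that("midpoint potential is the mean and respects reporting convention", {
  expect_identical(midpointEm(-42, -90), -66)
  expect_equal(midpointEm(-136, -175), -155.5)
  expect_identical(roundHalfAway(midpointEm(-136, -175)), -156)
  expect_identical(midpointEm(-70, -70), -70)
  expect_identical(midpointEm(-42, -90), midpointEm(-90, -42))
})

test_that("stability constant follows the comproportionation relation", {
  expect_equal(stabilityConstant(-100, -100), 1)
  expect_equal(stabilityConstant(-136, -175), 4.562853, tolerance = 1e-6)
  expect_equal(stabilityConstant(-42, -90), 6.476911, tolerance = 1e-6)
  ## antisymmetry of the exponent
  for (gap in c(10, 39, 48, 200))
    expect_equal(stabilityConstant(0, -gap) * stabilityConstant(-gap, 0),
                 1, tolerance = 1e-12)
  ## larger gap at lower temperature: stronger stabilization
  expect_gt(stabilityConstant(-136, -175, 273.15),
            stabilityConstant(-136, -175, 298.15))
})

test_that("maximal semiquinone fraction matches direct evaluation", {
  expect_equal(maxSemiquinoneFraction(-70, -70), 1 / 3)
  expect_equal(maxSemiquinoneFraction(-42, -90), 0.5599538,
               tolerance = 1e-6)
  expect_equal(maxSemiquinoneFraction(-136, -175), 0.5164508,
               tolerance = 1e-6)
})

test_that("occupancy is the quantitation over the theoretical maximum", {
  expect_equal(occupancy(0, -42, -90), 0)
  expect_equal(occupancy(0.5, -42, -90), 0.8929308, tolerance = 1e-6)
  expect_equal(occupancy(0.5, -136, -175), 0.9681465, tolerance = 1e-6)
  mm <- maxSemiquinoneFraction(-42, -90)
  expect_equal(occupancy(mm, -42, -90), 1)
  expect_error(occupancy(-0.1, -42, -90), "nonnegative")
})

test_that("binding ratio from the midpoint shift is exponential and antisymmetric", {
  br0 <- bindingRatioFromShift(0)
  expect_equal(br0$ratio, 1)
  expect_equal(br0$foldTighterOxidized, 1)
  br <- bindingRatioFromShift(-56)
  expect_equal(br$ratio, 0.01278816, tolerance = 1e-6)
  expect_equal(br$foldTighterOxidized, 78.19732, tolerance = 1e-6)
  expect_equal(bindingRatioFromShift(56)$ratio,
               1 / bindingRatioFromShift(-56)$ratio, tolerance = 1e-12)
})

test_that("Em-vs-pH slope reproduces the two-point slope and handles degeneracy", {
  expect_equal(phSlope(c(6, 7.5), c(-66, -155.5)), -59.66667,
               tolerance = 1e-5)
  expect_identical(round(phSlope(c(6, 7.5), c(-66, -155.5))), -60)
  expect_equal(phSlope(c(6, 7), c(-50, -50)), 0)
  ## three collinear points give the two-point slope
  expect_equal(phSlope(c(6, 7, 8), c(-60, -120, -180)), -60)
  expect_error(phSlope(c(7, 7), c(-60, -80)), "distinct")
})

test_that("titration fit recovers noiseless parameters essentially exactly", {
  E <- seq(-300, 50, length.out = 30)
  A <- 0.8 * semiquinoneFraction(E, -136, -175)
  tc <- titrationCurve(E, A, pH = 7.5)
  fit <- fitTitration(tc)
  expect_true(fit@converged)
  expect_lt(fit@rss, 1e-12)
  expect_equal(fit@e1, -136, tolerance = 1e-4)
  expect_equal(fit@e2, -175, tolerance = 1e-4)
  expect_equal(fit@scale, 0.8, tolerance = 1e-6)
  expect_gte(fit@e1, fit@e2)
})

test_that("titration fit recovers seeded noisy truth within a few mV", {
  tc <- genTitration(e1 = -136, e2 = -175, scale = 1, nPoints = 30,
                     noiseSd = 0.02, seed = 1)
  fit <- fitTitration(tc)
  expect_true(fit@converged)
  ## the fit standard error under these conditions is ~3 mV; allow 3 SE
  expect_lt(abs(fit@e1 - (-136)), 9)
  expect_lt(abs(fit@e2 - (-175)), 9)
  ## standard errors are finite and of mV magnitude
  expect_true(is.finite(fit@e1Err) && fit@e1Err < 10)
})

test_that("titration fit is invariant to point order and initialization", {
  tc <- genTitration(e1 = -42, e2 = -90, ph = 6, nPoints = 30,
                     noiseSd = 0.02, seed = 11)
  fit <- fitTitration(tc)
  o <- sample(length(potentials(tc)))
  tc2 <- titrationCurve(potentials(tc)[o], amplitudes(tc)[o], pH = 6)
  fit2 <- fitTitration(tc2)
  expect_equal(fit2@e1, fit@e1, tolerance = 1e-6)
  expect_equal(fit2@e2, fit@e2, tolerance = 1e-6)
  fit3 <- fitTitration(tc, init = c(-20, -150, 2))
  expect_equal(fit3@e1, fit@e1, tolerance = 1e-6)
})

test_that("degenerate and undersized titrations are rejected", {
  expect_error(
    fitTitration(titrationCurve(seq(-200, 0, 50), rep(0.4, 5))),
    "degenerate")
  expect_error(
    fitTitration(titrationCurve(c(-100, -50, 0), c(0.1, 0.5, 0.1))),
    "at least 5")
  expect_error(titrationCurve(c(-10, -10), c(0.1, 0.2)), "unique")
})

test_that("derived quantities bundle is consistent with its parts", {
  tc <- genTitration(seed = 5)
  fit <- fitTitration(tc)
  d <- derivedRedox(fit, mskPerEnzyme = 0.5, emFree = -100)
  expect_equal(d$em, midpointEm(fit@e1, fit@e2))
  expect_equal(d$ks, stabilityConstant(fit@e1, fit@e2))
  expect_equal(d$rOcc, 0.5 / d$mskMax)
  expect_equal(d$emShift, d$em + 100)
  expect_equal(d$bindingRatio * d$foldTighterOxidized, 1)
})
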