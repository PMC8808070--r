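## spectra built from the analytic Gaussian-derivative helpers; field
## axes in mT around typical X-band values

test_that("polynomial baselines are removed from signal-free regions", {
  B <- seq(320, 350, length.out = 1500)
  sig <- gaussDerivLine(B, 335, 1.2, area = 3)
  ## linear ramp
  sp <- eprSpectrum(B, sig + 0.02 * (B - 320) - 0.5, 9.4)
  corr <- baselineCorrect(sp, order = 1, exclude = list(c(330, 340)))
  resid <- intensities(corr) - sig
  expect_lt(sqrt(mean(resid^2)) / max(abs(sig)), 0.01)
  ## order 0 on an already-centered spectrum changes nothing
  sp0 <- eprSpectrum(B, sig, 9.4)
  corr0 <- baselineCorrect(sp0, order = 0, exclude = list(c(328, 342)))
  expect_lt(max(abs(intensities(corr0) - sig)), 1e-12)
  ## pure cubic baseline, no signal: output is ~0 everywhere
  cub <- eprSpectrum(B, 1e-4 * (B - 335)^3 + 0.2 * (B - 335), 9.4)
  cc <- baselineCorrect(cub, order = 3)
  expect_lt(max(abs(intensities(cc))), 1e-8 * max(abs(cub@intensity)))
  expect_error(baselineCorrect(sp, order = 1,
                               exclude = list(c(300, 360))),
               "fewer than 10")
})

test_that("peak-to-peak width of a Gaussian derivative is FWHM/sqrt(2 ln 2)", {
  B <- seq(330, 340, length.out = 4096)
  for (w in c(0.6, 0.88, 1.5)) {
    sp <- eprSpectrum(B, gaussDerivLine(B, 335, w), 9.4)
    pp <- peakToPeak(sp)
    expect_equal(unname(pp["width"]), w / sqrt(2 * log(2)),
                 tolerance = 5e-3)
  }
  sp <- eprSpectrum(B, gaussDerivLine(B, 335, 0.9), 9.4)
  sp2 <- eprSpectrum(B, 2 * intensities(sp), 9.4)
  expect_equal(unname(peakToPeak(sp2)["amplitude"]),
               2 * unname(peakToPeak(sp)["amplitude"]))
  expect_equal(unname(peakToPeak(sp2)["width"]),
               unname(peakToPeak(sp)["width"]))
  expect_error(peakToPeak(eprSpectrum(B, seq_along(B), 9.4)),
               "monotone")
})

test_that("simulated peak-to-peak linewidth matches the analytic relation", {
  ## isotropic H-strain line: simulate_powder and the Gaussian
  ## derivative relation must agree to < 2% at fine field sampling
  sys <- spinSystem(rep(2.004, 3), lwMode = "H_strain", lwWidths = 1.0)
  sp <- simulatePowder(sys, 9.48, nPoints = 2048)
  expect_equal(unname(peakToPeak(sp)["width"]), 1 / sqrt(2 * log(2)),
               tolerance = 0.02)
  ## the packaged semiquinone fixture is calibrated to the observed
  ## 0.88 mT X-band peak-to-peak width
  msk <- exampleSpinSystems()$msk
  spm <- simulatePowder(msk, 9.4812, nPoints = 4096)
  grid <- diff(fieldAxis(spm))[1]
  expect_lt(abs(unname(peakToPeak(spm)["width"]) - 0.88), 2 * grid)
})

test_that("double integration recovers analytic absorption areas", {
  B <- seq(325, 345, length.out = 4096)
  for (S in c(1, 4.7)) {
    sp <- eprSpectrum(B, gaussDerivLine(B, 335, 1.1, area = S), 9.4)
    expect_equal(doubleIntegral(sp), S, tolerance = 5e-3)
  }
  ## zero spectrum
  expect_equal(doubleIntegral(eprSpectrum(B, rep(0, length(B)), 9.4)), 0)
  ## linearity over disjoint lines
  y1 <- gaussDerivLine(B, 330, 0.8, area = 2)
  y2 <- gaussDerivLine(B, 341, 0.8, area = 3)
  di1 <- doubleIntegral(eprSpectrum(B, y1, 9.4), c(326, 334))
  di2 <- doubleIntegral(eprSpectrum(B, y2, 9.4), c(337, 345))
  diBoth <- doubleIntegral(eprSpectrum(B, y1 + y2, 9.4))
  expect_equal(diBoth, di1 + di2, tolerance = 5e-3)
  ## invariance to a linear baseline removed first
  ramp <- 0.01 * (B - 325)
  spr <- baselineCorrect(
    eprSpectrum(B, gaussDerivLine(B, 335, 1.1) + ramp, 9.4),
    order = 1, exclude = list(c(331, 339)))
  expect_equal(doubleIntegral(spr), 1, tolerance = 5e-3)
})

test_that("internal-standard quantitation returns the windowed DI ratio", {
  B <- seq(320, 360, length.out = 8192)
  ## composite mirroring the published procedure: radical-region signal
  ## with 4.7x the area of the FeS internal reference
  y <- gaussDerivLine(B, 333, 1.0, area = 4.7) +
    gaussDerivLine(B, 350, 1.0, area = 1)
  sp <- eprSpectrum(B, y, 9.4)
  q <- quantitateSpins(sp, sampleWindow = c(327, 339),
                       referenceWindow = c(344, 356),
                       referenceSpins = 1)
  expect_equal(q@spinsPerEnzyme, 4.7, tolerance = 0.02)
  ## equal areas give 1, proportionality in the reference spin count
  ye <- gaussDerivLine(B, 333, 1, area = 2) +
    gaussDerivLine(B, 350, 1, area = 1)
  spe <- eprSpectrum(B, ye, 9.4)
  expect_equal(quantitateSpins(spe, c(327, 339), c(344, 356),
                               1)@spinsPerEnzyme / 2, 1,
               tolerance = 0.02)
  expect_equal(quantitateSpins(spe, c(327, 339), c(344, 356),
                               2)@spinsPerEnzyme, 4, tolerance = 0.05)
  ## common gain cancels
  spg <- eprSpectrum(B, 7.3 * y, 9.4)
  expect_equal(quantitateSpins(spg, c(327, 339), c(344, 356),
                               1)@spinsPerEnzyme,
               q@spinsPerEnzyme, tolerance = 1e-9)
  expect_error(quantitateSpins(sp, c(327, 345), c(344, 356), 1),
               "disjoint")
})

test_that("Mn(II) marker calibration recovers injected field offsets", {
  pred <- markerPredictedPositions(9.4)
  expect_equal(length(pred), 6)
  expect_equal(mean(pred), 335.6349, tolerance = 1e-3)
  expect_equal(diff(pred), rep(8.710, 5), tolerance = 1e-9)
  ## exact positions: zero offset
  expect_equal(calibrateField(pred, 9.4)@offset, 0)
  ## uniform 0.30 mT discrepancy
  cal <- calibrateField(pred + 0.30, 9.4)
  expect_equal(cal@offset, 0.30, tolerance = 1e-9)
  expect_equal(cal@nLinesUsed, 6L)
  ## single matched line
  expect_equal(calibrateField(pred[3] - 0.12, 9.4)@offset, -0.12,
               tolerance = 1e-9)
  expect_error(calibrateField(c(pred, 400), 9.4), "6")
})

test_that("field calibration round-trips through a synthetic marker spectrum", {
  mn <- exampleSpinSystems()$mnMarker
  sp <- genSpectrum(mn, 9.4, noiseSd = 0, fieldOffset = 0.3,
                    nPoints = 4096)
  pos <- markerLinePositions(sp)
  expect_equal(length(pos), 6)
  cal <- calibrateField(pos, 9.4)
  grid <- diff(fieldAxis(sp))[1]
  expect_lt(abs(cal@offset - 0.3), grid)
  ## applying the calibration restores the true axis
  fixed <- applyFieldCalibration(sp, cal)
  posFixed <- markerLinePositions(fixed)
  expect_lt(max(abs(posFixed - markerPredictedPositions(9.4))),
            2 * grid)
})
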