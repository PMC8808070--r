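test_that("effective g interpolates the principal values", {
  g <- c(2.1, 2.1, 2.1)
  for (ang in list(c(0, 0), c(pi / 3, 1), c(1.2, 0.4)))
    expect_equal(effectiveG(g, ang[1], ang[2]), 2.1, tolerance = 1e-12)
  g <- c(2.05, 1.95, 1.90)
  expect_equal(effectiveG(g, 0, 0), g[3])
  expect_equal(effectiveG(g, pi / 2, 0), g[1])
  expect_equal(effectiveG(g, pi / 2, pi / 2), g[2])
  expect_equal(effectiveG(c(2, 2, 1), pi / 4, 0), sqrt(2.5),
               tolerance = 1e-12)
})

test_that("resonance field follows h nu = g muB B", {
  expect_equal(resonanceField(9.4, 2.0023), 335.4186, tolerance = 1e-4)
  expect_equal(resonanceField(9.47864, 1.9933), 339.7518,
               tolerance = 1e-4)
  expect_equal(resonanceField(18.8, 2.0023),
               2 * resonanceField(9.4, 2.0023), tolerance = 1e-12)
  expect_error(resonanceField(9.4, 0), "positive")
  ## field -> g inversion round-trips
  expect_equal(fieldToG(resonanceField(9.48, 1.993), 9.48), 1.993,
               tolerance = 1e-12)
})

test_that("hyperfine offsets give first-order multiplets", {
  ## isotropic 13 MHz proton at isotropic g = 1.9933: doublet split by
  ## 13 / (1.9933 x 13.9962) = 0.4660 mT at any orientation
  hf <- hyperfine(13, nuclearSpin = 0.5)
  off <- hyperfineOffsets(hf, rep(1.9933, 3), 0.7, 0.3)
  expect_equal(nrow(off), 2)
  expect_equal(diff(off$offset), 0.4659728, tolerance = 1e-5)
  expect_equal(off$weight, c(0.5, 0.5))
  ## zero coupling: single line at zero offset
  off0 <- hyperfineOffsets(hyperfine(0, 0.5), rep(2, 3), 0.2, 0.2)
  expect_equal(off0$offset, c(0, 0))
  ## I = 5/2: six equally spaced, equally weighted lines
  off6 <- hyperfineOffsets(hyperfine(-243.95, 2.5), rep(2.00101, 3),
                           1.0, 0.5)
  expect_equal(nrow(off6), 6)
  expect_equal(diff(off6$offset), rep(diff(off6$offset)[1], 5),
               tolerance = 1e-12)
  expect_equal(off6$weight, rep(1 / 6, 6))
  ## two equivalent protons: 1:2:1 triplet
  off3 <- hyperfineOffsets(hyperfine(13, 0.5, nEquiv = 2L),
                           rep(2, 3), 1, 1)
  expect_equal(off3$weight, c(0.25, 0.5, 0.25))
})

test_that("orientation grid weights are normalized and spacing controls size", {
  g2 <- powderGrid(2)
  expect_equal(sum(g2$weight), 1, tolerance = 1e-12)
  expect_gt(nrow(powderGrid(1)), nrow(g2))
  expect_true(all(g2$theta > 0 & g2$theta < pi / 2 + 1e-9))
  expect_error(powderGrid(0), "spacingDeg")
})

test_that("isotropic system reproduces the analytic Gaussian line", {
  sys <- spinSystem(rep(2.0023, 3), lwMode = "H_strain", lwWidths = 0.8)
  sp <- simulatePowder(sys, 9.4, fieldRange = c(330, 341),
                       nPoints = 2048, harmonic = 0)
  yRef <- gaussAbsLine(fieldAxis(sp), resonanceField(9.4, 2.0023), 0.8)
  expect_lt(max(abs(intensities(sp) - yRef)) / max(yRef), 1e-6)
})

test_that("absorption spectra integrate to the system weight", {
  sys <- exampleSpinSystems()
  for (s in list(sys$moV, sys$msk)) {
    sp <- simulatePowder(s, 9.47864, nPoints = 2048, harmonic = 0)
    area <- pracma::trapz(fieldAxis(sp), intensities(sp))
    expect_equal(area, s@weight, tolerance = 5e-3)
  }
  s2 <- spinSystem(c(2.01, 2.00, 1.99), lwWidths = 0.5, weight = 2.5)
  sp <- simulatePowder(s2, 9.4, nPoints = 2048, harmonic = 0)
  expect_equal(pracma::trapz(fieldAxis(sp), intensities(sp)), 2.5,
               tolerance = 5e-3)
})

test_that("first derivative equals numerical differentiation of absorption", {
  sys <- exampleSpinSystems()$moV
  fr <- c(336, 344)
  sp0 <- simulatePowder(sys, 9.47864, fieldRange = fr, nPoints = 4096,
                        harmonic = 0)
  sp1 <- simulatePowder(sys, 9.47864, fieldRange = fr, nPoints = 4096,
                        harmonic = 1)
  B <- fieldAxis(sp0)
  num <- diff(intensities(sp0)) / diff(B)
  mid <- (intensities(sp1)[-1] + intensities(sp1)[-4096]) / 2
  expect_lt(max(abs(num - mid)) / max(abs(mid)), 5e-3)
})

test_that("spectrum is invariant under joint permutation of principal axes", {
  perm <- c(3, 1, 2)
  a <- spinSystem(c(2.03, 2.00, 1.97),
                  hyperfine(c(15, 10, 5), 0.5),
                  lwMode = "H_strain", lwWidths = c(0.4, 0.5, 0.6))
  b <- spinSystem(a@g[perm], hyperfine(a@hyperfine[[1]]@A[perm], 0.5),
                  lwMode = "H_strain", lwWidths = a@lwWidths[perm])
  fr <- c(330, 346)
  spA <- simulatePowder(a, 9.5, fieldRange = fr, nPoints = 1024)
  spB <- simulatePowder(b, 9.5, fieldRange = fr, nPoints = 1024)
  expect_lt(max(abs(intensities(spA) - intensities(spB))) /
              max(abs(intensities(spA))), 0.02)
})

test_that("g-strain linewidth scales with frequency while H-strain does not", {
  gv <- c(2.005, 2.005, 2.005)
  widths <- sapply(c(9.4, 34, 94), function(nu) {
    gs <- simulatePowder(spinSystem(gv, lwMode = "g_strain",
                                    lwWidths = 0.002),
                         nu, nPoints = 4096)
    hs <- simulatePowder(spinSystem(gv, lwMode = "H_strain",
                                    lwWidths = 0.7),
                         nu, nPoints = 4096)
    c(g = unname(peakToPeak(gs)["width"]),
      h = unname(peakToPeak(hs)["width"]))
  })
  ## g-strain: proportional to frequency
  expect_equal(unname(widths["g", 2] / widths["g", 1]), 34 / 9.4,
               tolerance = 0.02)
  expect_equal(unname(widths["g", 3] / widths["g", 1]), 94 / 9.4,
               tolerance = 0.02)
  ## H-strain: flat across bands
  expect_equal(unname(widths["h", 2] / widths["h", 1]), 1,
               tolerance = 0.02)
  expect_equal(unname(widths["h", 3] / widths["h", 1]), 1,
               tolerance = 0.02)
})

test_that("production grid agrees with the naive brute-force oracle", {
  ## light version of the multifrequency check: X band, both species
  sys <- exampleSpinSystems()
  for (s in list(sys$moV, sys$msk)) {
    sp <- simulatePowder(s, 9.47864, nPoints = 1024)
    yb <- bruteForcePowder(s, 9.47864, fieldAxis(sp))
    expect_lt(max(abs(intensities(sp) - yb)) /
                max(abs(intensities(sp))), 0.01)
  }
})

test_that("apparent g features read back the input tensor", {
  sys <- exampleSpinSystems()
  ## axial FeS cluster: outer features at g-perp and g-par
  ag <- apparentG(simulatePowder(sys$fe2s2, 9.48, nPoints = 2048))
  expect_lt(abs(ag["gLowField"] - 2.020), 0.002)
  expect_lt(abs(ag["gHighField"] - 1.939), 0.002)
  ## isotropic line: all features within half a linewidth of g
  iso <- simulatePowder(spinSystem(rep(2.005, 3), lwWidths = 0.6), 9.4,
                        nPoints = 2048)
  agi <- apparentG(iso)
  halfWidthG <- 2.005 - fieldToG(resonanceField(9.4, 2.005) + 0.3, 9.4)
  expect_true(all(abs(agi - 2.005) <= halfWidthG + 1e-6))
  ## semiquinone g3 is resolved at W band (not at X band)
  agw <- apparentG(simulatePowder(sys$msk, 94.244, nPoints = 4096))
  expect_lt(abs(agw["gHighField"] - 2.0023), 5e-4)
  agx <- apparentG(simulatePowder(sys$msk, 9.4812, nPoints = 4096))
  expect_gt(abs(agx["gHighField"] - 2.0023), 5e-4)
})

test_that("degenerate spectra and bad windows are handled", {
  flat <- eprSpectrum(1:100, rep(0, 100), 9.4)
  expect_error(apparentG(flat), "flat")
  sys <- spinSystem(rep(2.0, 3), lwWidths = 0.5)
  expect_warning(simulatePowder(sys, 9.4, fieldRange = c(200, 250)),
                 "window")
  abs0 <- simulatePowder(sys, 9.4, harmonic = 0)
  expect_error(apparentG(abs0), "harmonic")
})
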