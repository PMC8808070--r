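## Independent oracles used across the test suite. These deliberately
## re-derive the physics with naive loop code and closed forms so that
## the production implementations are checked against something they do
## not share code with.

## naive brute-force powder accumulation on a uniform theta x phi grid
## (default 3 degrees) with sin(theta) quadrature weights
bruteForcePowder <- function(sys, frequencyGHz, field, stepDeg = 3,
                             harmonic = 1) {
  h <- 6.62607015e-34
  muB <- 9.2740100783e-24
  y <- numeric(length(field))
  wtot <- 0
  th <- (seq(0, 90 - stepDeg, by = stepDeg) + stepDeg / 2) * pi / 180
  ph <- th
  for (t in th) for (p in ph) {
    l2 <- c((sin(t) * cos(p))^2, (sin(t) * sin(p))^2, cos(t)^2)
    geff <- sqrt(sum(sys@g^2 * l2))
    B0 <- h * frequencyGHz * 1e9 / (geff * muB) * 1000
    w <- sys@g^2 * l2 / geff^2
    fw <- if (sys@lwMode == "H_strain") {
      sqrt(sum(w * sys@lwWidths^2))
    } else {
      sqrt(sum(w * (sys@lwWidths * B0 / geff)^2))
    }
    sg <- fw / (2 * sqrt(2 * log(2)))
    off <- 0
    hw <- 1
    for (hf in sys@hyperfine) {
      aEff <- sqrt(sum(w * hf@A^2))
      mI <- seq(-hf@nuclearSpin * hf@nEquiv, hf@nuclearSpin * hf@nEquiv,
                by = 1)
      mult <- rep(1, round(2 * hf@nuclearSpin + 1))
      mw <- 1
      for (k in seq_len(hf@nEquiv))
        mw <- stats::convolve(mw, rev(mult), type = "open")
      mw <- mw / sum(mw)
      off <- as.vector(outer(off, mI * aEff / (geff * 13.9962), "+"))
      hw <- as.vector(outer(hw, mw, "*"))
    }
    ow <- sin(t)
    wtot <- wtot + ow
    for (k in seq_along(off)) {
      x <- (field - B0 - off[k]) / sg
      kern <- exp(-0.5 * x^2) / (sg * sqrt(2 * pi))
      if (harmonic == 1) kern <- -x / sg * kern
      y <- y + ow * hw[k] * kern
    }
  }
  y / wtot * sys@weight
}

## analytic first derivative of a unit-area Gaussian absorption line
gaussDerivLine <- function(field, center, fwhm, area = 1) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  x <- (field - center) / s
  -area * x / s * exp(-0.5 * x^2) / (s * sqrt(2 * pi))
}

## analytic Gaussian absorption line of given area
gaussAbsLine <- function(field, center, fwhm, area = 1) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  area * exp(-0.5 * ((field - center) / s)^2) / (s * sqrt(2 * pi))
}
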