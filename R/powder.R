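## First-harmonic CW-EPR powder-pattern simulation for S = 1/2 species
## with rhombic g-tensors, first-order hyperfine structure, and
## H-strain / g-strain Gaussian linewidth models.

#' Effective g-value at one orientation
#'
#' For a spin-1/2 with principal g-values (g1, g2, g3) and the static
#' field along the direction with polar angles (theta, phi) in the
#' g-tensor frame:
#' \deqn{g_{eff} = \sqrt{g_1^2 \sin^2\theta\cos^2\phi +
#'   g_2^2 \sin^2\theta\sin^2\phi + g_3^2 \cos^2\theta}}
#'
#' @param g numeric length 3, principal g-values.
#' @param theta,phi numeric, polar and azimuthal angles in radians
#'   (vectorized).
#' @return Effective g-value(s).
#' @examples
#' effectiveG(c(2, 2, 1), pi / 4, 0)  # sqrt(2.5)
#' @export
effectiveG <- function(g, theta, phi) {
  st <- sin(theta)
  sqrt(g[1]^2 * (st * cos(phi))^2 + g[2]^2 * (st * sin(phi))^2 +
       g[3]^2 * cos(theta)^2)
}

#' Resonance field for a given effective g
#'
#' Resonance condition h nu = g muB B, solved for B.
#'
#' @param frequencyGHz microwave frequency, GHz.
#' @param gEff effective g-value (> 0).
#' @return Resonance field in mT.
#' @examples
#' resonanceField(9.4, 2.0023)  # 335.4 mT
#' @export
resonanceField <- function(frequencyGHz, gEff) {
  if (any(gEff <= 0)) stop("gEff must be positive")
  .H_CONST * frequencyGHz * 1e9 / (gEff * .MUB_CONST) * 1000
}

#' Convert field positions to apparent g-values
#'
#' @param field field position(s), mT.
#' @param frequencyGHz microwave frequency, GHz.
#' @return Apparent g-value(s), g = h nu / (muB B).
#' @export
fieldToG <- function(field, frequencyGHz) {
  .H_CONST * frequencyGHz * 1e9 / (.MUB_CONST * field * 1e-3)
}

## direction-cosine weights w_i = g_i^2 l_i^2 / g_eff^2 (sum to 1)
.dirWeights <- function(g, theta, phi) {
  l2 <- c((sin(theta) * cos(phi))^2, (sin(theta) * sin(phi))^2,
          cos(theta)^2)
  w <- g^2 * l2
  w / sum(w)
}

## multinomial projection weights for n equivalent nuclei of spin I:
## total projections M = -nI ... +nI in unit steps, weights from
## n-fold convolution of the single-nucleus uniform multiplet
.equivalentWeights <- function(nuclearSpin, nEquiv) {
  single <- rep(1, round(2 * nuclearSpin + 1))
  w <- 1
  for (k in seq_len(nEquiv)) w <- stats::convolve(w, rev(single),
                                                  type = "open")
  w / sum(w)
}

#' First-order hyperfine line offsets at one orientation
#'
#' Projects the hyperfine tensor onto the field direction using the
#' same direction-cosine weights as the effective g-value
#' (\eqn{A_{eff}^2 = \sum_i w_i A_i^2}, \eqn{w_i = g_i^2 l_i^2 /
#' g_{eff}^2}) and returns the first-order line offsets
#' \eqn{\Delta B = M \, A_{eff} / (g_{eff} \cdot \mu_B/h)} for every
#' total nuclear projection M, with multiplicity weights for
#' equivalent nuclei (weights sum to 1).
#'
#' @param h a \linkS4class{Hyperfine}.
#' @param g numeric length 3 principal g-values of the host system.
#' @param theta,phi orientation angles, radians.
#' @return A data.frame with columns \code{offset} (mT) and
#'   \code{weight}.
#' @examples
#' ## isotropic 13 MHz proton doublet at g = 1.9933:
#' hyperfineOffsets(hyperfine(13, 1/2), rep(1.9933, 3), pi / 3, 1)
#' @export
hyperfineOffsets <- function(h, g, theta, phi) {
  stopifnot(is(h, "Hyperfine"))
  gEff <- effectiveG(g, theta, phi)
  w <- .dirWeights(g, theta, phi)
  aEff <- sqrt(sum(w * h@A^2))                    # MHz
  mT <- aEff / (gEff * .MHZ_PER_MT)               # field per unit M
  M <- seq(-h@nEquiv * h@nuclearSpin, h@nEquiv * h@nuclearSpin, by = 1)
  data.frame(offset = M * mT,
             weight = .equivalentWeights(h@nuclearSpin, h@nEquiv))
}

## combined offsets/weights over all hyperfine tensors of a system at
## one orientation (outer sum of offsets, product of weights)
.allOffsets <- function(system, theta, phi) {
  off <- 0; wt <- 1
  for (h in system@hyperfine) {
    hf <- hyperfineOffsets(h, system@g, theta, phi)
    off <- as.vector(outer(off, hf$offset, "+"))
    wt  <- as.vector(outer(wt, hf$weight, "*"))
  }
  list(offset = off, weight = wt)
}

#' Deterministic equal-area orientation grid over one octant
#'
#' Uniformly spaced polar rings carrying their exact annulus area as
#' weight; each ring is split into azimuthal cells in proportion to
#' sin(theta), so every cell subtends approximately the same solid
#' angle. One octant suffices for tensors with collinear principal
#' axes.
#'
#' @param spacingDeg approximate angular spacing in degrees
#'   (default 2).
#' @return A data.frame with columns \code{theta}, \code{phi},
#'   \code{weight} (weights sum to 1).
#' @export
powderGrid <- function(spacingDeg = 2) {
  if (spacingDeg <= 0 || spacingDeg > 45)
    stop("spacingDeg must be in (0, 45]")
  nRings <- ceiling(90 / spacingDeg)
  dth <- (pi / 2) / nRings
  theta <- (seq_len(nRings) - 0.5) * dth
  ## ring weight = exact annulus area; phi cells proportional to
  ## sin(theta), so cells subtend approximately equal solid angles
  ringW <- cos(theta - dth / 2) - cos(theta + dth / 2)
  out <- vector("list", nRings)
  for (i in seq_len(nRings)) {
    m <- max(1L, ceiling(90 * sin(theta[i]) / spacingDeg))
    out[[i]] <- data.frame(
      theta = theta[i],
      phi = (seq_len(m) - 0.5) / m * (pi / 2),
      weight = ringW[i] / m)
  }
  grid <- do.call(rbind, out)
  grid$weight <- grid$weight / sum(grid$weight)
  grid
}

## per-orientation Gaussian FWHM (mT): principal widths combined in
## quadrature with direction-cosine weights; g-strain widths are
## delta-g FWHMs converted to field via |dB/dg| = B/g at that
## orientation (hence proportional to frequency)
.orientationFwhm <- function(system, w, gEff, B0) {
  if (system@lwMode == "H_strain") {
    sqrt(sum(w * system@lwWidths^2))
  } else {
    sqrt(sum(w * (system@lwWidths * B0 / gEff)^2))
  }
}

#' Simulate a first-harmonic CW-EPR powder spectrum
#'
#' Accumulates Gaussian lines over a deterministic equal-area
#' orientation grid (one octant). For each orientation the resonance
#' field follows from the effective g-value, first-order hyperfine
#' offsets are added, and the Gaussian FWHM interpolates the three
#' principal widths in quadrature with direction-cosine weights
#' (strains treated as uncorrelated). In g-strain mode the principal
#' widths are delta-g distributions converted to field widths via
#' |dB/dg| = B/g, so the linewidth scales with frequency; in H-strain
#' mode widths are field-independent. Harmonic 1 returns the analytic
#' first derivative of the Gaussian kernel (modulation amplitude is
#' not modelled); in absorption mode (harmonic 0) the spectrum
#' integrates to the summed system weights.
#'
#' @param systems a \linkS4class{SpinSystem} or list of them.
#' @param frequencyGHz microwave frequency, GHz.
#' @param fieldRange numeric length 2, mT; when NULL an automatic
#'   window covering all resonances plus 5 FWHM is used.
#' @param nPoints number of field points (>= 64, default 1024).
#' @param harmonic 0 (absorption) or 1 (first derivative, default).
#' @param gridSpacing orientation grid spacing in degrees (default 2).
#' @param label label for the returned spectrum.
#' @return An \linkS4class{EPRSpectrum}. A warning is emitted when the
#'   requested window does not cover all resonance positions.
#' @examples
#' mo <- spinSystem(c(1.9971, 1.9933, 1.9890),
#'                  hyperfine(c(13, 13, 11), 1/2), lwWidths = 0.25)
#' sp <- simulatePowder(mo, 9.47864)
#' @export
simulatePowder <- function(systems, frequencyGHz, fieldRange = NULL,
                           nPoints = 1024, harmonic = 1L,
                           gridSpacing = 2, label = "") {
  if (is(systems, "SpinSystem")) systems <- list(systems)
  if (!length(systems)) stop("at least one spin system is required")
  if (nPoints < 64) stop("nPoints must be >= 64")
  harmonic <- as.integer(harmonic)
  grid <- powderGrid(gridSpacing)
  if (!nrow(grid)) stop("empty orientation grid")

  ## precompute per-system, per-orientation line lists
  lines <- list()
  for (sys in systems) {
    gEff <- effectiveG(sys@g, grid$theta, grid$phi)
    B0 <- resonanceField(frequencyGHz, gEff)
    for (k in seq_len(nrow(grid))) {
      w <- .dirWeights(sys@g, grid$theta[k], grid$phi[k])
      fw <- .orientationFwhm(sys, w, gEff[k], B0[k])
      hf <- .allOffsets(sys, grid$theta[k], grid$phi[k])
      lines[[length(lines) + 1L]] <- list(
        center = B0[k] + hf$offset,
        weight = sys@weight * grid$weight[k] * hf$weight,
        fwhm = fw)
    }
  }
  centers <- unlist(lapply(lines, `[[`, "center"))
  fwhms <- unlist(lapply(lines, function(l)
    rep(l$fwhm, length(l$center))))
  weights <- unlist(lapply(lines, `[[`, "weight"))
  sigmas <- pmax(fwhms / (2 * sqrt(2 * log(2))), 1e-6)

  if (is.null(fieldRange)) {
    fieldRange <- c(min(centers - 5 * fwhms), max(centers + 5 * fwhms))
  } else if (min(centers) < fieldRange[1] || max(centers) > fieldRange[2]) {
    warning("field window does not cover all resonance positions")
  }
  if (fieldRange[2] <= fieldRange[1])
    stop("field_stop must exceed field_start")
  B <- seq(fieldRange[1], fieldRange[2], length.out = nPoints)

  y <- numeric(nPoints)
  for (j in seq_along(centers)) {
    x <- (B - centers[j]) / sigmas[j]
    kern <- exp(-0.5 * x^2) / (sigmas[j] * sqrt(2 * pi))
    if (harmonic == 1L) kern <- -x / sigmas[j] * kern
    y <- y + weights[j] * kern
  }
  eprSpectrum(B, y, frequencyGHz, harmonic, label = label)
}

#' Apparent g-values from a first-derivative spectrum
#'
#' Reads the conventional features of a derivative powder spectrum:
#' the low-field derivative maximum (the first local maximum exceeding
#' 5% of the spectrum amplitude), the high-field derivative minimum
#' (the last local minimum below -5% of the amplitude), and the
#' steepest zero crossing between them (the central crossing of an
#' isotropic or rhombic pattern). Each position is converted to a
#' g-value via g = h nu / (muB B).
#'
#' @param spectrum an \linkS4class{EPRSpectrum} with harmonic 1.
#' @param threshold fraction of the peak-to-peak amplitude below which
#'   local extrema are ignored (default 0.05).
#' @return Named numeric vector \code{c(gLowField, gZeroCross,
#'   gHighField)}.
#' @export
apparentG <- function(spectrum, threshold = 0.05) {
  stopifnot(is(spectrum, "EPRSpectrum"))
  if (spectrum@harmonic != 1L)
    stop("apparentG requires a first-derivative spectrum (harmonic 1)")
  y <- spectrum@intensity
  B <- spectrum@field
  amp <- diff(range(y))
  if (amp <= .Machine$double.eps * max(1, max(abs(y))))
    stop("flat spectrum: no features to locate")
  thr <- threshold * amp
  n <- length(y)
  mid <- 2:(n - 1)
  locMax <- mid[y[mid] >= y[mid - 1] & y[mid] >= y[mid + 1] &
                  y[mid] > thr]
  locMin <- mid[y[mid] <= y[mid - 1] & y[mid] <= y[mid + 1] &
                  y[mid] < -thr]
  if (!length(locMax) || !length(locMin))
    stop("no derivative extrema above threshold")
  iMax <- locMax[1]
  iMin <- locMin[length(locMin)]
  if (iMax >= iMin) stop("derivative maximum must precede the minimum")
  ## steepest zero crossing between the outer features
  seg <- iMax:(iMin - 1)
  cross <- seg[y[seg] > 0 & y[seg + 1] <= 0]
  if (!length(cross)) stop("no zero crossing between the extrema")
  i0 <- cross[which.max(abs(y[cross + 1] - y[cross]))]
  bz <- B[i0] + (0 - y[i0]) * (B[i0 + 1] - B[i0]) / (y[i0 + 1] - y[i0])
  nu <- spectrum@frequencyGHz
  c(gLowField = fieldToG(B[iMax], nu),
    gZeroCross = fieldToG(bz, nu),
    gHighField = fieldToG(B[iMin], nu))
}
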