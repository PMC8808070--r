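## Spectrum post-processing: baseline correction, peak-to-peak metrics,
## double integration, internal-standard spin quantitation, Mn(II)
## marker field calibration.

.windowIdx <- function(field, window) {
  if (is.null(window)) return(seq_along(field))
  which(field >= window[1] & field <= window[2])
}

#' Polynomial baseline correction
#'
#' Fits a polynomial of given order to the signal-free regions of a
#' spectrum (all points outside the excluded windows) and subtracts it
#' over the full grid.
#'
#' @param spectrum an \linkS4class{EPRSpectrum}.
#' @param order polynomial order, 0 to 3.
#' @param exclude list of numeric length-2 field windows (mT) to leave
#'   out of the baseline fit (the signal regions). Empty by default.
#' @return A baseline-corrected \linkS4class{EPRSpectrum}.
#' @export
baselineCorrect <- function(spectrum, order = 1, exclude = list()) {
  stopifnot(is(spectrum, "EPRSpectrum"))
  if (order < 0 || order > 3) stop("order must be between 0 and 3")
  B <- spectrum@field
  keep <- rep(TRUE, length(B))
  for (w in exclude) keep[B >= w[1] & B <= w[2]] <- FALSE
  if (sum(keep) < 10)
    stop("excluded windows leave fewer than 10 points for baseline fitting")
  y <- spectrum@intensity
  base <- if (order == 0) {
    rep(mean(y[keep]), length(B))
  } else {
    fit <- stats::lm(y[keep] ~ stats::poly(B[keep], order, raw = TRUE))
    as.numeric(cbind(1, stats::poly(B, order, raw = TRUE)) %*%
                 stats::coef(fit))
  }
  eprSpectrum(B, y - base, spectrum@frequencyGHz, spectrum@harmonic,
              label = spectrum@label, truth = spectrum@truth)
}

#' Peak-to-peak amplitude and linewidth
#'
#' For a first-derivative line: amplitude is max minus min intensity,
#' width the field separation between the derivative extrema. For a
#' Gaussian line of FWHM w the peak-to-peak width is
#' w / sqrt(2 ln 2) = 0.8493 w.
#'
#' @param spectrum an \linkS4class{EPRSpectrum} with harmonic 1.
#' @param window optional numeric length-2 field window, mT.
#' @return Named numeric vector \code{c(amplitude, width)}.
#' @export
peakToPeak <- function(spectrum, window = NULL) {
  stopifnot(is(spectrum, "EPRSpectrum"))
  if (spectrum@harmonic != 1L)
    stop("peakToPeak requires a first-derivative spectrum (harmonic 1)")
  idx <- .windowIdx(spectrum@field, window)
  y <- spectrum@intensity[idx]
  B <- spectrum@field[idx]
  if (length(y) < 3 || all(diff(y) >= 0) || all(diff(y) <= 0))
    stop("monotone spectrum: no peak-to-peak feature")
  c(amplitude = max(y) - min(y),
    width = abs(B[which.min(y)] - B[which.max(y)]))
}

#' Double integration of a first-derivative spectrum
#'
#' Cumulative trapezoid integration applied twice over the field axis.
#' After the first integration the recovered absorption line is forced
#' to return to zero at the end of the (windowed) range by subtracting
#' a linear tilt, a standard guard against residual derivative-baseline
#' drift; the second integration then gives the double integral,
#' proportional to the spin count.
#'
#' @param spectrum an \linkS4class{EPRSpectrum} with harmonic 1,
#'   baseline corrected.
#' @param window optional numeric length-2 field window, mT.
#' @return Double integral in field-squared-weighted intensity units.
#' @export
doubleIntegral <- function(spectrum, window = NULL) {
  stopifnot(is(spectrum, "EPRSpectrum"))
  if (spectrum@harmonic != 1L)
    stop("doubleIntegral requires a first-derivative spectrum")
  idx <- .windowIdx(spectrum@field, window)
  if (length(idx) < 3) stop("window contains fewer than 3 points")
  B <- spectrum@field[idx]
  y <- spectrum@intensity[idx]
  absn <- pracma::cumtrapz(B, y)[, 1]
  ## tilt correction: force the absorption to end at zero
  absn <- absn - (B - B[1]) / (B[length(B)] - B[1]) * absn[length(absn)]
  pracma::trapz(B, absn)
}

#' Internal-standard spin quantitation
#'
#' Ratio of windowed double integrals scaled by the spin count
#' assigned to the reference center, assuming both windows were
#' acquired under identical, non-saturating conditions:
#' spins/enzyme = DI(sample) / DI(reference) x referenceSpins.
#' Windows must be disjoint and each isolate one species (overlapping
#' signals must be separated experimentally, e.g. by relaxation
#' filtering, before quantitation).
#'
#' @param spectrum an \linkS4class{EPRSpectrum} with harmonic 1.
#' @param sampleWindow,referenceWindow numeric length-2 field windows,
#'   mT, disjoint.
#' @param referenceSpins spins per enzyme assigned to the reference
#'   center (default 1).
#' @return A \linkS4class{QuantitationResult}.
#' @export
quantitateSpins <- function(spectrum, sampleWindow, referenceWindow,
                            referenceSpins = 1) {
  if (!(sampleWindow[2] < referenceWindow[1] ||
        referenceWindow[2] < sampleWindow[1]))
    stop("sample and reference windows must be disjoint")
  sdi <- doubleIntegral(spectrum, sampleWindow)
  rdi <- doubleIntegral(spectrum, referenceWindow)
  if (rdi <= 0) stop("reference double integral is not positive")
  new("QuantitationResult", sampleDI = sdi, referenceDI = rdi,
      referenceSpins = referenceSpins,
      spinsPerEnzyme = sdi / rdi * referenceSpins)
}

#' Predicted Mn(II) marker line positions
#'
#' First-order positions of the six-line Mn(II) hyperfine pattern:
#' B_m = h nu / (g muB) + m a for m = -5/2 ... +5/2, returned in
#' ascending field order.
#'
#' @param frequencyGHz microwave frequency, GHz.
#' @param markerG marker isotropic g-value (default 2.00101).
#' @param markerA marker isotropic hyperfine constant, mT (default
#'   -8.710).
#' @return Numeric vector of 6 field positions, mT.
#' @export
markerPredictedPositions <- function(frequencyGHz, markerG = 2.00101,
                                     markerA = -8.710) {
  center <- resonanceField(frequencyGHz, markerG)
  sort(center + seq(-2.5, 2.5, by = 1) * markerA)
}

#' Locate Mn(II) marker lines in a derivative spectrum
#'
#' Finds the zero crossing of each marker hyperfine line within a
#' half-spacing window around its predicted position. Lines whose
#' window falls outside the spectrum or contains no crossing are
#' dropped.
#'
#' @param spectrum an \linkS4class{EPRSpectrum} with harmonic 1.
#' @inheritParams markerPredictedPositions
#' @return Numeric vector of measured line positions (mT), ascending.
#' @export
markerLinePositions <- function(spectrum, markerG = 2.00101,
                                markerA = -8.710) {
  stopifnot(is(spectrum, "EPRSpectrum"), spectrum@harmonic == 1L)
  pred <- markerPredictedPositions(spectrum@frequencyGHz, markerG,
                                   markerA)
  half <- abs(markerA) / 2
  B <- spectrum@field
  y <- spectrum@intensity
  found <- numeric()
  for (p in pred) {
    idx <- which(B >= p - half & B <= p + half)
    if (length(idx) < 3) next
    iMax <- idx[which.max(y[idx])]
    iMin <- idx[which.min(y[idx])]
    if (iMax >= iMin) next
    seg <- iMax:iMin
    sc <- which(diff(sign(y[seg])) != 0)
    if (!length(sc)) next
    i0 <- seg[sc[1]]
    found <- c(found,
               B[i0] - y[i0] * (B[i0 + 1] - B[i0]) / (y[i0 + 1] - y[i0]))
  }
  sort(found)
}

#' Field calibration against the Mn(II) marker sextet
#'
#' Compares measured Mn(II) line positions with the first-order
#' predictions for the marker's g-value and isotropic hyperfine
#' constant; each measured line is matched to the nearest predicted
#' one, and the calibration offset is the mean discrepancy (measured
#' minus predicted). Line positions are computed to first order;
#' second-order shifts (~a^2/B, about 0.2 mT at X band) are not
#' applied.
#'
#' @param measured numeric vector of 1 to 6 measured line positions,
#'   mT, ascending.
#' @inheritParams markerPredictedPositions
#' @return A \linkS4class{FieldCalibration}; apply \code{-offset} to a
#'   field axis to correct it (see
#'   \code{\link{applyFieldCalibration}}).
#' @examples
#' pred <- markerPredictedPositions(9.4)
#' calibrateField(pred + 0.30, 9.4)  # offset 0.30 mT
#' @export
calibrateField <- function(measured, frequencyGHz, markerG = 2.00101,
                           markerA = -8.710) {
  if (!length(measured) || length(measured) > 6)
    stop("between 1 and 6 measured marker lines are required")
  if (is.unsorted(measured))
    stop("measured line positions must be ascending")
  pred <- markerPredictedPositions(frequencyGHz, markerG, markerA)
  matched <- vapply(measured, function(b) pred[which.min(abs(pred - b))],
                    numeric(1))
  new("FieldCalibration", offset = mean(measured - matched),
      markerG = markerG, markerA = markerA,
      nLinesUsed = length(measured))
}

#' Apply a field calibration to a spectrum
#'
#' Shifts the field axis by \code{-offset}, so that marker lines move
#' onto their predicted positions.
#'
#' @param spectrum an \linkS4class{EPRSpectrum}.
#' @param calibration a \linkS4class{FieldCalibration}.
#' @return The corrected \linkS4class{EPRSpectrum}.
#' @export
applyFieldCalibration <- function(spectrum, calibration) {
  stopifnot(is(spectrum, "EPRSpectrum"),
            is(calibration, "FieldCalibration"))
  eprSpectrum(spectrum@field - calibration@offset, spectrum@intensity,
              spectrum@frequencyGHz, spectrum@harmonic,
              label = spectrum@label, truth = spectrum@truth)
}
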