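#' @import methods
NULL

## ---------------------------------------------------------------------------
## TitrationCurve
## ---------------------------------------------------------------------------

#' TitrationCurve: an EPR-monitored potentiometric titration series
#'
#' Stores one redox titration of an EPR-active species: ambient redox
#' potential (mV vs SHE) against the normalized peak-to-peak amplitude of
#' the EPR signal, together with the pH and temperature at which the
#' titration was run. Potentials need not be sorted but must be unique.
#'
#' @slot potential numeric, ambient redox potentials in mV vs SHE.
#' @slot amplitude numeric, normalized signal amplitudes (>= 0).
#' @slot amplitudeErr numeric, optional per-point amplitude standard
#'   errors (length 0 when absent).
#' @slot pH numeric scalar.
#' @slot temperature numeric scalar, K.
#' @slot label character scalar.
#' @slot truth list, generating parameters when the curve is synthetic
#'   (empty for experimental data).
#' @aliases TitrationCurve
#' @exportClass TitrationCurve
setClass("TitrationCurve",
  slots = c(
    potential    = "numeric",
    amplitude    = "numeric",
    amplitudeErr = "numeric",
    pH           = "numeric",
    temperature  = "numeric",
    label        = "character",
    truth        = "list"
  ),
  prototype = prototype(pH = NA_real_, temperature = 298.15,
                        label = "", truth = list())
)

setValidity("TitrationCurve", function(object) {
  msg <- character()
  if (length(object@potential) != length(object@amplitude))
    msg <- c(msg, "potential and amplitude must have equal length")
  if (length(object@amplitudeErr) &&
      length(object@amplitudeErr) != length(object@potential))
    msg <- c(msg, "amplitudeErr must be empty or match potential length")
  if (any(!is.finite(object@potential)))
    msg <- c(msg, "potentials must be finite")
  if (anyDuplicated(object@potential))
    msg <- c(msg, "potentials must be unique")
  if (any(object@amplitude < 0, na.rm = TRUE))
    msg <- c(msg, "amplitudes must be nonnegative")
  if (length(object@temperature) != 1 || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (K)")
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationCurve
#'
#' @param potential numeric, potentials in mV vs SHE.
#' @param amplitude numeric, normalized amplitudes.
#' @param amplitudeErr optional numeric amplitude errors.
#' @param pH numeric scalar.
#' @param temperature numeric scalar in K (default 298.15, room
#'   temperature).
#' @param label character label.
#' @param truth optional list of generating parameters.
#' @return A \linkS4class{TitrationCurve}.
#' @examples
#' tc <- titrationCurve(seq(-300, 50, length.out = 8),
#'                      rep(0.1, 8), pH = 7.5)
#' tc
#' @export
titrationCurve <- function(potential, amplitude, amplitudeErr = numeric(),
                           pH = NA_real_, temperature = 298.15,
                           label = "", truth = list()) {
  new("TitrationCurve",
      potential = as.numeric(potential), amplitude = as.numeric(amplitude),
      amplitudeErr = as.numeric(amplitudeErr), pH = as.numeric(pH),
      temperature = as.numeric(temperature), label = label, truth = truth)
}

setMethod("show", "TitrationCurve", function(object) {
  cat("TitrationCurve", if (nzchar(object@label))
        paste0("'", object@label, "'") else "", "\n")
  cat("  ", length(object@potential), " points, E in [",
      round(min(object@potential)), ", ", round(max(object@potential)),
      "] mV vs SHE\n", sep = "")
  cat("  pH ", object@pH, ", T = ", object@temperature, " K\n", sep = "")
  if (length(object@truth))
    cat("  synthetic (truth recorded: ",
        paste(names(object@truth), collapse = ", "), ")\n", sep = "")
})

## ---------------------------------------------------------------------------
## TwoStepFit
## ---------------------------------------------------------------------------

#' TwoStepFit: fitted two-step one-electron Nernst model
#'
#' Result of fitting a bell-shaped semiquinone titration curve to the
#' two successive one-electron model. By convention \code{e1 >= e2}
#' (quinone/semiquinone couple at the higher potential).
#'
#' @slot e1 numeric, midpoint potential of the oxidized/semiquinone
#'   couple, mV vs SHE.
#' @slot e2 numeric, midpoint potential of the semiquinone/quinol
#'   couple, mV vs SHE.
#' @slot scale numeric, fitted amplitude scale (> 0).
#' @slot e1Err,e2Err,scaleErr numeric, standard errors from the fit
#'   covariance (NA when unavailable).
#' @slot rss numeric, residual sum of squares.
#' @slot converged logical.
#' @slot temperature numeric, K (carried from the curve).
#' @slot pH numeric (carried from the curve).
#' @slot label character.
#' @aliases TwoStepFit
#' @exportClass TwoStepFit
setClass("TwoStepFit",
  slots = c(e1 = "numeric", e2 = "numeric", scale = "numeric",
            e1Err = "numeric", e2Err = "numeric", scaleErr = "numeric",
            rss = "numeric", converged = "logical",
            temperature = "numeric", pH = "numeric", label = "character"),
  prototype = prototype(e1Err = NA_real_, e2Err = NA_real_,
                        scaleErr = NA_real_, rss = NA_real_,
                        converged = TRUE, temperature = 298.15,
                        pH = NA_real_, label = "")
)

setValidity("TwoStepFit", function(object) {
  msg <- character()
  if (object@e1 < object@e2)
    msg <- c(msg, "ordering convention violated: e1 must be >= e2")
  if (!is.na(object@scale) && object@scale <= 0)
    msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TwoStepFit", function(object) {
  cat("TwoStepFit (two successive one-electron steps)\n")
  cat(sprintf("  E1 = %s mV (+/- %s), E2 = %s mV (+/- %s)\n",
              format(roundHalfAway(object@e1)),
              format(signif(object@e1Err, 2)),
              format(roundHalfAway(object@e2)),
              format(signif(object@e2Err, 2))))
  cat(sprintf("  scale = %.4g, rss = %.3g, converged = %s\n",
              object@scale, object@rss, object@converged))
  cat(sprintf("  Em = %s mV at pH %s, T = %s K\n",
              format(roundHalfAway(midpointEm(object@e1, object@e2))),
              format(object@pH), format(object@temperature)))
})

## ---------------------------------------------------------------------------
## Spin systems
## ---------------------------------------------------------------------------

#' Hyperfine: one (set of equivalent) coupled nucleus/nuclei
#'
#' First-order hyperfine coupling with principal values collinear with
#' the g-tensor axes.
#'
#' @slot A numeric length 3, principal values in MHz.
#' @slot nuclearSpin numeric, half-integer nuclear spin (1/2, 1, 3/2,
#'   2 or 5/2).
#' @slot nEquiv integer, number of equivalent nuclei (>= 1).
#' @aliases Hyperfine
#' @exportClass Hyperfine
setClass("Hyperfine",
  slots = c(A = "numeric", nuclearSpin = "numeric", nEquiv = "integer"),
  prototype = prototype(nuclearSpin = 0.5, nEquiv = 1L)
)

setValidity("Hyperfine", function(object) {
  msg <- character()
  if (length(object@A) != 3) msg <- c(msg, "A must have 3 principal values")
  if (!object@nuclearSpin %in% c(0.5, 1, 1.5, 2, 2.5))
    msg <- c(msg, "nuclearSpin must be one of 1/2, 1, 3/2, 2, 5/2")
  if (object@nEquiv < 1L) msg <- c(msg, "nEquiv must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param A numeric length 3 (or scalar, recycled), MHz.
#' @param nuclearSpin half-integer nuclear spin.
#' @param nEquiv number of equivalent nuclei.
#' @rdname Hyperfine-class
#' @examples
#' hyperfine(c(13, 13, 11), 1/2)
#' @export
hyperfine <- function(A, nuclearSpin = 0.5, nEquiv = 1L) {
  if (length(A) == 1) A <- rep(A, 3)
  new("Hyperfine", A = as.numeric(A), nuclearSpin = as.numeric(nuclearSpin),
      nEquiv = as.integer(nEquiv))
}

#' SpinSystem: an S = 1/2 paramagnetic species
#'
#' A spin-1/2 species described by a rhombic g-tensor, optional
#' first-order hyperfine couplings, a Gaussian linewidth model
#' (field-independent H-strain, widths in mT FWHM; or field-dependent
#' g-strain, widths as dimensionless FWHM g-distributions) and a
#' relative weight (concentration).
#'
#' @slot g numeric length 3, principal g-values.
#' @slot hyperfine list of \linkS4class{Hyperfine} objects (may be
#'   empty).
#' @slot lwMode character, \code{"H_strain"} or \code{"g_strain"}.
#' @slot lwWidths numeric length 3, FWHM along the g principal axes
#'   (mT for H-strain, delta-g for g-strain).
#' @slot weight numeric, relative concentration (> 0).
#' @slot label character.
#' @aliases SpinSystem
#' @exportClass SpinSystem
setClass("SpinSystem",
  slots = c(g = "numeric", hyperfine = "list", lwMode = "character",
            lwWidths = "numeric", weight = "numeric", label = "character"),
  prototype = prototype(hyperfine = list(), lwMode = "H_strain",
                        weight = 1, label = "")
)

setValidity("SpinSystem", function(object) {
  msg <- character()
  if (length(object@g) != 3 || any(object@g <= 0))
    msg <- c(msg, "g must be 3 positive principal values")
  if (!object@lwMode %in% c("H_strain", "g_strain"))
    msg <- c(msg, "lwMode must be 'H_strain' or 'g_strain'")
  if (length(object@lwWidths) != 3 || any(object@lwWidths < 0))
    msg <- c(msg, "lwWidths must be 3 nonnegative values")
  if (object@weight <= 0) msg <- c(msg, "weight must be positive")
  if (!all(vapply(object@hyperfine, is, logical(1), class2 = "Hyperfine")))
    msg <- c(msg, "hyperfine must be a list of Hyperfine objects")
  if (length(msg)) msg else TRUE
})

#' @param g numeric length 3 principal g-values.
#' @param hyperfine list of \linkS4class{Hyperfine} (or a single one).
#' @param lwMode linewidth model, \code{"H_strain"} or
#'   \code{"g_strain"}.
#' @param lwWidths numeric length 3 (or scalar) FWHM widths, mT for
#'   H-strain, delta-g for g-strain.
#' @param weight relative concentration.
#' @param label character label.
#' @rdname SpinSystem-class
#' @examples
#' spinSystem(c(2.0054, 2.0051, 2.0023), lwWidths = 0.7)
#' @export
spinSystem <- function(g, hyperfine = list(), lwMode = "H_strain",
                       lwWidths = 0.5, weight = 1, label = "") {
  if (is(hyperfine, "Hyperfine")) hyperfine <- list(hyperfine)
  if (length(lwWidths) == 1) lwWidths <- rep(lwWidths, 3)
  new("SpinSystem", g = as.numeric(g), hyperfine = hyperfine,
      lwMode = lwMode, lwWidths = as.numeric(lwWidths),
      weight = as.numeric(weight), label = label)
}

setMethod("show", "SpinSystem", function(object) {
  cat("SpinSystem", if (nzchar(object@label))
        paste0("'", object@label, "'") else "", "\n")
  cat("  g = (", paste(format(object@g), collapse = ", "), ")\n", sep = "")
  for (h in object@hyperfine)
    cat("  hyperfine: A = (", paste(format(h@A), collapse = ", "),
        ") MHz, I = ", h@nuclearSpin, ", n = ", h@nEquiv, "\n", sep = "")
  cat("  linewidth: ", object@lwMode, " FWHM = (",
      paste(format(object@lwWidths), collapse = ", "), ")",
      if (object@lwMode == "H_strain") " mT" else " (delta-g)",
      ", weight = ", object@weight, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EPRSpectrum
## ---------------------------------------------------------------------------

#' EPRSpectrum: a field-swept EPR spectrum
#'
#' Field axis (mT, strictly increasing) and intensity (arbitrary
#' units), with microwave frequency and detection harmonic metadata
#' (harmonic 0 = absorption, 1 = first derivative).
#'
#' @slot field numeric, mT, strictly increasing.
#' @slot intensity numeric, arbitrary units.
#' @slot frequencyGHz numeric scalar.
#' @slot harmonic integer, 0 or 1.
#' @slot label character.
#' @slot truth list, generating parameters for synthetic spectra.
#' @aliases EPRSpectrum
#' @exportClass EPRSpectrum
setClass("EPRSpectrum",
  slots = c(field = "numeric", intensity = "numeric",
            frequencyGHz = "numeric", harmonic = "integer",
            label = "character", truth = "list"),
  prototype = prototype(harmonic = 1L, label = "", truth = list())
)

setValidity("EPRSpectrum", function(object) {
  msg <- character()
  if (length(object@field) != length(object@intensity))
    msg <- c(msg, "field and intensity must have equal length")
  if (is.unsorted(object@field, strictly = TRUE))
    msg <- c(msg, "field axis must be strictly increasing")
  if (length(object@frequencyGHz) != 1 || object@frequencyGHz <= 0)
    msg <- c(msg, "frequencyGHz must be a single positive value")
  if (!object@harmonic %in% c(0L, 1L))
    msg <- c(msg, "harmonic must be 0 (absorption) or 1 (derivative)")
  if (length(msg)) msg else TRUE
})

#' Construct an EPRSpectrum
#'
#' @param field numeric field axis, mT.
#' @param intensity numeric intensities.
#' @param frequencyGHz microwave frequency, GHz.
#' @param harmonic 0 (absorption) or 1 (first derivative).
#' @param label character label.
#' @param truth optional list of generating parameters.
#' @return An \linkS4class{EPRSpectrum}.
#' @export
eprSpectrum <- function(field, intensity, frequencyGHz, harmonic = 1L,
                        label = "", truth = list()) {
  new("EPRSpectrum", field = as.numeric(field),
      intensity = as.numeric(intensity),
      frequencyGHz = as.numeric(frequencyGHz),
      harmonic = as.integer(harmonic), label = label, truth = truth)
}

setMethod("show", "EPRSpectrum", function(object) {
  cat("EPRSpectrum", if (nzchar(object@label))
        paste0("'", object@label, "'") else "", "\n")
  cat(sprintf("  %d points, B in [%.2f, %.2f] mT\n",
              length(object@field), min(object@field), max(object@field)))
  cat(sprintf("  frequency = %.5f GHz, harmonic = %d (%s)\n",
              object@frequencyGHz, object@harmonic,
              if (object@harmonic == 0L) "absorption" else
                "first derivative"))
})

## ---------------------------------------------------------------------------
## Kinetics
## ---------------------------------------------------------------------------

#' KineticsTable: substrate-rate pairs with enzyme metadata
#'
#' Steady-state kinetics of one enzyme preparation: substrate
#' concentrations (mM) against specific rates in enzyme units
#' (U = umol min-1 mg-1), with the molar mass of the complex used to
#' convert Vmax to a turnover number.
#'
#' @slot substrate numeric, mM (>= 0).
#' @slot rate numeric, U (>= 0).
#' @slot rateErr numeric, optional rate standard errors.
#' @slot enzymeMW numeric, complex molar mass in kDa.
#' @slot pH numeric.
#' @slot label character.
#' @slot truth list, generating parameters when synthetic.
#' @aliases KineticsTable
#' @exportClass KineticsTable
setClass("KineticsTable",
  slots = c(substrate = "numeric", rate = "numeric", rateErr = "numeric",
            enzymeMW = "numeric", pH = "numeric", label = "character",
            truth = "list"),
  prototype = prototype(rateErr = numeric(), pH = NA_real_, label = "",
                        truth = list())
)

setValidity("KineticsTable", function(object) {
  msg <- character()
  if (length(object@substrate) != length(object@rate))
    msg <- c(msg, "substrate and rate must have equal length")
  if (length(object@substrate) < 4)
    msg <- c(msg, "at least 4 substrate/rate pairs are required")
  if (any(object@substrate < 0) || any(object@rate < 0))
    msg <- c(msg, "substrate and rate must be nonnegative")
  if (length(object@rateErr) &&
      length(object@rateErr) != length(object@rate))
    msg <- c(msg, "rateErr must be empty or match rate length")
  if (length(object@enzymeMW) != 1 || !is.finite(object@enzymeMW) ||
      object@enzymeMW <= 0)
    msg <- c(msg, "enzymeMW must be a single positive value (kDa)")
  if (length(msg)) msg else TRUE
})

#' Construct a KineticsTable
#'
#' @param substrate numeric, mM.
#' @param rate numeric, U (umol min-1 mg-1).
#' @param rateErr optional numeric rate errors.
#' @param enzymeMW complex molar mass, kDa.
#' @param pH numeric.
#' @param label character.
#' @param truth optional list of generating parameters.
#' @return A \linkS4class{KineticsTable}.
#' @export
kineticsTable <- function(substrate, rate, rateErr = numeric(),
                          enzymeMW, pH = NA_real_, label = "",
                          truth = list()) {
  new("KineticsTable", substrate = as.numeric(substrate),
      rate = as.numeric(rate), rateErr = as.numeric(rateErr),
      enzymeMW = as.numeric(enzymeMW), pH = as.numeric(pH),
      label = label, truth = truth)
}

setMethod("show", "KineticsTable", function(object) {
  cat("KineticsTable", if (nzchar(object@label))
        paste0("'", object@label, "'") else "", "\n")
  cat(sprintf("  %d points, S in [%.3g, %.3g] mM, MW = %g kDa, pH %s\n",
              length(object@substrate), min(object@substrate),
              max(object@substrate), object@enzymeMW,
              format(object@pH)))
})

#' MMFit: fitted Michaelis-Menten parameters
#'
#' @slot vmax numeric, U.
#' @slot km numeric, mM.
#' @slot vmaxErr,kmErr numeric standard errors.
#' @slot kcat numeric, s-1 (vmax x MW / 60).
#' @slot rss numeric residual sum of squares.
#' @slot converged logical.
#' @slot enzymeMW numeric, kDa.
#' @slot label character.
#' @aliases MMFit
#' @exportClass MMFit
setClass("MMFit",
  slots = c(vmax = "numeric", km = "numeric", vmaxErr = "numeric",
            kmErr = "numeric", kcat = "numeric", rss = "numeric",
            converged = "logical", enzymeMW = "numeric",
            label = "character"),
  prototype = prototype(vmaxErr = NA_real_, kmErr = NA_real_,
                        rss = NA_real_, converged = TRUE, label = "")
)

setMethod("show", "MMFit", function(object) {
  cat("MMFit (Michaelis-Menten)\n")
  cat(sprintf("  Vmax = %.3g +/- %.2g U, Km = %.3g +/- %.2g mM\n",
              object@vmax, object@vmaxErr, object@km, object@kmErr))
  cat(sprintf("  kcat = %.3g s-1 (MW = %g kDa), rss = %.3g, converged = %s\n",
              object@kcat, object@enzymeMW, object@rss, object@converged))
})

## ---------------------------------------------------------------------------
## Spectral-analysis result containers
## ---------------------------------------------------------------------------

#' QuantitationResult: internal-standard spin quantitation
#'
#' @slot sampleDI numeric, double integral of the sample window (a.u.).
#' @slot referenceDI numeric, double integral of the reference window.
#' @slot referenceSpins numeric, spins per enzyme assigned to the
#'   reference center.
#' @slot spinsPerEnzyme numeric, sampleDI/referenceDI x referenceSpins.
#' @aliases QuantitationResult
#' @exportClass QuantitationResult
setClass("QuantitationResult",
  slots = c(sampleDI = "numeric", referenceDI = "numeric",
            referenceSpins = "numeric", spinsPerEnzyme = "numeric"))

setValidity("QuantitationResult", function(object) {
  if (object@referenceDI <= 0) return("referenceDI must be positive")
  ratio <- object@sampleDI / object@referenceDI * object@referenceSpins
  if (abs(ratio - object@spinsPerEnzyme) >
      1e-8 * max(1, abs(object@spinsPerEnzyme)))
    return("spinsPerEnzyme inconsistent with DI ratio")
  TRUE
})

setMethod("show", "QuantitationResult", function(object) {
  cat(sprintf(
    "QuantitationResult: %.3g spins/enzyme (DI ratio %.4g x %g reference spins)\n",
    object@spinsPerEnzyme, object@sampleDI / object@referenceDI,
    object@referenceSpins))
})

#' FieldCalibration: Mn(II)-marker field calibration
#'
#' The \code{offset} slot holds the mean discrepancy (measured minus
#' predicted marker line position); the additive correction to apply to
#' a field axis is \code{-offset} (see
#' \code{\link{applyFieldCalibration}}).
#'
#' @slot offset numeric, mT.
#' @slot markerG numeric, marker isotropic g-value.
#' @slot markerA numeric, marker isotropic hyperfine constant, mT.
#' @slot nLinesUsed integer, number of marker lines matched (1-6).
#' @aliases FieldCalibration
#' @exportClass FieldCalibration
setClass("FieldCalibration",
  slots = c(offset = "numeric", markerG = "numeric", markerA = "numeric",
            nLinesUsed = "integer"))

setValidity("FieldCalibration", function(object) {
  if (object@nLinesUsed < 1L || object@nLinesUsed > 6L)
    return("nLinesUsed must be between 1 and 6")
  TRUE
})

setMethod("show", "FieldCalibration", function(object) {
  cat(sprintf(
    "FieldCalibration: offset = %+.4f mT (apply %+.4f mT to field axis; %d marker lines)\n",
    object@offset, -object@offset, object@nLinesUsed))
})
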