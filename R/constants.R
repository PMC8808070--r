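#' Physical constants (CODATA 2018)
#'
#' Fixed physical constants used throughout the package: the Faraday
#' constant, the molar gas constant, the Planck constant, the Bohr
#' magneton and the free-electron g-factor. Values follow the CODATA
#' 2018 adjustment and are immutable.
#'
#' @return A named list with elements \code{faraday} (C mol-1),
#'   \code{gasConstant} (J mol-1 K-1), \code{planck} (J s),
#'   \code{bohrMagneton} (J T-1) and \code{freeElectronG}
#'   (dimensionless).
#' @examples
#' physicalConstants()$faraday
#' @export
physicalConstants <- function() {
  list(
    faraday       = 96485.33212,
    gasConstant   = 8.314462618,
    planck        = 6.62607015e-34,
    bohrMagneton  = 9.2740100783e-24,
    freeElectronG = 2.00231930436256
  )
}

## internal shorthands (hot paths avoid repeated list construction)
.F_CONST   <- 96485.33212
.R_CONST   <- 8.314462618
.H_CONST   <- 6.62607015e-34
.MUB_CONST <- 9.2740100783e-24

## Bohr magneton over Planck constant, in MHz per mT (= GHz per T).
## Converts hyperfine couplings in MHz to field offsets in mT.
.MHZ_PER_MT <- .MUB_CONST / .H_CONST * 1e-9

#' Round half away from zero
#'
#' Formatting convention for reported potentials: values are rounded
#' half away from zero (so -155.5 mV reports as -156 mV), unlike base
#' \code{round()} which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfAway(-155.5)  # -156
#' @export
roundHalfAway <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
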