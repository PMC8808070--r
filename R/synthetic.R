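## Seeded synthetic-data generators. Each generator draws from its own
## explicitly seeded stream (the caller's random state is restored on
## exit) and records the generating truth in the returned object, so
## recovery tests can compare fits against it.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a synthetic semiquinone titration curve
#'
#' Samples the two-step one-electron Nernst bell on an equally spaced
#' potential grid spanning [e2 - 120, e1 + 120] mV and adds Gaussian
#' amplitude noise, emulating an EPR-monitored reductive titration.
#' Defaults reproduce the conditions of a room-temperature titration
#' of a protein-stabilized menasemiquinone at pH 7.5: the printed fit
#' (E1, E2) = (-136, -175) mV, 30 points and amplitude noise of 0.02
#' (about 4% of the bell maximum).
#'
#' @param e1,e2 generating midpoint potentials, mV (e1 >= e2).
#' @param scale amplitude scale (default 1).
#' @param ph pH metadata (default 7.5).
#' @param temperature K (default 298.15).
#' @param nPoints number of titration points (>= 5, default 30).
#' @param noiseSd Gaussian amplitude noise SD (default 0.02).
#' @param seed integer seed (NULL uses the current stream).
#' @param label label.
#' @return A \linkS4class{TitrationCurve} with the generating
#'   parameters in \code{truthParams()}.
#' @examples
#' tc <- genTitration(seed = 1)
#' truthParams(tc)$e1
#' @export
genTitration <- function(e1 = -136, e2 = -175, scale = 1, ph = 7.5,
                         temperature = 298.15, nPoints = 30,
                         noiseSd = 0.02, seed = NULL, label = "") {
  if (nPoints < 5) stop("nPoints must be >= 5")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  E <- seq(e2 - 120, e1 + 120, length.out = nPoints)
  A <- .withSeed(seed,
    scale * semiquinoneFraction(E, e1, e2, temperature) +
      stats::rnorm(nPoints, 0, noiseSd))
  titrationCurve(E, pmax(A, 0), pH = ph, temperature = temperature,
                 label = label,
                 truth = list(e1 = e1, e2 = e2, scale = scale,
                              noiseSd = noiseSd, seed = seed))
}

#' Generate a synthetic EPR spectrum
#'
#' Simulates the powder spectrum of a spin system, shifts the field
#' axis by a (mis)calibration offset and adds white Gaussian noise,
#' emulating an experimental acquisition with an uncalibrated magnet.
#'
#' @param systems a \linkS4class{SpinSystem} or list of them.
#' @param frequencyGHz microwave frequency, GHz.
#' @param noiseSd white-noise SD in units of the spectrum's intensity
#'   (default 0).
#' @param fieldOffset additive field-axis offset, mT (default 0):
#'   features appear at their true position plus this offset.
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{simulatePowder}}
#'   (fieldRange, nPoints, harmonic, gridSpacing).
#' @return An \linkS4class{EPRSpectrum} with truth recorded.
#' @export
genSpectrum <- function(systems, frequencyGHz, noiseSd = 0,
                        fieldOffset = 0, seed = NULL, ...) {
  sp <- simulatePowder(systems, frequencyGHz, ...)
  y <- .withSeed(seed,
    sp@intensity + stats::rnorm(length(sp@intensity), 0, noiseSd))
  eprSpectrum(sp@field + fieldOffset, y, frequencyGHz, sp@harmonic,
              label = sp@label,
              truth = list(fieldOffset = fieldOffset, noiseSd = noiseSd,
                           seed = seed))
}

#' Generate a synthetic Michaelis-Menten kinetics table
#'
#' Log-spaced substrate grid from 0.1 Km to 30 Km with proportional
#' Gaussian rate noise, rate = MM(S) x (1 + N(0, relNoise)), emulating
#' spectrophotometric initial-rate assays (5% proportional error by
#' default). Negative noisy rates are clipped at zero and the clip
#' count recorded in the truth.
#'
#' @param vmax generating Vmax, U (default 43.7).
#' @param km generating Km, mM (default 5.1).
#' @param mw enzyme complex molar mass, kDa (default 132).
#' @param nPoints number of substrate points (default 12).
#' @param relNoise proportional noise SD (default 0.05).
#' @param ph pH metadata.
#' @param seed integer seed.
#' @param label label.
#' @return A \linkS4class{KineticsTable} with truth recorded.
#' @export
genKinetics <- function(vmax = 43.7, km = 5.1, mw = 132, nPoints = 12,
                        relNoise = 0.05, ph = 10, seed = NULL,
                        label = "") {
  if (relNoise < 0) stop("relNoise must be nonnegative")
  s <- exp(seq(log(0.1 * km), log(30 * km), length.out = nPoints))
  v <- .withSeed(seed,
    mmRate(s, vmax, km) * (1 + stats::rnorm(nPoints, 0, relNoise)))
  nClipped <- sum(v < 0)
  kineticsTable(s, pmax(v, 0), enzymeMW = mw, pH = ph, label = label,
                truth = list(vmax = vmax, km = km, mw = mw,
                             relNoise = relNoise, seed = seed,
                             nClipped = nClipped))
}
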