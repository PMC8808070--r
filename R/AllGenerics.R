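#' Accessors for EPRedox data classes
#'
#' Accessor generics for the package's S4 containers: \code{potentials}
#' and \code{amplitudes} for \linkS4class{TitrationCurve},
#' \code{fieldAxis} and \code{intensities} for
#' \linkS4class{EPRSpectrum}, \code{truthParams} for the generating
#' parameters recorded by the synthetic-data generators, and
#' \code{fitCoefficients} for fitted parameter vectors.
#'
#' @param x an EPRedox object.
#' @return Numeric vectors (or a list for \code{truthParams}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("fieldAxis", function(x) standardGeneric("fieldAxis"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))
#' @rdname accessors
#' @export
setGeneric("fitCoefficients", function(x) standardGeneric("fitCoefficients"))

#' @rdname accessors
setMethod("potentials", "TitrationCurve", function(x) x@potential)
#' @rdname accessors
setMethod("amplitudes", "TitrationCurve", function(x) x@amplitude)
#' @rdname accessors
setMethod("fieldAxis", "EPRSpectrum", function(x) x@field)
#' @rdname accessors
setMethod("intensities", "EPRSpectrum", function(x) x@intensity)
#' @rdname accessors
setMethod("truthParams", "TitrationCurve", function(x) x@truth)
#' @rdname accessors
setMethod("truthParams", "EPRSpectrum", function(x) x@truth)
#' @rdname accessors
setMethod("truthParams", "KineticsTable", function(x) x@truth)
#' @rdname accessors
setMethod("fitCoefficients", "TwoStepFit", function(x)
  c(e1 = x@e1, e2 = x@e2, scale = x@scale))
#' @rdname accessors
setMethod("fitCoefficients", "MMFit", function(x)
  c(vmax = x@vmax, km = x@km, kcat = x@kcat))
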