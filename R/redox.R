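## Two successive one-electron Nernst model for semiquinone titrations
## and the thermodynamic quantities derived from it.

#' Nernstian exponent factor alpha = F/RT
#'
#' @param temperature numeric, absolute temperature in K.
#' @return alpha in V-1. Callers working in mV must convert potential
#'   differences to volts before exponentiation.
#' @examples
#' alphaFactor(298.15)  # 38.92 V-1
#' @export
alphaFactor <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive (K)")
  .F_CONST / (.R_CONST * temperature)
}

#' Semiquinone fraction under the two-step one-electron model
#'
#' Fraction of a quinone pool present as the semiquinone at ambient
#' potential E when the quinone/semiquinone and semiquinone/quinol
#' couples have midpoint potentials \code{e1} and \code{e2}:
#' \deqn{f(E) = 1 / (1 + e^{\alpha(E - E_1)} + e^{\alpha(E_2 - E)})}
#' with \eqn{\alpha = F/RT}. The curve is bell-shaped, peaking at
#' \eqn{E_m = (E_1 + E_2)/2}.
#'
#' @param potential numeric vector, ambient potential in mV vs SHE.
#' @param e1 midpoint potential of the oxidized/semiquinone couple, mV.
#' @param e2 midpoint potential of the semiquinone/quinol couple, mV.
#' @param temperature K (default 298.15).
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' semiquinoneFraction(-66, -42, -90)   # 0.560
#' semiquinoneFraction(-100, -100, -100)  # 1/3
#' @export
semiquinoneFraction <- function(potential, e1, e2, temperature = 298.15) {
  a <- alphaFactor(temperature) / 1000  # per mV
  1 / (1 + exp(a * (potential - e1)) + exp(a * (e2 - potential)))
}

#' Two-electron midpoint potential
#'
#' @param e1,e2 one-electron midpoint potentials, mV.
#' @return (e1 + e2)/2, mV.
#' @examples
#' midpointEm(-42, -90)    # -66
#' midpointEm(-136, -175)  # -155.5, reported as -156 at 1 mV rounding
#' @export
midpointEm <- function(e1, e2) (e1 + e2) / 2

#' Semiquinone stability constant
#'
#' Equilibrium constant of the comproportionation reaction
#' quinone + quinol = 2 semiquinone,
#' \eqn{K_S = [SQ]^2/([Q][QH_2]) = e^{\alpha(E_1 - E_2)}}.
#'
#' @inheritParams midpointEm
#' @param temperature K.
#' @return Dimensionless stability constant.
#' @examples
#' stabilityConstant(-136, -175)  # 4.56, ~5
#' @export
stabilityConstant <- function(e1, e2, temperature = 298.15) {
  exp(alphaFactor(temperature) * (e1 - e2) / 1000)
}

#' Maximal semiquinone fraction
#'
#' Peak value of the bell-shaped semiquinone curve, attained at
#' \eqn{E_m}: \eqn{SQ_{max} = 1/(1 + 2 e^{(\alpha/2)(E_2 - E_1)})}.
#'
#' @inheritParams stabilityConstant
#' @return Fraction in (0, 1].
#' @examples
#' maxSemiquinoneFraction(-42, -90)  # 0.560
#' @export
maxSemiquinoneFraction <- function(e1, e2, temperature = 298.15) {
  1 / (1 + 2 * exp(alphaFactor(temperature) / 2 * (e2 - e1) / 1000))
}

#' Q-site occupancy from semiquinone quantitation
#'
#' Ratio between the measured semiquinone concentration per enzyme
#' (from spin quantitation) and the theoretical maximal semiquinone
#' fraction for the fitted couple potentials.
#'
#' @param mskPerEnzyme measured semiquinone per enzyme (>= 0).
#' @inheritParams stabilityConstant
#' @return Occupancy (dimensionless, ~0 to 1).
#' @examples
#' occupancy(0.5, -42, -90)  # 0.89
#' @export
occupancy <- function(mskPerEnzyme, e1, e2, temperature = 298.15) {
  if (any(mskPerEnzyme < 0)) stop("mskPerEnzyme must be nonnegative")
  mskPerEnzyme / maxSemiquinoneFraction(e1, e2, temperature)
}

#' Quinone/quinol binding ratio from a midpoint-potential shift
#'
#' A difference in the binding constants of the oxidized quinone (K_Q)
#' and the quinol (K_QH2) to a protein site shifts the bound couple's
#' two-electron midpoint potential from the free one:
#' \deqn{E_m(bound) - E_m(free) = (1/2\alpha) \ln(K_{QH_2}/K_Q)}
#' Inverting, the ratio is \eqn{K_{QH_2}/K_Q = e^{2\alpha \Delta E_m}}.
#' A negative shift therefore means tighter binding of the oxidized
#' quinone; the reciprocal is reported as \code{foldTighterOxidized}.
#'
#' @param emShift Em(bound) - Em(free), mV.
#' @param temperature K.
#' @return A list with \code{ratio} (K_QH2/K_Q) and
#'   \code{foldTighterOxidized} (K_Q/K_QH2).
#' @examples
#' bindingRatioFromShift(-56)$foldTighterOxidized  # 78.2-fold
#' @export
bindingRatioFromShift <- function(emShift, temperature = 298.15) {
  r <- exp(2 * alphaFactor(temperature) * emShift / 1000)
  list(ratio = r, foldTighterOxidized = 1 / r)
}

#' Em-vs-pH slope
#'
#' Least-squares slope of the two-electron midpoint potential against
#' pH; -59 mV/pH at 25 C indicates a 2H+/2e- reaction. With two
#' points this reduces to the exact two-point slope.
#'
#' @param ph numeric vector of pH values (>= 2 distinct values).
#' @param em numeric vector of Em values, mV.
#' @return Slope in mV per pH unit.
#' @examples
#' phSlope(c(6, 7.5), c(-66, -155.5))  # -59.7
#' @export
phSlope <- function(ph, em) {
  if (length(ph) != length(em)) stop("ph and em must have equal length")
  if (length(unique(ph)) < 2)
    stop("at least 2 distinct pH values are required")
  unname(stats::coef(stats::lm(em ~ ph))[2])
}

#' Fit a titration curve to the two-step one-electron model
#'
#' Least-squares fit of amplitude = scale x
#' \code{\link{semiquinoneFraction}}(E; e1, e2) to a bell-shaped
#' EPR-monitored titration. A free multiplicative scale is always
#' fitted, because normalizing to a noisy observed maximum is
#' ill-defined when the true peak falls between sampled potentials.
#' Levenberg-Marquardt least squares is started from 8 deterministic
#' initial guesses spanning the observed potential range (the
#' likelihood is occasionally flat in E1 - E2); the best fit by
#' residual sum of squares is kept and relabeled so e1 >= e2 (the
#' model is symmetric under label exchange). Weighted least squares
#' (1/err^2) is used when the curve carries amplitude errors.
#'
#' @param curve a \linkS4class{TitrationCurve} with >= 5 points.
#' @param init optional numeric c(e1, e2, scale) initial guess, tried
#'   in addition to the deterministic multi-starts.
#' @return A \linkS4class{TwoStepFit}; \code{converged} is FALSE when
#'   no start converged (parameters then come from the best attempt).
#' @examples
#' tc <- genTitration(e1 = -136, e2 = -175, seed = 1)
#' fitTitration(tc)
#' @export
fitTitration <- function(curve, init = NULL) {
  stopifnot(is(curve, "TitrationCurve"))
  E <- curve@potential
  A <- curve@amplitude
  if (length(E) < 5) stop("at least 5 titration points are required")
  if (diff(range(A)) <= .Machine$double.eps * max(1, max(abs(A))))
    stop("degenerate curve: amplitude is constant")
  Tk <- curve@temperature

  w <- if (length(curve@amplitudeErr) && all(curve@amplitudeErr > 0))
    1 / curve@amplitudeErr^2 else rep(1, length(E))

  ## deterministic multi-starts: center from the amplitude-weighted
  ## observed maximum region, gaps spanning narrow to wide bells
  emCand <- c(E[which.max(A)], sum(E * A) / sum(A))
  gapCand <- c(20, 60, 120, 240)
  starts <- expand.grid(em = emCand, gap = gapCand)
  startList <- lapply(seq_len(nrow(starts)), function(i) {
    em <- starts$em[i]; gap <- starts$gap[i]
    c(e1 = em + gap / 2, e2 = em - gap / 2,
      scale = max(A) / maxSemiquinoneFraction(gap / 2, -gap / 2, Tk))
  })
  if (!is.null(init)) {
    init <- as.numeric(init)
    startList <- c(list(c(e1 = init[1], e2 = init[2], scale = init[3])),
                   startList)
  }

  dat <- data.frame(E = E, A = A)
  best <- NULL
  for (st in startList) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        A ~ scale * semiquinoneFraction(E, e1, e2, Tk),
        data = dat, start = as.list(st), weights = w,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-14)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new("TwoStepFit", e1 = 0, e2 = 0, scale = 1,
               rss = NA_real_, converged = FALSE,
               temperature = Tk, pH = curve@pH, label = curve@label))

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   c(e1 = NA_real_, e2 = NA_real_, scale = NA_real_))
  ## relabel so e1 >= e2
  if (cf["e1"] < cf["e2"]) {
    cf[c("e1", "e2")] <- cf[c("e2", "e1")]
    se[c("e1", "e2")] <- se[c("e2", "e1")]
  }
  new("TwoStepFit",
      e1 = unname(cf["e1"]), e2 = unname(cf["e2"]),
      scale = unname(cf["scale"]),
      e1Err = unname(se["e1"]), e2Err = unname(se["e2"]),
      scaleErr = unname(se["scale"]),
      rss = best$rss, converged = isTRUE(best$fit$convInfo$isConv),
      temperature = Tk, pH = curve@pH, label = curve@label)
}

#' Thermodynamic quantities derived from a two-step fit
#'
#' Collects the derived redox quantities for a fitted (or printed)
#' pair of one-electron midpoint potentials: the two-electron midpoint
#' potential, the semiquinone stability constant and the maximal
#' semiquinone fraction; optionally the Q-site occupancy (when a
#' semiquinone-per-enzyme quantitation is supplied) and the
#' quinol/quinone binding ratio (when the free couple's Em is
#' supplied).
#'
#' @param fit a \linkS4class{TwoStepFit}, or a numeric e1 (mV) together
#'   with \code{e2}.
#' @param e2 numeric, mV (ignored when \code{fit} is a TwoStepFit).
#' @param temperature K (taken from the fit when available).
#' @param mskPerEnzyme optional measured semiquinone per enzyme.
#' @param emFree optional Em of the free quinone couple, mV.
#' @return A list with \code{em}, \code{ks}, \code{mskMax} and, when
#'   computable, \code{rOcc}, \code{emShift}, \code{bindingRatio}
#'   (K_QH2/K_Q) and \code{foldTighterOxidized}.
#' @examples
#' derivedRedox(-136, -175)
#' @export
derivedRedox <- function(fit, e2 = NULL, temperature = 298.15,
                         mskPerEnzyme = NULL, emFree = NULL) {
  if (is(fit, "TwoStepFit")) {
    e1 <- fit@e1; e2 <- fit@e2; temperature <- fit@temperature
  } else {
    e1 <- fit
    if (is.null(e2)) stop("supply e2 when fit is a numeric e1")
  }
  out <- list(
    em     = midpointEm(e1, e2),
    ks     = stabilityConstant(e1, e2, temperature),
    mskMax = maxSemiquinoneFraction(e1, e2, temperature))
  if (!is.null(mskPerEnzyme))
    out$rOcc <- occupancy(mskPerEnzyme, e1, e2, temperature)
  if (!is.null(emFree)) {
    out$emShift <- out$em - emFree
    br <- bindingRatioFromShift(out$emShift, temperature)
    out$bindingRatio <- br$ratio
    out$foldTighterOxidized <- br$foldTighterOxidized
  }
  out
}
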