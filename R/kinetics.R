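## Michaelis-Menten fitting and the unit conversions connecting Vmax,
## enzyme molar mass and kcat.

#' Michaelis-Menten rate
#'
#' @param s substrate concentration, mM (vectorized).
#' @param vmax maximal specific rate, U (umol min-1 mg-1).
#' @param km half-saturation constant, mM (> 0).
#' @return Rate(s), U.
#' @examples
#' mmRate(50, 43.7, 5.1)  # 39.7 U
#' @export
mmRate <- function(s, vmax, km) {
  if (any(km <= 0)) stop("km must be positive")
  vmax * s / (km + s)
}

#' Turnover number from specific activity
#'
#' Converts a maximal specific rate in enzyme units
#' (U = umol min-1 mg-1) to a turnover number using the molar mass of
#' the complex: U x kDa = umol min-1 mg-1 x mg umol-1 = min-1, divided
#' by 60 to give s-1. The molar mass of the full complex is used, so
#' the result is a per-complex turnover; substitute a per-active-site
#' mass for per-site numbers.
#'
#' @param vmax maximal specific rate, U.
#' @param mw molar mass, kDa.
#' @return kcat in s-1.
#' @examples
#' kcatFromVmax(43.7, 132)  # 96.1 s-1
#' kcatFromVmax(7.5, 132)   # 16.5 s-1
#' @export
kcatFromVmax <- function(vmax, mw) {
  if (any(vmax < 0) || any(mw <= 0))
    stop("vmax must be nonnegative and mw positive")
  vmax * mw / 60
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least-squares fit of rate = Vmax S / (Km + S)
#' (Levenberg-Marquardt), weighted by 1/err^2 when rate errors are
#' present. Standard errors come from the fit covariance; the turnover
#' number is filled via \code{\link{kcatFromVmax}} using the table's
#' enzyme molar mass.
#'
#' @param table a \linkS4class{KineticsTable} with >= 4 points spanning
#'   substrate concentrations below and above Km.
#' @return An \linkS4class{MMFit}; \code{converged} is FALSE when the
#'   optimizer failed to converge.
#' @examples
#' kt <- genKinetics(vmax = 43.7, km = 5.1, mw = 132, seed = 7)
#' fitMM(kt)
#' @export
fitMM <- function(table) {
  stopifnot(is(table, "KineticsTable"))
  s <- table@substrate
  v <- table@rate
  if (length(unique(s)) < 2)
    stop("substrate concentrations are all equal")
  w <- if (length(table@rateErr) && all(table@rateErr > 0))
    1 / table@rateErr^2 else rep(1, length(v))
  dat <- data.frame(s = s, v = v)
  start <- list(vmax = max(v) * 1.2,
                km = max(stats::median(s), min(s[s > 0]) / 2))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = dat,
                      start = start, weights = w,
                      lower = c(vmax = 0, km = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("MMFit", vmax = NA_real_, km = NA_real_,
               kcat = NA_real_, converged = FALSE,
               enzymeMW = table@enzymeMW, label = table@label))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  new("MMFit",
      vmax = unname(cf["vmax"]), km = unname(cf["km"]),
      vmaxErr = unname(se["vmax"]), kmErr = unname(se["km"]),
      kcat = kcatFromVmax(unname(cf["vmax"]), table@enzymeMW),
      rss = sum(w * stats::residuals(fit)^2),
      converged = isTRUE(fit$convInfo$isConv),
      enzymeMW = table@enzymeMW, label = table@label)
}

#' pH optimum by quadratic interpolation
#'
#' Locates the pH of maximal activity by fitting a parabola through
#' the maximal point and its two neighbours. Monotone profiles return
#' the boundary pH with a warning; ties break toward the lower pH.
#'
#' @param ph numeric vector of pH values (>= 3).
#' @param kcat numeric vector of activities at those pH values.
#' @return The interpolated optimum pH.
#' @examples
#' phOptimum(c(8, 9, 10), c(1, 3, 1))  # 9
#' @export
phOptimum <- function(ph, kcat) {
  if (length(ph) != length(kcat)) stop("ph and kcat lengths differ")
  if (length(ph) < 3) stop("at least 3 points are required")
  o <- order(ph)
  ph <- ph[o]; kcat <- kcat[o]
  i <- which.max(kcat)  # first maximum = lower pH on ties
  if (i == 1 || i == length(ph)) {
    warning("monotone profile: optimum at the boundary of the pH range")
    return(ph[i])
  }
  x <- ph[(i - 1):(i + 1)]
  y <- kcat[(i - 1):(i + 1)]
  cf <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (cf[3] >= 0) return(ph[i])  # degenerate curvature
  unname(-cf[2] / (2 * cf[3]))
}
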