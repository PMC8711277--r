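#' Fit the length-mass power law
#'
#' Estimates `mass = a * SL^b` by nonlinear least squares in natural
#' (untransformed) space, so the absolute residuals of the heaviest
#' individuals are weighted as measured rather than log-compressed.
#' Starting values come from the log-log linear regression.
#'
#' @param SL Shell lengths (mm), > 0.
#' @param mass Masses (g), same length; typically total wet weight, but
#'   the same machinery serves flesh dry weight.
#' @param min_n Minimum number of usable records (default 10).
#' @return An object of class `"allometry_fit"`: list with `a`
#'   (g mm^-b), `b` (dimensionless), `n`, `rmse` (g). A warning is
#'   emitted when `b` falls outside the biologically usual 2-4 band.
#' @export
#' @examples
#' sl <- seq(5, 60, length.out = 50)
#' fit_allometry(sl, 1e-5 * sl^3)
fit_allometry <- function(SL, mass, min_n = 10) {
  keep <- is.finite(SL) & is.finite(mass) & SL > 0 & mass > 0
  SL <- SL[keep]; mass <- mass[keep]
  if (length(SL) < min_n)
    stop("need at least ", min_n, " records with both length and mass")
  if (length(unique(SL)) < 2)
    stop("all lengths equal: exponent is unidentifiable")
  start_fit <- stats::lm(log(mass) ~ log(SL))
  start <- list(a = exp(stats::coef(start_fit)[[1]]),
                b = stats::coef(start_fit)[[2]])
  fit <- minpack.lm::nlsLM(mass ~ a * SL^b, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf[["b"]] < 2 || cf[["b"]] > 4)
    warning(sprintf("allometric exponent b = %.2f outside the usual 2-4 range",
                    cf[["b"]]))
  structure(list(a = cf[["a"]], b = cf[["b"]], n = length(SL),
                 rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Power-law allometry: mass = %.4g * SL^%.3f  (n = %d, rmse = %.3g g)\n",
              x$a, x$b, x$n, x$rmse))
  invisible(x)
}

#' Predict mass from shell length
#'
#' @param fit An `"allometry_fit"` (or list with `a` and `b`).
#' @param SL Shell length(s), mm, >= 0.
#' @return Predicted mass in g.
#' @export
predict_mass <- function(fit, SL) {
  if (any(SL < 0)) stop("'SL' must be non-negative")
  fit$a * SL^fit$b
}
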