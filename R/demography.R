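#' Age-class distribution from known ages
#'
#' Bins ages (decimal years since recruitment) into one-year classes:
#' class `t` holds ages in `[t - 1, t)`. Useful when true ages are
#' available (simulation truth, sclerochronology) and as the substrate
#' of [fit_mortality()].
#'
#' @param ages Non-negative ages in years.
#' @return An object of class `"age_structure"`.
#' @export
age_structure_from_ages <- function(ages) {
  if (length(ages) == 0L) stop("no ages supplied")
  if (any(ages < 0)) stop("ages must be non-negative")
  cls <- floor(ages) + 1L
  structure(list(age_class = seq_len(max(cls)),
                 count = tabulate(cls, nbins = max(cls)),
                 n_dropped = 0L),
            class = "age_structure")
}

#' Build an age-class distribution from shell lengths
#'
#' Ages are obtained by inverting the growth curve
#' ([age_from_length()]); age class `t` collects ages in the interval
#' `[t - 1, t)` years, so class 1 is the first year of life (the class
#' later excluded from the mortality regression because recruitment
#' variability dominates it). Individuals at or above `Linf` cannot be
#' aged and are dropped with a warning.
#'
#' @param SL Shell lengths (mm).
#' @param params A [growth_params()] object.
#' @param max_age Classes are retained contiguously from 1 up to the
#'   oldest occupied class (zero-count classes kept in between).
#' @return An object of class `"age_structure"`: list with
#'   `age_class` (1, 2, ...), `count`, and `n_dropped`.
#' @export
assign_age_classes <- function(SL, params, max_age = NULL) {
  params <- as_growth_params(params)
  if (length(SL) == 0L) stop("no individuals supplied")
  drop <- SL >= params$Linf
  if (any(drop))
    warning(sum(drop), " individuals at or above Linf dropped (unageable)")
  SL <- SL[!drop]
  if (length(SL) == 0L) stop("all individuals at or above Linf")
  age <- age_from_length(params, SL) - params$t0
  cls <- floor(age) + 1L
  top <- max(cls)
  structure(list(age_class = seq_len(top),
                 count = tabulate(cls, nbins = top),
                 n_dropped = sum(drop)),
            class = "age_structure")
}

#' @export
print.age_structure <- function(x, ...) {
  cat("Age-class distribution\n")
  print(stats::setNames(x$count, x$age_class))
  invisible(x)
}

#' Catch-curve mortality from an age-class distribution
#'
#' Fits the negative exponential survivorship model `N_t = N_1 *
#' exp(-Z t)` by ordinary least squares of `log(N_t)` on `t` over the
#' included classes (the classic catch-curve estimator). Age class 1 is
#' excluded by default: its size reflects the most recent recruitment
#' pulse more than cumulative mortality. Classes with zero counts
#' cannot enter the log regression and are omitted with a note. Z is
#' invariant to rescaling all counts, so raw counts and standardized
#' densities give the same estimate.
#'
#' @param structure An `"age_structure"` (or list with `age_class` and
#'   `count`).
#' @param exclude_class_1 Drop age class 1 (default `TRUE`).
#' @return An object of class `"mortality_fit"`: list with `Z` (1/yr),
#'   `N1_hat` (fitted abundance at t = 1), `r_squared`,
#'   `n_classes_used` and `excluded_class_1`.
#' @export
fit_mortality <- function(structure, exclude_class_1 = TRUE) {
  t <- structure$age_class
  n <- structure$count
  keep <- n > 0
  if (exclude_class_1) keep <- keep & t != 1L
  t <- t[keep]; n <- n[keep]
  if (length(t) < 3)
    stop("need at least 3 positive age classes after exclusion")
  y <- log(n)
  if (stats::sd(y) < 1e-12) {
    z <- 0; n1 <- n[1]; r2 <- 0
  } else {
    fit <- stats::lm(y ~ t)
    cf <- stats::coef(fit)
    z <- -cf[[2]]
    n1 <- exp(cf[[1]] + cf[[2]] * 1)
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  }
  structure(list(Z = z, N1_hat = n1, r_squared = r2,
                 n_classes_used = length(t),
                 excluded_class_1 = exclude_class_1),
            class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("Catch-curve mortality: Z = %.3f /yr (r2 = %.3f, %d classes%s)\n",
              x$Z, x$r_squared, x$n_classes_used,
              if (x$excluded_class_1) ", class 1 excluded" else ""))
  invisible(x)
}
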