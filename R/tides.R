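#' Simulate an hourly tide-height series
#'
#' Sum of sinusoidal constituents around a mean level, sampled hourly —
#' a stand-in for a tide-gauge record. The defaults emulate a
#' mixed/semidiurnal regime with principal lunar (M2, 12.42 h) and
#' solar (S2, 12.00 h) constituents, whose beat produces the
#' spring-neap cycle.
#'
#' @param years Length of the series in years.
#' @param amplitudes Constituent amplitudes (m).
#' @param periods_h Constituent periods (hours), same length.
#' @param mean_level Mean water height (m above LAT).
#' @param phases Constituent phases (radians), default 0.
#' @param surge_sd Standard deviation of optional Gaussian surge noise
#'   (m); 0 disables it.
#' @param seed Seed used only when `surge_sd > 0`.
#' @param start_year Decimal year of the first record.
#' @return A data frame of class `"tide_series"` with `time` (decimal
#'   years) and `height_m` (m above LAT).
#' @export
simulate_tides <- function(years = 5, amplitudes = c(2.0, 0.6),
                           periods_h = c(12.42, 12.00), mean_level = 4,
                           phases = NULL, surge_sd = 0, seed = 1,
                           start_year = 2015) {
  stopifnot(length(amplitudes) == length(periods_h), all(periods_h > 0),
            years > 0)
  if (is.null(phases)) phases <- rep(0, length(amplitudes))
  hours <- seq(0, years * 8766 - 1)  # 8766 h = one mean year
  h <- rep(mean_level, length(hours))
  for (i in seq_along(amplitudes))
    h <- h + amplitudes[i] * sin(2 * pi * hours / periods_h[i] + phases[i])
  if (surge_sd > 0) {
    set.seed(seed)
    h <- h + stats::rnorm(length(h), 0, surge_sd)
  }
  structure(data.frame(time = start_year + hours / 8766, height_m = h),
            class = c("tide_series", "data.frame"))
}

#' Empirical percentage immersion time at a height
#'
#' Fraction of hourly records during which the water stood at or above
#' the given intertidal height (a tie counts as immersed), expressed as
#' a percentage. Exactly non-increasing in height by construction.
#'
#' @param tides Data frame with a `height_m` column (hourly records).
#' @param height Intertidal height(s), m above LAT.
#' @return Immersion percentage(s) in `[0, 100]`.
#' @export
empirical_immersion <- function(tides, height) {
  h <- tides$height_m
  if (length(h) == 0) stop("empty tide series")
  vapply(height, function(z) 100 * mean(h >= z), numeric(1))
}

#' Fit the cubic immersion-vs-height model
#'
#' Least-squares cubic polynomial through the (height, empirical
#' immersion) pairs evaluated on a grid across the mussel zone. The
#' cubic gives a smooth, invertible summary of the empirical immersion
#' curve over the fitted range; evaluations are clamped to `[0, 100]`.
#'
#' @param tides Hourly tide series (data frame with `height_m`).
#' @param height_grid Heights (m) at which the empirical immersion is
#'   computed; default 0.1 m steps over 3.0-5.5 m, the observed mussel
#'   zone. At least 8 points spanning at least 4 distinct heights.
#' @return An object of class `"immersion_model"`: `coefficients`
#'   (intercept first), `fit_range`, `rmse` (percentage points) and the
#'   fitted grid.
#' @export
fit_immersion_polynomial <- function(tides,
                                     height_grid = seq(3.0, 5.5, by = 0.1)) {
  if (length(height_grid) < 8 || length(unique(height_grid)) < 4)
    stop("degenerate height grid: need >= 8 points, >= 4 distinct heights")
  imm <- empirical_immersion(tides, height_grid)
  fit <- stats::lm(imm ~ stats::poly(height_grid, 3, raw = TRUE))
  pred <- stats::fitted(fit)
  structure(list(coefficients = unname(stats::coef(fit)),
                 fit_range = range(height_grid),
                 rmse = sqrt(mean((imm - pred)^2)),
                 grid = data.frame(height_m = height_grid,
                                   immersion_pct = imm)),
            class = "immersion_model")
}

#' Evaluate an immersion model at intertidal heights
#'
#' @param model An `"immersion_model"`.
#' @param height Heights (m above LAT).
#' @return Immersion percentages clamped to `[0, 100]`; heights outside
#'   the fitted range are evaluated at the polynomial but flagged via
#'   the `"out_of_range"` attribute.
#' @export
predict_immersion <- function(model, height) {
  cf <- model$coefficients
  val <- cf[1] + cf[2] * height + cf[3] * height^2 + cf[4] * height^3
  out <- height < model$fit_range[1] | height > model$fit_range[2]
  val[height < model$fit_range[1]] <- 100
  val[height > model$fit_range[2]] <- 0
  val <- pmin(pmax(val, 0), 100)
  attr(val, "out_of_range") <- out
  val
}

#' Annotate quadrats with their immersion percentage
#'
#' Adds `immersion_pct` and `immersion_out_of_range` columns to a
#' quadrat table, from each quadrat's intertidal height. Row count and
#' order are preserved, and re-annotating is idempotent.
#'
#' @param model An `"immersion_model"`.
#' @param quadrats Data frame with a `height_lat_m` column.
#' @return The quadrat table with the two added columns.
#' @export
assign_immersion <- function(model, quadrats) {
  stopifnot("height_lat_m" %in% names(quadrats))
  val <- predict_immersion(model, quadrats$height_lat_m)
  quadrats$immersion_pct <- as.numeric(val)
  quadrats$immersion_out_of_range <- attr(val, "out_of_range")
  quadrats
}

#' @export
print.immersion_model <- function(x, ...) {
  cat(sprintf("Cubic immersion model over %.2f-%.2f m (rmse %.2f %%-points)\n",
              x$fit_range[1], x$fit_range[2], x$rmse))
  cat("  coefficients:", format(x$coefficients, digits = 4), "\n")
  invisible(x)
}
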