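#' Constants of the reproductive-output calculation
#'
#' Bundles the biological constants behind the potential
#' reproductive-output estimate: reproductive maturity above 12 mm
#' shell length, gamete output worth 28% of flesh dry mass, the
#' egg-mass equivalence of one million eggs per 52.5 mg, and a 1:1 sex
#' ratio (half the biomass is female and produces eggs).
#'
#' @param maturity_length_mm Maturity threshold, strict `>` comparison.
#' @param fecundity_fraction Fraction of flesh dry mass released as
#'   gametes.
#' @param egg_mass_equiv_mg Milligrams per 10^6 eggs.
#' @param female_fraction Fraction of mature individuals assumed
#'   female; set to 1 to count total gamete mass without halving.
#' @return A list of class `"repro_constants"`.
#' @export
repro_constants <- function(maturity_length_mm = 12,
                            fecundity_fraction = 0.28,
                            egg_mass_equiv_mg = 52.5,
                            female_fraction = 0.5) {
  stopifnot(maturity_length_mm > 0, fecundity_fraction > 0,
            fecundity_fraction <= 1, egg_mass_equiv_mg > 0,
            female_fraction > 0, female_fraction <= 1)
  structure(list(maturity_length_mm = maturity_length_mm,
                 fecundity_fraction = fecundity_fraction,
                 egg_mass_equiv_mg = egg_mass_equiv_mg,
                 female_fraction = female_fraction),
            class = "repro_constants")
}

#' Condition index
#'
#' `CI = FDW / SL^3`: flesh dry weight over shell length cubed, a
#' mass-per-volume proxy of physiological state. With `SL` in mm the
#' index is in g mm^-3; only relative comparisons are meaningful, so
#' the unit is a labelling convention.
#'
#' @param FDW Flesh dry weight (g), >= 0.
#' @param SL Shell length (> 0), in mm by convention.
#' @return Condition index.
#' @export
condition_index <- function(FDW, SL) {
  if (any(SL <= 0)) stop("'SL' must be positive")
  if (any(FDW < 0)) stop("'FDW' must be non-negative")
  FDW / SL^3
}

#' G-test of independence for a 2x2 table
#'
#' Likelihood-ratio test `G = 2 * sum(O * log(O / E))` with expected
#' counts from the independence model; used to contrast the frequency
#' of spawning versus non-spawning individuals between shores at each
#' sampling date. Zero cells contribute nothing to the sum; a zero
#' marginal makes the table degenerate and is an error.
#'
#' @param table A 2x2 matrix of counts.
#' @return List with `G`, `df` (1) and `p` (chi-square reference).
#' @export
#' @examples
#' g_test(matrix(c(8, 3, 2, 7), 2))
g_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("degenerate table: zero marginal")
  E <- outer(rs, cs) / n
  terms <- ifelse(table > 0, table * log(table / E), 0)
  G <- 2 * sum(terms)
  list(G = G, df = 1L, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Chi-squared test of a 1:1 sex ratio
#'
#' `X^2 = (n_female - n_male)^2 / (n_female + n_male)` against the
#' equal-frequency null, referred to chi-square with 1 df.
#'
#' @param n_female,n_male Counts.
#' @return List with `chi2`, `df` and `p`.
#' @export
sex_ratio_test <- function(n_female, n_male) {
  stopifnot(n_female >= 0, n_male >= 0)
  n <- n_female + n_male
  if (n == 0) stop("no sexed individuals")
  chi2 <- (n_female - n_male)^2 / n
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Convert a gamete mass flux to an egg flux
#'
#' Applies the egg-mass equivalence (default 10^6 eggs = 52.5 mg):
#' `eggs = mass_g * 1000 / equiv_mg * 10^6`.
#'
#' @param mass_g Gamete mass (g, per m^2 or absolute), >= 0.
#' @param egg_mass_equiv_mg Milligrams per 10^6 eggs.
#' @return Number of eggs (same spatial normalisation as the input).
#' @export
#' @examples
#' eggs_from_mass(112.92)  # ~2.15e9 eggs
eggs_from_mass <- function(mass_g, egg_mass_equiv_mg = 52.5) {
  if (any(mass_g < 0)) stop("'mass_g' must be non-negative")
  mass_g * 1000 / egg_mass_equiv_mg * 1e6
}

#' Potential reproductive output of a quadrat population
#'
#' Egg mass and egg numbers released per square meter of covered area:
#' mature individuals (shell length strictly above the maturity
#' threshold) contribute `female_fraction * fecundity_fraction` of
#' their flesh dry weight, summed and divided by the covered area
#' `CC * QA`; the mass flux is converted to eggs with the egg-mass
#' equivalence. Missing flesh dry weights are predicted from shell
#' length through a dry-mass allometry.
#'
#' @param individuals Data frame with `sl_mm` and optionally `fdw_g`.
#' @param covered_fraction CC in (0, 1].
#' @param quadrat_area_m2 QA in m^2.
#' @param fdw_allometry An `"allometry_fit"` of flesh dry weight on
#'   shell length, used where `fdw_g` is missing (may be `NULL` if all
#'   mature individuals carry `fdw_g`).
#' @param constants A [repro_constants()] object.
#' @return List of class `"repro_output"`: `mass_output_g_m2`,
#'   `egg_output_m2`, `n_mature`, `mature_density_m2`.
#' @export
reproductive_output <- function(individuals, covered_fraction,
                                quadrat_area_m2 = 0.0625,
                                fdw_allometry = NULL,
                                constants = repro_constants()) {
  area <- covered_area_m2(covered_fraction, quadrat_area_m2)
  mature <- individuals[individuals$sl_mm > constants$maturity_length_mm, ,
                        drop = FALSE]
  if (nrow(mature) == 0) {
    return(structure(list(mass_output_g_m2 = 0, egg_output_m2 = 0,
                          n_mature = 0L, mature_density_m2 = 0),
                     class = "repro_output"))
  }
  fdw <- if ("fdw_g" %in% names(mature)) mature$fdw_g
         else rep(NA_real_, nrow(mature))
  miss <- !is.finite(fdw)
  if (any(miss)) {
    if (is.null(fdw_allometry))
      stop(sum(miss), " mature individuals lack fdw_g and no allometry given")
    fdw[miss] <- predict_mass(fdw_allometry, mature$sl_mm[miss])
  }
  mass <- constants$female_fraction * constants$fecundity_fraction *
    sum(fdw) / area
  structure(list(mass_output_g_m2 = mass,
                 egg_output_m2 = eggs_from_mass(mass,
                                                constants$egg_mass_equiv_mg),
                 n_mature = nrow(mature),
                 mature_density_m2 = nrow(mature) / area),
            class = "repro_output")
}

#' @export
print.repro_output <- function(x, ...) {
  cat(sprintf("Reproductive output: %.2f g m-2 = %.3g eggs m-2 (%d mature, %.0f ind m-2)\n",
              x$mass_output_g_m2, x$egg_output_m2, x$n_mature,
              x$mature_density_m2))
  invisible(x)
}

#' Per-date spawning contrast between two shores
#'
#' Runs the G-test of independence on the spawning / non-spawning
#' counts of the two shores at every sampling date.
#'
#' @param spawning Data frame with columns `shore`, `date`,
#'   `n_spawning`, `n_non_spawning`; exactly two shores per date.
#' @return Data frame with one row per date: `G`, `p`.
#' @export
spawning_contrast <- function(spawning) {
  stopifnot(all(c("shore", "date", "n_spawning", "n_non_spawning")
                %in% names(spawning)))
  dates <- sort(unique(spawning$date))
  rows <- lapply(dates, function(d) {
    sub <- spawning[spawning$date == d, ]
    if (nrow(sub) != 2) stop("need exactly two shores at date ", d)
    tab <- as.matrix(sub[, c("n_spawning", "n_non_spawning")])
    res <- tryCatch(g_test(tab), error = function(e) list(G = NA, p = NA))
    data.frame(date = d, G = res$G, p = res$p)
  })
  do.call(rbind, rows)
}
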