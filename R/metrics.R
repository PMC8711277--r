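#' Basal area of a mussel from its shell length
#'
#' Footprint of an individual on the rock, from the biometric
#' relationship `(SL / 1.8) * (SL / 2.4) = SL^2 / 4.32`: length over
#' 1.8 approximates shell width and length over 2.4 the basal ellipse
#' minor axis.
#'
#' @param SL Shell length(s) in mm, >= 0.
#' @return Basal area in mm^2.
#' @export
#' @examples
#' basal_area(24)  # 133.33 mm^2
basal_area <- function(SL) {
  if (any(SL < 0)) stop("'SL' must be non-negative")
  (SL / 1.8) * (SL / 2.4)
}

#' Split individuals into recruits and adults
#'
#' Recruits are the individuals with shell length strictly smaller than
#' the threshold — by default 1.07 mm, the length attained one month
#' after settlement under the site-wide growth curve.
#'
#' @param SL Shell lengths (mm).
#' @param threshold_mm Recruit threshold (mm), default 1.07.
#' @return A logical vector, `TRUE` for recruits.
#' @export
is_recruit <- function(SL, threshold_mm = 1.07) {
  if (!is.numeric(threshold_mm) || threshold_mm < 0)
    stop("'threshold_mm' must be non-negative")
  SL < threshold_mm
}

#' @rdname is_recruit
#' @param individuals A data frame with an `sl_mm` column.
#' @return `classify_recruits` returns a list with `recruits` and
#'   `adults`, a disjoint exhaustive partition of the input rows.
#' @export
classify_recruits <- function(individuals, threshold_mm = 1.07) {
  rec <- is_recruit(individuals$sl_mm, threshold_mm)
  list(recruits = individuals[rec, , drop = FALSE],
       adults = individuals[!rec, , drop = FALSE])
}

# covered area of a quadrat in m^2; errors on empty cover
covered_area_m2 <- function(covered_fraction, quadrat_area_m2) {
  if (!is.finite(covered_fraction) || covered_fraction <= 0)
    stop("empty cover: covered fraction must be > 0")
  if (!is.finite(quadrat_area_m2) || quadrat_area_m2 <= 0)
    stop("'quadrat_area_m2' must be > 0")
  covered_fraction * quadrat_area_m2
}

#' Cover-standardized biomass of a quadrat
#'
#' Total biomass per square meter of mussel-covered area,
#' `sum(TWW in kg) / (CC * QA)`, where CC is the proportion of the
#' quadrat covered by the patch and QA the quadrat area. Individuals
#' without a measured total wet weight get one predicted from shell
#' length through the allometric fit.
#'
#' @param individuals Data frame with `sl_mm` and optionally `tww_g`.
#' @param covered_fraction CC, in (0, 1].
#' @param quadrat_area_m2 QA in m^2 (default 0.0625, a 25 x 25 cm
#'   quadrat).
#' @param allometry An `"allometry_fit"` used to impute missing masses;
#'   may be `NULL` when every individual carries `tww_g`.
#' @return Biomass in kg per m^2 of covered area.
#' @export
total_biomass <- function(individuals, covered_fraction,
                          quadrat_area_m2 = 0.0625, allometry = NULL) {
  area <- covered_area_m2(covered_fraction, quadrat_area_m2)
  if (nrow(individuals) == 0) return(0)
  tww <- if ("tww_g" %in% names(individuals)) individuals$tww_g
         else rep(NA_real_, nrow(individuals))
  miss <- !is.finite(tww)
  if (any(miss)) {
    if (is.null(allometry))
      stop(sum(miss), " individuals lack tww_g and no allometry was supplied")
    tww[miss] <- predict_mass(allometry, individuals$sl_mm[miss])
  }
  sum(tww) / 1000 / area
}

#' Cover-standardized density of a quadrat
#'
#' Number of individuals per square meter of mussel-covered area.
#'
#' @inheritParams total_biomass
#' @param include_recruits Keep individuals below the recruit threshold
#'   (default `TRUE`).
#' @param threshold_mm Recruit threshold (mm).
#' @return Individuals per m^2 of covered area.
#' @export
pop_density <- function(individuals, covered_fraction,
                        quadrat_area_m2 = 0.0625, include_recruits = TRUE,
                        threshold_mm = 1.07) {
  area <- covered_area_m2(covered_fraction, quadrat_area_m2)
  n <- if (include_recruits) nrow(individuals)
       else sum(!is_recruit(individuals$sl_mm, threshold_mm))
  n / area
}

#' Monthly recruit density of a quadrat
#'
#' Recruits (shell length below the threshold) per square meter of
#' covered area, attributed to the quadrat's sampling month.
#'
#' @inheritParams pop_density
#' @return Recruits per m^2 of covered area per month.
#' @export
recruit_density <- function(individuals, covered_fraction,
                            quadrat_area_m2 = 0.0625, threshold_mm = 1.07) {
  area <- covered_area_m2(covered_fraction, quadrat_area_m2)
  sum(is_recruit(individuals$sl_mm, threshold_mm)) / area
}

#' Crowding index of a mussel patch
#'
#' Degree of overlap of individuals in a monolayer aggregation: the
#' cumulative basal area of all adults divided by the observed covered
#' area. A value of 1 means the summed footprints exactly tile the
#' patch; values above 1 mean individuals overlap (tight crowding),
#' below 1 that free space remains between them. Recruits are excluded
#' — their footprint is negligible. `inverse = TRUE` returns the
#' reciprocal (observed area over summed basal area) for comparison
#' with area-ratio formulations oriented the other way.
#'
#' @param SL Adult shell lengths (mm); recruits should already be
#'   excluded (see [classify_recruits()]), but any length below
#'   `threshold_mm` is dropped defensively.
#' @param observed_area_mm2 Observed covered area of the patch, mm^2.
#' @param threshold_mm Recruit threshold (mm).
#' @param inverse Return observed / basal instead.
#' @return Dimensionless crowding index.
#' @export
crowding_index <- function(SL, observed_area_mm2, threshold_mm = 1.07,
                           inverse = FALSE) {
  if (!is.finite(observed_area_mm2) || observed_area_mm2 <= 0)
    stop("'observed_area_mm2' must be > 0")
  SL <- SL[!is_recruit(SL, threshold_mm)]
  ratio <- sum(basal_area(SL)) / observed_area_mm2
  if (inverse) 1 / ratio else ratio
}

#' Median and maximum shell length, recruits excluded
#'
#' @param SL Shell lengths (mm).
#' @param threshold_mm Recruit threshold (mm).
#' @return List with `median_mm` (midpoint convention for even sample
#'   sizes) and `max_mm`.
#' @export
size_stats <- function(SL, threshold_mm = 1.07) {
  SL <- SL[!is_recruit(SL, threshold_mm)]
  if (length(SL) == 0) stop("no adults: size statistics undefined")
  list(median_mm = stats::median(SL), max_mm = max(SL))
}

#' Per-quadrat population summary
#'
#' Computes the standardized population parameters for every quadrat:
#' density (with and without recruits), biomass, crowding index, median
#' and maximum adult length, recruit density and counts. The observed
#' covered area entering the crowding denominator is `CC * QA`
#' expressed in mm^2 unless the quadrat table carries an explicit
#' `observed_area_mm2` column (as written by the simulator, where the
#' patch area is known exactly).
#'
#' @param individuals Data frame of individual records (`quadrat_id`,
#'   `sl_mm`, optional `tww_g`, ...).
#' @param quadrats Data frame of quadrat metadata (`quadrat_id`,
#'   `shore`, `date`, `height_lat_m`, `covered_fraction`,
#'   `quadrat_area_m2`, optional `observed_area_mm2`).
#' @param allometry An `"allometry_fit"` for mass imputation, or `NULL`
#'   to fit one from the individuals carrying measured masses.
#' @param threshold_mm Recruit threshold (mm).
#' @return A data frame, one row per quadrat, with the summary fields.
#' @export
summarize_quadrats <- function(individuals, quadrats, allometry = NULL,
                               threshold_mm = 1.07) {
  stopifnot(all(c("quadrat_id", "sl_mm") %in% names(individuals)),
            all(c("quadrat_id", "covered_fraction", "quadrat_area_m2")
                %in% names(quadrats)))
  if (is.null(allometry)) {
    has_mass <- "tww_g" %in% names(individuals) &&
      sum(is.finite(individuals$tww_g) & individuals$tww_g > 0) >= 10
    if (has_mass) {
      ok <- is.finite(individuals$tww_g) & individuals$tww_g > 0
      allometry <- fit_allometry(individuals$sl_mm[ok], individuals$tww_g[ok])
    }
  }
  rows <- lapply(seq_len(nrow(quadrats)), function(i) {
    q <- quadrats[i, ]
    ind <- individuals[individuals$quadrat_id == q$quadrat_id, , drop = FALSE]
    adults <- ind[!is_recruit(ind$sl_mm, threshold_mm), , drop = FALSE]
    obs_mm2 <- if ("observed_area_mm2" %in% names(q) &&
                   is.finite(q$observed_area_mm2)) q$observed_area_mm2
               else q$covered_fraction * q$quadrat_area_m2 * 1e6
    n_imputed <- if ("tww_g" %in% names(ind)) sum(!is.finite(ind$tww_g))
                 else nrow(ind)
    data.frame(
      quadrat_id = q$quadrat_id,
      shore = if ("shore" %in% names(q)) q$shore else NA,
      date = if ("date" %in% names(q)) q$date else NA,
      height_lat_m = if ("height_lat_m" %in% names(q)) q$height_lat_m else NA,
      n_total = nrow(ind),
      n_recruits = nrow(ind) - nrow(adults),
      density = pop_density(ind, q$covered_fraction, q$quadrat_area_m2,
                            include_recruits = TRUE,
                            threshold_mm = threshold_mm),
      density_adults = pop_density(ind, q$covered_fraction, q$quadrat_area_m2,
                                   include_recruits = FALSE,
                                   threshold_mm = threshold_mm),
      biomass_kg_m2 = total_biomass(ind, q$covered_fraction, q$quadrat_area_m2,
                                    allometry = allometry),
      crowding = if (nrow(adults) > 0)
        crowding_index(adults$sl_mm, obs_mm2, threshold_mm) else NA_real_,
      median_length_mm = if (nrow(adults) > 0)
        stats::median(adults$sl_mm) else NA_real_,
      max_length_mm = if (nrow(adults) > 0) max(adults$sl_mm) else NA_real_,
      recruit_density = recruit_density(ind, q$covered_fraction,
                                        q$quadrat_area_m2, threshold_mm),
      n_mass_imputed = n_imputed,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
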