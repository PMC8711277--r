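#' Default per-shore simulation settings
#'
#' Ground-truth parameters for one shore of the individual-based
#' generator. Defaults describe a temperate rocky-shore mussel
#' population: seasonal von Bertalanffy growth, height-dependent
#' exponential mortality (log-linear in intertidal height), bimodal
#' seasonal recruitment (spring and early-autumn pulses), power-law
#' length-mass allometry with multiplicative noise, and monolayer
#' aggregation at a target crowding level.
#'
#' @param growth A [growth_params()] object.
#' @param growth_cv Lognormal coefficient of variation of individual
#'   asymptotic length (growth variability acts on `Linf` only, so the
#'   mean curve remains invertible for ageing).
#' @param mortality_intercept,mortality_height_slope Coefficients of
#'   `log(Z) = intercept + slope * height`, Z in 1/yr, height in m
#'   above LAT.
#' @param recruitment_schedule Twelve monthly expected recruit counts
#'   per quadrat patch (January..December). The default is two Gaussian
#'   pulses centred on April and September.
#' @param allometry_a,allometry_b,allometry_cv Power-law total wet
#'   weight `a * SL^b` (g, mm) and lognormal noise CV.
#' @param fww_fraction,fdw_fraction Flesh wet / flesh dry weight as
#'   fractions of total wet weight.
#' @param crowding_target Crowding index the generator realises
#'   exactly: the observed patch area is set to the summed adult basal
#'   area divided by this value.
#' @param quadrat_heights Intertidal heights (m above LAT) of the
#'   quadrats sampled on each date; length gives quadrats per date.
#' @param covered_fraction_fallback Covered fraction used when a
#'   quadrat holds no adults (degenerate patch).
#' @param spawning_phase Fraction of year when the spawning probability
#'   peaks (shifts the seasonal logistic; shores can differ).
#' @return A list of shore settings.
#' @export
shore_config <- function(growth = growth_params(Linf = 65.25, K = 0.12,
                                                t0 = 0.52, C = 0.42,
                                                ts = 0.56),
                         growth_cv = 0.05,
                         mortality_intercept = -1.73,
                         mortality_height_slope = 0.3,
                         recruitment_schedule = default_recruitment_schedule(),
                         allometry_a = 1.2e-4, allometry_b = 3.0,
                         allometry_cv = 0.05,
                         fww_fraction = 0.35, fdw_fraction = 0.15,
                         crowding_target = 1.5,
                         quadrat_heights = c(3.8, 4.3, 4.8),
                         covered_fraction_fallback = 0.5,
                         spawning_phase = 0.35) {
  stopifnot(length(recruitment_schedule) == 12,
            all(recruitment_schedule >= 0), crowding_target > 0,
            growth_cv >= 0, allometry_a > 0, allometry_cv >= 0,
            fdw_fraction <= fww_fraction, fww_fraction <= 1)
  list(growth = as_growth_params(growth), growth_cv = growth_cv,
       mortality_intercept = mortality_intercept,
       mortality_height_slope = mortality_height_slope,
       recruitment_schedule = recruitment_schedule,
       allometry_a = allometry_a, allometry_b = allometry_b,
       allometry_cv = allometry_cv,
       fww_fraction = fww_fraction, fdw_fraction = fdw_fraction,
       crowding_target = crowding_target,
       quadrat_heights = quadrat_heights,
       covered_fraction_fallback = covered_fraction_fallback,
       spawning_phase = spawning_phase)
}

#' @rdname shore_config
#' @param total Expected recruits per quadrat per year.
#' @param centers Pulse centres as month numbers (April, September).
#' @param sd Pulse width in months.
#' @export
default_recruitment_schedule <- function(total = 300, centers = c(4, 9),
                                         sd = 1) {
  m <- 1:12
  w <- rowSums(vapply(centers, function(cc) exp(-(m - cc)^2 / (2 * sd^2)),
                      numeric(12)))
  total * w / sum(w)
}

#' Full simulation configuration
#'
#' @param shores Named list of [shore_config()] lists; the defaults
#'   mirror a two-shore design with distinct growth, mortality and
#'   spawning-phenology truths.
#' @param sample_dates Sampling times as decimal years; default twelve
#'   monthly samples from March 2019 to February 2020.
#' @param max_age Oldest simulated age in years (default 11, the
#'   observed longevity).
#' @param quadrat_area_m2 Quadrat area (default 0.0625 m^2).
#' @param tide List of tide-series settings passed to
#'   [simulate_tides()].
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(shores = NULL,
                              sample_dates = 2019 + (2:13 + 0.5) / 12,
                              max_age = 11,
                              quadrat_area_m2 = 0.0625,
                              tide = list(years = 5, amplitudes = c(2.0, 0.6),
                                          periods_h = c(12.42, 12.00),
                                          mean_level = 4, start_year = 2015)) {
  if (is.null(shores)) {
    shores <- list(
      West = shore_config(),
      East = shore_config(
        growth = growth_params(Linf = 62.54, K = 0.19, t0 = 0.67,
                               C = 0.51, ts = 0.5),
        mortality_intercept = -1.37,
        spawning_phase = 0.45))
  }
  stopifnot(length(sample_dates) >= 1, max_age > 0, quadrat_area_m2 > 0)
  structure(list(shores = shores, sample_dates = sort(sample_dates),
                 max_age = max_age, quadrat_area_m2 = quadrat_area_m2,
                 tide = tide),
            class = "sim_config")
}

# decimal year <-> ISO date (365-day civil year approximation,
# deterministic both ways)
dec_to_iso <- function(t) {
  yr <- floor(t)
  as.character(as.Date(paste0(yr, "-01-01")) + floor((t - yr) * 365))
}
iso_to_dec <- function(iso) {
  d <- as.Date(iso)
  yr <- as.integer(format(d, "%Y"))
  yr + as.numeric(d - as.Date(paste0(yr, "-01-01"))) / 365
}

# independent substream per quadrat: adding quadrats, dates or shores
# never perturbs the draws of existing ones
quadrat_seed <- function(seed, shore_i, date_i, quad_i) {
  (seed %% 100000L) * 10007L + shore_i * 1009L + date_i * 101L + quad_i
}

#' Simulate a two-shore mussel population survey
#'
#' Individual-based generation in the field-data schema. Per quadrat
#' and date: monthly cohorts are drawn over a burn-in of `max_age`
#' years from the shore's recruitment schedule (Poisson counts, birth
#' times uniform within the month); each individual survives to the
#' sampling date with probability `exp(-Z * age)` where
#' `log(Z) = intercept + slope * height`; lengths follow the seasonal
#' von Bertalanffy curve anchored at the individual's birth time with
#' individual lognormal `Linf`; masses follow the power-law allometry
#' with multiplicative noise; flesh wet/dry weights are fixed fractions
#' of total wet weight; sex is Bernoulli(1/2) and spawning stage (for
#' individuals above 12 mm) follows a seasonal logistic with a
#' shore-specific phase. The observed patch area is set to the summed
#' adult basal area divided by the shore's crowding target, so the
#' realised crowding index is exact by construction.
#'
#' @param config A [simulation_config()].
#' @param seed Integer root seed; the full dataset is deterministic
#'   given `(config, seed)` and every quadrat has its own substream.
#' @return An object of class `"shorepop_sim"`: list with data frames
#'   `quadrats`, `individuals`, `tides`, and `truth` (per-quadrat
#'   realised Z, expected and realised recruit counts, plus the
#'   configured ground truth).
#' @export
simulate_population <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  qrows <- list(); irows <- list(); trows <- list()
  for (si in seq_along(config$shores)) {
    shore <- names(config$shores)[si]
    sc <- config$shores[[si]]
    gp <- sc$growth
    sdlog_linf <- sqrt(log(1 + sc$growth_cv^2))
    sdlog_mass <- sqrt(log(1 + sc$allometry_cv^2))
    for (di in seq_along(config$sample_dates)) {
      d <- config$sample_dates[di]
      for (ki in seq_along(sc$quadrat_heights)) {
        h <- sc$quadrat_heights[ki]
        set.seed(quadrat_seed(seed, si, di, ki))
        z <- exp(sc$mortality_intercept + sc$mortality_height_slope * h)
        expected_n <- sum(sc$recruitment_schedule) *
          sum(exp(-z * (seq_len(ceiling(config$max_age)) - 0.5)))
        if (expected_n < 1)
          warning("near-extinct configuration for quadrat at height ", h)
        qid <- sprintf("%s_%s_q%d", shore, dec_to_iso(d), ki)

        # monthly cohorts over the burn-in window
        month_starts <- seq(from = d - config$max_age, to = d - 1e-9,
                            by = 1 / 12)
        sl <- numeric(0); ages <- numeric(0)
        n_expected_recruits <- 0
        for (ms in month_starts) {
          mon <- floor((ms - floor(ms)) * 12 + 1e-9) + 1L
          lam <- sc$recruitment_schedule[min(mon, 12L)]
          n0 <- stats::rpois(1, lam)
          if (n0 == 0) next
          tb <- ms + stats::runif(n0) / 12
          a <- d - tb
          keep <- a > 0 & stats::runif(n0) < exp(-z * a)
          if (!any(keep)) next
          tb <- tb[keep]; a <- a[keep]
          linf_i <- gp$Linf * stats::rlnorm(length(tb),
                                            -sdlog_linf^2 / 2, sdlog_linf)
          st <- gp$C * gp$K / (2 * pi) * sin(2 * pi * (d - gp$ts))
          stb <- gp$C * gp$K / (2 * pi) * sin(2 * pi * (tb - gp$ts))
          li <- linf_i * (1 - exp(-gp$K * (d - tb) + st - stb))
          pos <- li > 0
          sl <- c(sl, li[pos]); ages <- c(ages, a[pos])
        }
        n <- length(sl)
        if (n == 0) {
          qrows[[length(qrows) + 1L]] <- data.frame(
            quadrat_id = qid, shore = shore, date = dec_to_iso(d),
            height_lat_m = h,
            covered_fraction = sc$covered_fraction_fallback,
            quadrat_area_m2 = config$quadrat_area_m2,
            observed_area_mm2 = sc$covered_fraction_fallback *
              config$quadrat_area_m2 * 1e6,
            stringsAsFactors = FALSE)
          trows[[length(trows) + 1L]] <- data.frame(
            quadrat_id = qid, shore = shore, height_lat_m = h,
            Z_true = z, n_individuals = 0L, n_recruits = 0L,
            stringsAsFactors = FALSE)
          next
        }
        tww <- sc$allometry_a * sl^sc$allometry_b *
          stats::rlnorm(n, -sdlog_mass^2 / 2, sdlog_mass)
        fww <- sc$fww_fraction * tww
        fdw <- sc$fdw_fraction * tww
        sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
        p_spawn <- stats::plogis(
          2 * cos(2 * pi * ((d - floor(d)) - sc$spawning_phase)))
        stage <- ifelse(sl > 12,
                        ifelse(stats::runif(n) < p_spawn,
                               "spawning", "non-spawning"),
                        "unknown")
        adult <- !is_recruit(sl)
        obs_mm2 <- if (any(adult))
          sum(basal_area(sl[adult])) / sc$crowding_target
        else sc$covered_fraction_fallback * config$quadrat_area_m2 * 1e6
        cc <- min(obs_mm2 / (config$quadrat_area_m2 * 1e6), 1)

        qrows[[length(qrows) + 1L]] <- data.frame(
          quadrat_id = qid, shore = shore, date = dec_to_iso(d),
          height_lat_m = h, covered_fraction = cc,
          quadrat_area_m2 = config$quadrat_area_m2,
          observed_area_mm2 = obs_mm2, stringsAsFactors = FALSE)
        irows[[length(irows) + 1L]] <- data.frame(
          quadrat_id = qid, sl_mm = sl, tww_g = tww, fww_g = fww,
          fdw_g = fdw, sex = sex, stage = stage,
          age_true = ages, stringsAsFactors = FALSE)
        trows[[length(trows) + 1L]] <- data.frame(
          quadrat_id = qid, shore = shore, height_lat_m = h,
          Z_true = z, n_individuals = n,
          n_recruits = sum(!adult), stringsAsFactors = FALSE)
      }
    }
  }
  tide_args <- config$tide
  tide_args$seed <- seed
  tides <- do.call(simulate_tides, tide_args)
  truth_shores <- lapply(config$shores, function(sc) {
    c(unclass(sc["growth"])$growth,
      sc[setdiff(names(sc), "growth")])
  })
  structure(list(quadrats = do.call(rbind, qrows),
                 individuals = do.call(rbind, irows),
                 tides = tides,
                 truth = list(seed = seed, shores = truth_shores,
                              max_age = config$max_age,
                              quadrats = do.call(rbind, trows))),
            class = "shorepop_sim")
}

#' @export
print.shorepop_sim <- function(x, ...) {
  cat(sprintf("Simulated survey: %d quadrats, %d individuals, %d tide records\n",
              nrow(x$quadrats), nrow(x$individuals), nrow(x$tides)))
  invisible(x)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Emits `individuals.csv`, `quadrats.csv`, `tides.csv` and
#' `truth.json` in the schemas the reader functions expect; reading the
#' directory back reproduces the in-memory tables, and writing again
#' produces byte-identical files.
#'
#' @param dataset A `"shorepop_sim"` object.
#' @param dir Output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset`
#'   returns a `"shorepop_sim"` object.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  utils::write.csv(dataset$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$quadrats, file.path(dir, "quadrats.csv"),
                   row.names = FALSE)
  t0_year <- floor(min(dataset$tides$time))
  tides <- data.frame(
    timestamp = format(as.POSIXct(paste0(t0_year, "-01-01 00:00:00"),
                                  tz = "UTC") +
                         round((dataset$tides$time -
                                  min(dataset$tides$time)) * 8766) * 3600,
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    height_m_lat = dataset$tides$height_m,
    time_dec = dataset$tides$time)
  utils::write.csv(tides, file.path(dir, "tides.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, c("individuals.csv", "quadrats.csv", "tides.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing dataset files: ", paste(miss, collapse = ", "))
  tides_df <- utils::read.csv(file.path(dir, "tides.csv"))
  tides <- structure(data.frame(time = tides_df$time_dec,
                                height_m = tides_df$height_m_lat),
                     class = c("tide_series", "data.frame"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(quadrats = utils::read.csv(file.path(dir, "quadrats.csv"),
                                            stringsAsFactors = FALSE),
                 individuals = utils::read.csv(file.path(dir, "individuals.csv"),
                                               stringsAsFactors = FALSE),
                 tides = tides, truth = truth),
            class = "shorepop_sim")
}
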