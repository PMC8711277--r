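# shared fixtures, all generated in code

iso_dates_to_dec <- function(iso) {
  vapply(iso, function(d) {
    y <- as.integer(substr(d, 1, 4))
    y + as.numeric(as.Date(d) - as.Date(paste0(y, "-01-01"))) / 365
  }, numeric(1), USE.NAMES = FALSE)
}

# small single-shore survey used by several suites
small_survey <- function(seed = 1, n_dates = 4, total = 120) {
  cfg <- simulation_config(
    shores = list(S = shore_config(
      growth = growth_params(Linf = 60, K = 0.3, t0 = 0.5, C = 0.2, ts = 0.5),
      recruitment_schedule = default_recruitment_schedule(total = total),
      quadrat_heights = c(3.8, 4.6))),
    sample_dates = 2019 + (seq_len(n_dates) + 2.5) / 12,
    tide = list(years = 1, amplitudes = c(2.0, 0.6),
                periods_h = c(12.42, 12.00), mean_level = 4,
                start_year = 2019))
  simulate_population(cfg, seed = seed)
}

# single-pulse recovery configuration: cohorts anchored like the soVBGF
recovery_config <- function(Linf = 65, K = 0.12, C = 0.4, ts = 0.5,
                            total = 330) {
  simulation_config(
    shores = list(S = shore_config(
      growth = growth_params(Linf = Linf, K = K, t0 = 0.5, C = C, ts = ts),
      recruitment_schedule = default_recruitment_schedule(total = total,
                                                          centers = 7, sd = 1),
      quadrat_heights = 4.3)),
    sample_dates = 2019 + (2:13 + 0.5) / 12)
}

# assemble an lfq object from an explicit count matrix
make_lfq <- function(counts, dates, bin_lower = NULL, width = 1) {
  counts <- as.matrix(counts)
  if (is.null(bin_lower)) bin_lower <- seq_len(nrow(counts))
  structure(list(midLengths = bin_lower + width / 2, bin_lower = bin_lower,
                 bin_width = width, dates = dates, catch = counts),
            class = "lfq")
}

sim_lfq <- function(sim, bin_width = 1) {
  ind <- merge(sim$individuals, sim$quadrats[, c("quadrat_id", "date")])
  build_lfq(ind$sl_mm, iso_dates_to_dec(ind$date), bin_width = bin_width)
}
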