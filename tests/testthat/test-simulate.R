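test_that("simulation is deterministic and quadrat substreams are stable", {
  cfg <- simulation_config(
    shores = list(S = shore_config(quadrat_heights = c(3.8, 4.6))),
    sample_dates = 2019 + (3:4 + 0.5) / 12)
  a <- simulate_population(cfg, seed = 7)
  b <- simulate_population(cfg, seed = 7)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$quadrats, b$quadrats)
  # adding a quadrat leaves the existing quadrats' draws untouched
  cfg3 <- simulation_config(
    shores = list(S = shore_config(quadrat_heights = c(3.8, 4.6, 5.0))),
    sample_dates = 2019 + (3:4 + 0.5) / 12)
  c3 <- simulate_population(cfg3, seed = 7)
  shared <- c3$individuals[c3$individuals$quadrat_id %in%
                             a$quadrats$quadrat_id, ]
  rownames(shared) <- NULL
  rownames(a$individuals) <- NULL
  expect_equal(a$individuals, shared)
})

test_that("the generator realises the configured crowding exactly", {
  sim <- small_survey(seed = 12)
  summ <- summarize_quadrats(sim$individuals, sim$quadrats)
  expect_equal(summ$crowding, rep(1.5, nrow(summ)), tolerance = 1e-12)
  # and a different target propagates
  cfg <- simulation_config(
    shores = list(S = shore_config(crowding_target = 0.8,
                                   quadrat_heights = 4.2)),
    sample_dates = 2019.5)
  sim2 <- simulate_population(cfg, seed = 2)
  summ2 <- summarize_quadrats(sim2$individuals, sim2$quadrats)
  expect_equal(summ2$crowding, rep(0.8, nrow(summ2)), tolerance = 1e-12)
})

test_that("realised age structure decays at the configured mortality", {
  # one tall quadrat with a known Z; pool many monthly cohorts
  z_target <- 0.7
  h <- 4.0
  cfg <- simulation_config(
    shores = list(S = shore_config(
      mortality_intercept = log(z_target) - 0.3 * h,
      mortality_height_slope = 0.3,
      recruitment_schedule = rep(500, 12),
      quadrat_heights = h)),
    sample_dates = c(2019.25, 2019.5, 2019.75))
  sim <- simulate_population(cfg, seed = 3)
  expect_equal(unique(round(sim$truth$quadrats$Z_true, 10)),
               round(z_target, 10))
  expect_gt(nrow(sim$individuals), 5000)
  st <- age_structure_from_ages(sim$individuals$age_true)
  fit <- fit_mortality(st)
  expect_lt(abs(fit$Z - z_target) / z_target, 0.10)
})

test_that("dataset write/read/write round trip is byte-identical", {
  sim <- small_survey(seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(sim, d1)
  back <- read_dataset(d1)
  expect_equal(nrow(back$individuals), nrow(sim$individuals))
  expect_equal(nrow(back$quadrats), nrow(sim$quadrats))
  expect_equal(back$individuals$sl_mm, sim$individuals$sl_mm)
  write_dataset(back, d2)
  for (f in c("individuals.csv", "quadrats.csv", "tides.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true(file.exists(file.path(d1, "truth.json")))
  expect_equal(back$truth$seed, 13)
})

test_that("every individual references an existing quadrat", {
  sim <- small_survey(seed = 14)
  expect_true(all(sim$individuals$quadrat_id %in% sim$quadrats$quadrat_id))
  expect_true(all(sim$individuals$sl_mm > 0))
  with_mass <- is.finite(sim$individuals$tww_g)
  expect_true(all(sim$individuals$fdw_g[with_mass] <=
                    sim$individuals$fww_g[with_mass]))
  expect_true(all(sim$individuals$fww_g[with_mass] <=
                    sim$individuals$tww_g[with_mass]))
})

test_that("a near-extinct configuration warns instead of failing", {
  cfg <- simulation_config(
    shores = list(S = shore_config(
      recruitment_schedule = rep(0.001, 12),
      mortality_intercept = 1.5, quadrat_heights = 5.0)),
    sample_dates = 2019.5)
  expect_warning(simulate_population(cfg, seed = 1), "extinct")
})
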