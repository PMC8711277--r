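test_that("allometry fit recovers exact power-law data", {
  sl <- seq(5, 60, length.out = 50)
  fit <- fit_allometry(sl, 1e-5 * sl^3)
  expect_equal(fit$a, 1e-5, tolerance = 1e-8)
  expect_equal(fit$b, 3, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-10)
})

test_that("allometry fit handles noise and rejects degenerate designs", {
  set.seed(21)
  res <- replicate(20, {
    sl <- runif(720, 3, 60)
    tww <- 1e-5 * sl^3 * rlnorm(720, 0, sqrt(log(1 + 0.05^2)))
    fit <- fit_allometry(sl, tww)
    c(fit$a, fit$b)
  })
  expect_lt(abs(median(res[1, ]) - 1e-5) / 1e-5, 0.15)
  expect_lt(abs(median(res[2, ]) - 3) / 3, 0.02)
  expect_error(fit_allometry(rep(20, 50), rep(0.1, 50)), "unidentifiable")
  expect_error(fit_allometry(1:5, (1:5)^3), "at least 10")
})

test_that("mass prediction follows the power law", {
  fit <- list(a = 1e-5, b = 3)
  expect_equal(predict_mass(fit, 10), 0.01)
  expect_equal(predict_mass(fit, 0), 0)
  expect_equal(predict_mass(fit, 20) / predict_mass(fit, 10), 8)
})

test_that("biomass standardization divides by the covered area", {
  ind <- data.frame(sl_mm = rep(30, 5), tww_g = rep(100, 5))  # 0.5 kg
  expect_equal(total_biomass(ind, covered_fraction = 0.5), 16)
  expect_equal(total_biomass(ind, 0.25), 32)  # halving CC doubles biomass
  empty <- data.frame(sl_mm = numeric(0), tww_g = numeric(0))
  expect_equal(total_biomass(empty, 0.5), 0)
  expect_error(total_biomass(ind, 0), "cover")
  # missing masses are imputed through the allometry
  ind2 <- data.frame(sl_mm = c(30, 30), tww_g = c(NA, 100))
  fit <- list(a = 100 / 30^3, b = 3)
  expect_equal(total_biomass(ind2, 1, 1, allometry = fit), 0.2)
})

test_that("density standardization and the recruit filter agree", {
  ind <- data.frame(sl_mm = c(rep(20, 95), rep(0.5, 5)))
  expect_equal(pop_density(ind, 1), 100 / 0.0625)
  expect_equal(pop_density(ind, 1, include_recruits = FALSE), 95 / 0.0625)
  expect_equal(recruit_density(ind, 1),
               pop_density(ind, 1) - pop_density(ind, 1,
                                                 include_recruits = FALSE))
  expect_equal(recruit_density(data.frame(sl_mm = rep(0.5, 5)), 0.8), 100)
  expect_equal(pop_density(data.frame(sl_mm = numeric(0)), 1), 0)
  expect_error(pop_density(ind, 0), "cover")
})

test_that("basal area is the frozen biometric quadratic", {
  expect_equal(basal_area(0), 0)
  expect_equal(basal_area(24), (24 / 1.8) * (24 / 2.4))
  expect_equal(basal_area(24), 24^2 / 4.32)
  expect_equal(basal_area(48) / basal_area(24), 4)
  expect_error(basal_area(-1), "non-negative")
})

test_that("crowding index matches its defining ratio and excludes recruits", {
  sl <- c(20, 25, 30)
  obs <- sum(basal_area(sl))
  expect_equal(crowding_index(sl, obs), 1)
  expect_equal(crowding_index(sl, obs / 1.5), 1.5)
  # recruits do not contribute
  expect_equal(crowding_index(c(sl, 0.9), obs), 1)
  # inverse orientation
  expect_equal(crowding_index(sl, obs / 1.5, inverse = TRUE), 1 / 1.5)
  # scale consistency: s x lengths -> s^2 x index
  expect_equal(crowding_index(3 * sl, obs), 9)
  expect_error(crowding_index(sl, 0), "observed_area")
})

test_that("recruit classification is strict and exhaustive", {
  ind <- data.frame(sl_mm = c(1.06, 1.07, 0.2, 40))
  parts <- classify_recruits(ind)
  expect_equal(parts$recruits$sl_mm, c(1.06, 0.2))
  expect_equal(parts$adults$sl_mm, c(1.07, 40))
  expect_equal(nrow(parts$recruits) + nrow(parts$adults), nrow(ind))
  none <- classify_recruits(ind[0, , drop = FALSE])
  expect_equal(nrow(none$recruits), 0)
  expect_equal(nrow(none$adults), 0)
  expect_equal(sum(is_recruit(ind$sl_mm, threshold_mm = 0)), 0)
})

test_that("size statistics use the midpoint median and exclude recruits", {
  expect_equal(size_stats(c(10, 20, 30)), list(median_mm = 20, max_mm = 30))
  expect_equal(size_stats(c(10, 20, 30, 40)),
               list(median_mm = 25, max_mm = 40))
  s <- size_stats(c(0.5, 10, 20))  # recruit dropped
  expect_equal(s$median_mm, 15)
  expect_error(size_stats(c(0.5, 0.9)), "no adults")
})

test_that("per-quadrat summaries agree with the individual metrics", {
  sim <- small_survey(seed = 9)
  summ <- summarize_quadrats(sim$individuals, sim$quadrats)
  expect_equal(nrow(summ), nrow(sim$quadrats))
  q1 <- sim$quadrats$quadrat_id[1]
  ind1 <- sim$individuals[sim$individuals$quadrat_id == q1, ]
  expect_equal(summ$n_total[1], nrow(ind1))
  expect_equal(summ$density[1],
               pop_density(ind1, sim$quadrats$covered_fraction[1],
                           sim$quadrats$quadrat_area_m2[1]))
  expect_true(all(summ$median_length_mm <= summ$max_length_mm, na.rm = TRUE))
  expect_true(all(summ$density >= summ$density_adults))
  expect_true(all(summ$crowding > 0, na.rm = TRUE))
})
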