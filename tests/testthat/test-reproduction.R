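test_that("condition index scales cubically with length", {
  expect_equal(condition_index(0, 30), 0)
  expect_equal(condition_index(0.432, 30), 0.432 / 27000)
  expect_equal(condition_index(1, 10) / condition_index(1, 20), 8)
  expect_error(condition_index(0.1, 0), "SL")
})

test_that("G-test matches the likelihood-ratio closed form", {
  perfect <- g_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(perfect$G, 0)
  expect_equal(perfect$p, 1)
  tab <- matrix(c(8, 3, 2, 7), 2)  # rows (8,2) and (3,7)
  res <- g_test(tab)
  # direct evaluation of 2 * sum(O log(O/E))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$G, 2 * sum(tab * log(tab / E)), tolerance = 1e-12)
  expect_equal(res$G, 5.30, tolerance = 1e-3)
  expect_equal(round(res$p, 3), 0.021)
  # swapping rows leaves G unchanged
  expect_equal(g_test(tab[2:1, ])$G, res$G)
  expect_error(g_test(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)), "marginal")
})

test_that("G approaches the Pearson statistic near independence", {
  # independent cross-check: chisq.test without continuity correction
  base <- 1000
  for (eps in c(50, 10, 1)) {
    tab <- matrix(c(base + eps, base - eps, base - eps, base + eps), 2)
    G <- g_test(tab)$G
    X2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(G, unname(X2), tolerance = 1e-2 * max(G, 1e-6))
  }
})

test_that("G-test type-I error is controlled under equal spawning rates", {
  set.seed(41)
  n <- 1000
  rej <- replicate(n, {
    a <- rbinom(1, 10, 0.5); b <- rbinom(1, 10, 0.5)
    tab <- matrix(c(a, 10 - a, b, 10 - b), 2, byrow = TRUE)
    ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (ok) g_test(tab)$p < 0.05 else NA
  })
  rate <- mean(rej, na.rm = TRUE)
  # alpha plus two Monte-Carlo standard errors
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / sum(!is.na(rej))))
})

test_that("sex-ratio chi-square follows the 1:1 closed form", {
  even <- sex_ratio_test(50, 50)
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  expect_equal(sex_ratio_test(60, 40)$chi2, 4)
  expect_equal(sex_ratio_test(60, 40)$chi2, sex_ratio_test(40, 60)$chi2)
  # cross-check against the stock goodness-of-fit test
  ref <- stats::chisq.test(c(60, 40), p = c(0.5, 0.5))
  expect_equal(sex_ratio_test(60, 40)$chi2, unname(ref$statistic))
  expect_error(sex_ratio_test(0, 0), "sexed")
})

test_that("egg conversion is the linear mass equivalence", {
  expect_equal(eggs_from_mass(0.0525), 1e6)
  expect_equal(signif(eggs_from_mass(112.92), 3), 2.15e9)
  expect_equal(signif(eggs_from_mass(106.5), 3), 2.03e9)
  x <- c(0.3, 1.7); expect_equal(eggs_from_mass(sum(x)),
                                 sum(eggs_from_mass(x)))
  expect_error(eggs_from_mass(-1), "non-negative")
})

test_that("reproductive output counts only mature individuals", {
  one <- data.frame(sl_mm = 20, fdw_g = 1)
  out <- reproductive_output(one, covered_fraction = 1, quadrat_area_m2 = 1)
  expect_equal(out$mass_output_g_m2, 0.14)  # 0.5 * 0.28 * 1 g / 1 m2
  expect_equal(out$egg_output_m2, eggs_from_mass(0.14))
  expect_equal(out$n_mature, 1)
  # at the maturity boundary the comparison is strict
  at12 <- data.frame(sl_mm = 12, fdw_g = 1)
  expect_equal(reproductive_output(at12, 1, 1)$mass_output_g_m2, 0)
  small <- data.frame(sl_mm = c(5, 11.9), fdw_g = c(1, 1))
  expect_equal(reproductive_output(small, 1, 1)$egg_output_m2, 0)
  expect_error(reproductive_output(one, 0, 1), "cover")
})

test_that("reproductive output is monotone in flesh mass and mature set", {
  base <- data.frame(sl_mm = c(20, 30), fdw_g = c(1, 2))
  o1 <- reproductive_output(base, 1, 1)
  heavier <- base; heavier$fdw_g[1] <- 2
  expect_gt(reproductive_output(heavier, 1, 1)$mass_output_g_m2,
            o1$mass_output_g_m2)
  more <- rbind(base, data.frame(sl_mm = 25, fdw_g = 1))
  expect_gt(reproductive_output(more, 1, 1)$mass_output_g_m2,
            o1$mass_output_g_m2)
  # missing FDW falls back to the dry-mass allometry
  fdw_fit <- list(a = 1e-6, b = 3)
  mixed <- data.frame(sl_mm = c(20, 30), fdw_g = c(NA, 2))
  out <- reproductive_output(mixed, 1, 1, fdw_allometry = fdw_fit)
  expect_equal(out$mass_output_g_m2,
               0.5 * 0.28 * (1e-6 * 20^3 + 2))
})

test_that("per-date spawning contrasts run one G-test per date", {
  sp <- data.frame(shore = rep(c("W", "E"), 3),
                   date = rep(c("2019-04-15", "2019-05-15", "2019-06-15"),
                              each = 2),
                   n_spawning = c(8, 3, 5, 5, 2, 9),
                   n_non_spawning = c(2, 7, 5, 5, 8, 1))
  res <- spawning_contrast(sp)
  expect_equal(nrow(res), 3)
  expect_equal(res$G[1], g_test(matrix(c(8, 3, 2, 7), 2))$G)
  expect_equal(res$G[2], 0)
})
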