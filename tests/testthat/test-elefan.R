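# fabricate a restructured object with explicit scores
fake_restructured <- function(scores, dates, bin_lower = NULL, width = 1) {
  lfq <- make_lfq(matrix(0L, nrow(as.matrix(scores)), length(dates)),
                  dates, bin_lower, width)
  out <- unclass(lfq)
  out$rcounts <- as.matrix(scores)
  out$ma <- 3
  out$peak_runs <- apply(out$rcounts, 2, function(s) {
    pos <- which(s > 0)
    if (!length(pos)) {
      return(data.frame(start = integer(0), end = integer(0),
                        max_score = numeric(0)))
    }
    grp <- cumsum(c(1, diff(pos) > 1))
    do.call(rbind, lapply(split(pos, grp), function(ix)
      data.frame(start = min(ix), end = max(ix), max_score = max(s[ix]))))
  }, simplify = FALSE)
  structure(out, class = c("lfq_restructured", "lfq"))
}

test_that("a curve threading every single-bin peak scores exactly 1", {
  p <- growth_params(Linf = 60, K = 0.5, t0 = 0)
  dates <- c(2019.0, 2019.5)
  nbin <- 60
  scores <- matrix(0, nbin, 2)
  for (j in 1:2) {
    ages <- dates[j] - (2014:2018)   # cohorts well inside (0, max_age]
    bins <- floor(sovbgf_length(p, ages)) + 1
    scores[unique(bins), j] <- 1
  }
  rs <- fake_restructured(scores, dates, bin_lower = 0:(nbin - 1))
  expect_equal(score_growth_curve(p, rs), 1)
})

test_that("a curve missing the observed range scores non-positive", {
  scores <- matrix(c(-0.2, 1, -0.2, 0, 0), ncol = 1)
  rs <- fake_restructured(scores, dates = 2019.5, bin_lower = 100:104)
  # cohorts of this curve never reach lengths 100-105 within max age
  p <- growth_params(Linf = 60, K = 0.2, t0 = 0)
  expect_lte(score_growth_curve(p, rs), 0)
})

test_that("scoring matches a brute-force enumeration oracle on a toy LFQ", {
  set.seed(11)
  dates <- c(2019.2, 2019.6, 2020.0)
  nbin <- 25
  scores <- matrix(round(runif(nbin * 3, -1, 1), 2), nbin, 3)
  rs <- fake_restructured(scores, dates, bin_lower = 0:(nbin - 1))
  cand <- list(growth_params(24, 0.35, t0 = 0.3, C = 0.3, ts = 0.6),
               growth_params(30, 0.15, t0 = 0.7),
               growth_params(20, 0.8, t0 = 0.05, C = 1, ts = 0.1))
  # independent oracle: literal enumeration of cohorts, crossings and
  # the once-per-run-per-date credit rule
  oracle <- function(p, rs, max_age = 11) {
    runs <- rs$peak_runs
    asp <- sum(vapply(runs, function(r) sum(r$max_score), numeric(1)))
    esp <- 0
    for (j in seq_along(rs$dates)) {
      d <- rs$dates[j]
      crossed <- integer(0)
      for (y in (floor(min(rs$dates)) - 12):floor(max(rs$dates))) {
        age <- d - (y + p$t0)
        if (age <= 0 || age > max_age) next
        L <- sovbgf_length(p, d - y)
        b <- which(L >= rs$bin_lower & L < rs$bin_lower + rs$bin_width)
        if (length(b)) crossed <- union(crossed, b)
      }
      run_credit <- rep(-Inf, nrow(runs[[j]]))
      for (b in crossed) {
        s <- rs$rcounts[b, j]
        if (s < 0) esp <- esp + s
        if (s > 0) {
          k <- which(runs[[j]]$start <= b & runs[[j]]$end >= b)
          run_credit[k] <- max(run_credit[k], s)
        }
      }
      esp <- esp + sum(run_credit[is.finite(run_credit)])
    }
    esp / asp
  }
  for (p in cand)
    expect_equal(score_growth_curve(p, rs), oracle(p, rs), tolerance = 1e-12)
})

test_that("an all-negative restructuring is rejected as degenerate", {
  rs <- fake_restructured(matrix(c(-1, -0.5, 0, -0.2), ncol = 1),
                          dates = 2019.5)
  expect_error(score_growth_curve(growth_params(10, 0.5), rs), "degenerate")
})

test_that("the GA is deterministic given a seed and respects elitism", {
  sim <- small_survey(seed = 5)
  lfq <- sim_lfq(sim)
  ctrl <- list(pop_size = 15, generations = 20, stagnation = 8)
  f1 <- elefan_ga(lfq, ma = 5, n_boot = 3, seed = 99, control = ctrl)
  f2 <- elefan_ga(lfq, ma = 5, n_boot = 3, seed = 99, control = ctrl)
  expect_identical(f1, f2)
  # monotone best-score trace
  expect_true(all(diff(f1$trace) >= 0))
  # returned params live inside the search space
  sp <- f1$search_space
  expect_gte(f1$params$Linf, sp$Linf[1]); expect_lte(f1$params$Linf, sp$Linf[2])
  expect_gte(f1$params$K, sp$K[1]);       expect_lte(f1$params$K, sp$K[2])
  # phi-prime consistency
  expect_equal(f1$phi_prime, phi_prime(f1$params$K, f1$params$Linf))
  # bootstrap output shape
  expect_equal(nrow(f1$bootstrap_params), 3)
  ci <- elefan_boot_ci(f1)
  expect_equal(dim(ci), c(3, 5))
})

test_that("a point search space returns that point with its score", {
  sim <- small_survey(seed = 6)
  lfq <- sim_lfq(sim)
  sp <- elefan_search_space(Linf = c(60, 60), K = c(0.3, 0.3),
                            t0 = c(0.5, 0.5), C = c(0.2, 0.2),
                            ts = c(0.5, 0.5))
  fit <- elefan_ga(lfq, search_space = sp, ma = 5, n_boot = 0, seed = 1,
                   control = list(pop_size = 8, generations = 5,
                                  stagnation = 3))
  expect_equal(fit$params$Linf, 60)
  expect_equal(fit$params$K, 0.3)
  rs <- restructure_lfq(lfq, ma = 5)
  expect_equal(fit$score, score_growth_curve(fit$params, rs))
})

test_that("single-date data and empty search spaces are rejected", {
  one_date <- make_lfq(matrix(rpois(20, 5), ncol = 1), dates = 2019.5)
  expect_error(elefan_ga(one_date, seed = 1), "2 sampling dates")
  expect_error(elefan_search_space(Linf = c(80, 40)), "bounds")
})

test_that("Lmax anchoring brackets the largest observed individual", {
  sim <- small_survey(seed = 8)
  lfq <- sim_lfq(sim)
  rng <- linf_range_from_lmax(lfq)
  lmax <- max(sim$individuals$sl_mm)
  expect_lte(rng[1], lmax)
  expect_gte(rng[2], lmax)
})
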