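#' Score a growth curve against restructured length-frequency data
#'
#' The ELEFAN goodness of fit: the ratio of the Explained Sum of Peaks
#' (ESP) to the Available Sum of Peaks (ASP). ASP is the sum, over
#' dates, of the maximum score of every contiguous positive run in the
#' restructured histogram. Candidate growth curves are turned into
#' cohort trajectories, one per birth year spanning `max_age` years
#' before the first sample; where a trajectory crosses a date column it
#' selects the length bin it predicts. ESP adds the maximum score of
#' every distinct positive run hit (a run is counted at most once per
#' date, however many cohorts pass through it) and the score of every
#' distinct negative bin crossed, so curves threading the troughs are
#' penalised.
#'
#' @param params A [growth_params()] object (or coercible list).
#' @param restructured An `"lfq_restructured"` object from
#'   [restructure_lfq()].
#' @param max_age Maximum cohort age in years used to span birth years
#'   (default 11, the observed longevity of the population).
#' @return The ESP/ASP score, at most 1.
#' @export
score_growth_curve <- function(params, restructured, max_age = 11) {
  params <- as_growth_params(params)
  stopifnot(inherits(restructured, "lfq_restructured"))
  pre <- elefan_precompute(restructured)
  if (pre$asp <= 0) stop("degenerate LFQ: no positive scores to explain")
  elefan_esp(params, pre, max_age) / pre$asp
}

# Static per-dataset structures used by every score evaluation.
elefan_precompute <- function(restructured) {
  runs <- restructured$peak_runs
  scores <- restructured$rcounts
  nbin <- nrow(scores)
  run_id <- lapply(seq_along(runs), function(j) {
    id <- integer(nbin)
    rr <- runs[[j]]
    for (k in seq_len(nrow(rr))) id[rr$start[k]:rr$end[k]] <- k
    id
  })
  list(dates = restructured$dates,
       bin_lower = restructured$bin_lower,
       bin_width = restructured$bin_width,
       nbin = nbin,
       scores = scores,
       run_id = run_id,
       run_max = lapply(runs, function(rr) rr$max_score),
       asp = sum(vapply(runs, function(rr) sum(rr$max_score), numeric(1))))
}

elefan_esp <- function(params, pre, max_age = 11) {
  births <- seq(floor(min(pre$dates)) - ceiling(max_age),
                floor(max(pre$dates))) + params$t0
  esp <- 0
  off <- round(pre$bin_lower[1] / pre$bin_width)
  for (j in seq_along(pre$dates)) {
    d <- pre$dates[j]
    ages <- d - births
    act <- births[ages > 1e-9 & ages <= max_age]
    if (!length(act)) next
    len <- sovbgf_length(params, d - (act - params$t0))
    bins <- floor(len / pre$bin_width) - off + 1L
    bins <- unique(bins[bins >= 1L & bins <= pre$nbin])
    if (!length(bins)) next
    rid <- pre$run_id[[j]][bins]
    posb <- rid > 0L
    if (any(posb)) {
      # one credit per run per date: the best crossed bin of the run,
      # so curves threading mode centres outscore curves on shoulders
      esp <- esp + sum(tapply(pre$scores[bins[posb], j], rid[posb], max))
    }
    neg <- bins[pre$scores[bins, j] < 0]
    if (length(neg)) esp <- esp + sum(pre$scores[neg, j])
  }
  esp
}

#' Search space for growth-parameter estimation
#'
#' Bounds for the five soVBGF parameters. The asymptotic length and
#' growth constant ranges default to the broad exploration window
#' (Linf 40-140 mm, K 0.01-1 /yr); anchor time, oscillation amplitude
#' and season start span their full domains.
#'
#' @param Linf,K,t0,C,ts Length-2 numeric `(lo, hi)` bounds.
#' @return A named list of bounds.
#' @export
elefan_search_space <- function(Linf = c(40, 140), K = c(0.01, 1),
                                t0 = c(0, 1), C = c(0, 1), ts = c(0, 1)) {
  sp <- list(Linf = Linf, K = K, t0 = t0, C = C, ts = ts)
  for (nm in names(sp)) {
    b <- sp[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[2] < b[1])
      stop("bad bounds for '", nm, "'")
  }
  sp
}

#' Data-anchored asymptotic-length bounds
#'
#' ELEFAN score surfaces are ridge-shaped in (Linf, K): ever larger
#' asymptotic lengths with compensating smaller growth constants trace
#' nearly the same curve through the observed length range (the
#' phi-prime ridge), so an unbounded search drifts toward arbitrarily
#' large Linf. Standard practice anchors the search range on the
#' largest observed individual. The default spans 0.8-1.5 x Lmax:
#' below ~0.8 Lmax the largest individuals could not exist, while
#' beyond ~1.5 Lmax even the oldest observed cohort would sit far below
#' the asymptote on a scale length-frequency data cannot resolve.
#'
#' @param lfq An `"lfq"` object.
#' @param spread Multipliers `(lo, hi)` applied to the largest occupied
#'   bin's upper edge.
#' @return Length-2 numeric bounds for `Linf`.
#' @export
linf_range_from_lmax <- function(lfq, spread = c(0.8, 1.5)) {
  occ <- which(rowSums(lfq$catch) > 0)
  lmax <- lfq$bin_lower[max(occ)] + lfq$bin_width
  lmax * spread
}

space_to_params <- function(u, space) {
  val <- mapply(function(ui, b) b[1] + ui * (b[2] - b[1]), u, space)
  names(val) <- names(space)
  growth_params(Linf = val[["Linf"]], K = max(val[["K"]], 1e-8),
                t0 = min(max(val[["t0"]], 0), 1 - 1e-9),
                C = min(max(val[["C"]], 0), 1),
                ts = min(max(val[["ts"]], 0), 1 - 1e-9))
}

#' Response-surface pre-search over Linf and K
#'
#' Scores a grid of (Linf, K) combinations (seasonal terms off, anchor
#' time scanned coarsely and maximised out) against a restructured
#' length-frequency. Used to restrict the asymptotic-length search
#' range before the genetic algorithm, mirroring the two-stage protocol
#' of exploratory response-surface analysis followed by a refined fit.
#'
#' @param lfq An `"lfq"` object.
#' @param linf_range,k_range Grid bounds.
#' @param n_linf,n_k Grid resolution.
#' @param ma Moving-average window for restructuring.
#' @param max_age Maximum cohort age (years).
#' @return A data frame with `Linf`, `K` and `score`, one row per grid
#'   cell.
#' @export
rsa_grid <- function(lfq, linf_range = c(40, 140), k_range = c(0.01, 1),
                     n_linf = 21, n_k = 21, ma = 9, max_age = 11) {
  res <- restructure_lfq(lfq, ma = ma)
  pre <- elefan_precompute(res)
  if (pre$asp <= 0) stop("degenerate LFQ: no positive scores to explain")
  linfs <- seq(linf_range[1], linf_range[2], length.out = n_linf)
  ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_k))
  t0s <- seq(0, 11 / 12, by = 1 / 12)
  grid <- expand.grid(Linf = linfs, K = ks)
  grid$score <- mapply(function(li, ki) {
    max(vapply(t0s, function(tt) {
      elefan_esp(growth_params(Linf = li, K = ki, t0 = tt), pre, max_age)
    }, numeric(1))) / pre$asp
  }, grid$Linf, grid$K)
  grid
}

#' Fit seasonal von Bertalanffy growth to length-frequency data
#'
#' ELEFAN with a real-coded genetic algorithm: candidate parameter
#' vectors are scored with [score_growth_curve()] against the
#' restructured histogram and evolved under tournament selection,
#' blend crossover, Gaussian mutation and elitism. Optionally the fit
#' is bootstrapped by resampling individuals within each sampling date
#' (multinomial resampling of the count columns) and refitting, giving
#' empirical uncertainty for every parameter.
#'
#' @param lfq An `"lfq"` object with at least 2 dates and 5 bins.
#' @param search_space Bounds from [elefan_search_space()], or `NULL`
#'   (default) to anchor the asymptotic-length range on the largest
#'   observed individual via [linf_range_from_lmax()] and leave the
#'   other parameters at their full domains.
#' @param ma Moving-average window for restructuring (default 9 bins,
#'   approximately the width of the youngest cohort).
#' @param n_boot Number of bootstrap resamplings (default 100; 0 skips
#'   the bootstrap).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param max_age Maximum cohort age in years (default 11).
#' @param control GA settings: `pop_size` (50), `generations` (300),
#'   `tournament` (3), `crossover` (0.8), `mutation_sd` (0.05 of each
#'   parameter range), `mutation_prob` (0.3 per gene), `immigrants`
#'   (random individuals injected per generation, 5), `stagnation`
#'   (early stop after 60 generations without improvement).
#' @return An object of class `"elefan_fit"`: list with `params`
#'   ([growth_params()]), `score`, `phi_prime`, `bootstrap_params`
#'   (data frame, one row per resampling), `search_space`, `seed`,
#'   `ma` and the per-generation best-score trace `trace`.
#' @export
elefan_ga <- function(lfq, search_space = NULL,
                      ma = 9, n_boot = 100, seed = 1, max_age = 11,
                      control = list()) {
  stopifnot(inherits(lfq, "lfq"))
  if (length(lfq$dates) < 2) stop("at least 2 sampling dates are required")
  if (nrow(lfq$catch) < 5) stop("at least 5 length bins are required")
  if (is.null(search_space))
    search_space <- elefan_search_space(Linf = linf_range_from_lmax(lfq))
  ctrl <- utils::modifyList(list(pop_size = 50, generations = 300,
                                 tournament = 3, crossover = 0.8,
                                 mutation_sd = 0.05, mutation_prob = 0.3,
                                 immigrants = 5, stagnation = 60), control)
  res <- restructure_lfq(lfq, ma = ma)
  pre <- elefan_precompute(res)
  if (pre$asp <= 0) stop("degenerate LFQ: no positive scores to explain")

  set.seed(seed)
  main <- ga_optimize(pre, search_space, ctrl, max_age)

  boot <- NULL
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 5,
                   dimnames = list(NULL, c("Linf", "K", "t0", "C", "ts")))
    for (b in seq_len(n_boot)) {
      blfq <- resample_lfq(lfq)
      bres <- restructure_lfq(blfq, ma = ma)
      bpre <- elefan_precompute(bres)
      if (bpre$asp <= 0) next
      bp <- ga_optimize(bpre, search_space, ctrl, max_age)$params
      boot[b, ] <- unlist(bp)
    }
    boot <- as.data.frame(boot)
  }
  structure(list(params = main$params, score = main$score,
                 phi_prime = phi_prime(main$params$K, main$params$Linf),
                 bootstrap_params = boot, search_space = search_space,
                 seed = seed, ma = ma, max_age = max_age,
                 trace = main$trace),
            class = "elefan_fit")
}

#' @export
print.elefan_fit <- function(x, ...) {
  cat("ELEFAN genetic-algorithm growth fit\n")
  print(x$params)
  cat(sprintf("  ESP/ASP score = %.4f  (ma = %d, seed = %d)\n",
              x$score, x$ma, x$seed))
  if (!is.null(x$bootstrap_params))
    cat(sprintf("  bootstrap resamplings: %d\n", nrow(x$bootstrap_params)))
  invisible(x)
}

#' Bootstrap percentile intervals for an ELEFAN fit
#'
#' @param fit An `"elefan_fit"` with bootstrap resamplings.
#' @param probs Percentiles (default 2.5/50/97.5).
#' @return A matrix of percentiles (rows) by parameter (columns).
#' @export
elefan_boot_ci <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fit, "elefan_fit"))
  if (is.null(fit$bootstrap_params)) stop("fit has no bootstrap resamplings")
  apply(fit$bootstrap_params, 2, stats::quantile, probs = probs, na.rm = TRUE)
}

# multinomial resampling of individuals within each date column
resample_lfq <- function(lfq) {
  catch <- apply(lfq$catch, 2, function(cnt) {
    n <- sum(cnt)
    if (n == 0) return(cnt)
    as.integer(stats::rmultinom(1, n, cnt / n))
  })
  lfq$catch <- matrix(catch, nrow = nrow(lfq$catch),
                      dimnames = dimnames(lfq$catch))
  lfq
}

# Real-coded GA on the unit cube; maximises ESP/ASP. Elitist: the best
# individual survives unchanged, so the best score never decreases.
ga_optimize <- function(pre, space, ctrl, max_age) {
  npar <- 5L
  fitness <- function(u) {
    elefan_esp(space_to_params(u, space), pre, max_age) / pre$asp
  }
  pop <- matrix(stats::runif(ctrl$pop_size * npar), ctrl$pop_size, npar)
  fit <- apply(pop, 1, fitness)
  best_i <- which.max(fit)
  best_u <- pop[best_i, ]
  best_f <- fit[best_i]
  trace <- numeric(0)
  stagnant <- 0L
  n_imm <- min(ctrl$immigrants, ctrl$pop_size - 2L)
  for (g in seq_len(ctrl$generations)) {
    newpop <- matrix(NA_real_, ctrl$pop_size, npar)
    newpop[1, ] <- best_u  # elitism
    for (i in seq(2L, ctrl$pop_size)) {
      p1 <- tournament_pick(fit, ctrl$tournament)
      p2 <- tournament_pick(fit, ctrl$tournament)
      child <- if (stats::runif(1) < ctrl$crossover) {
        w <- stats::runif(npar)
        w * pop[p1, ] + (1 - w) * pop[p2, ]
      } else pop[p1, ]
      mut <- stats::runif(npar) < ctrl$mutation_prob
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, ctrl$mutation_sd)
      newpop[i, ] <- pmin(pmax(child, 0), 1)
    }
    # random immigrants keep the search exploring new basins
    if (n_imm > 0) {
      imm_rows <- seq(ctrl$pop_size - n_imm + 1L, ctrl$pop_size)
      newpop[imm_rows, ] <- stats::runif(n_imm * npar)
    }
    pop <- newpop
    fit <- apply(pop, 1, fitness)
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_f) {
      best_f <- fit[gen_best]
      best_u <- pop[gen_best, ]
      stagnant <- 0L
    } else stagnant <- stagnant + 1L
    trace <- c(trace, best_f)
    if (stagnant >= ctrl$stagnation) break
  }
  list(params = space_to_params(best_u, space), score = best_f, trace = trace)
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), min(k, length(fit)))
  cand[which.max(fit[cand])]
}
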