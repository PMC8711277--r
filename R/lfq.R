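#' Build a length-frequency object from individual lengths
#'
#' Bins shell lengths into uniform-width classes per sampling date. Bin
#' membership follows the half-open convention `[lo, lo + width)`: a
#' length exactly on an edge belongs to the upper bin. Bin edges are
#' aligned to multiples of `bin_width` so binning does not depend on the
#' observed minimum.
#'
#' @param lengths Shell lengths (mm), > 0.
#' @param dates Sampling time of each individual, decimal years (same
#'   length as `lengths`).
#' @param bin_width Bin width in mm (default 2).
#' @return An object of class `"lfq"`: a list with `midLengths` (bin
#'   midpoints, mm), `bin_lower` (lower edges), `bin_width`, `dates`
#'   (sorted unique decimal years) and `catch` (bins x dates count
#'   matrix).
#' @export
build_lfq <- function(lengths, dates, bin_width = 2) {
  if (length(lengths) == 0L) stop("no individuals supplied")
  if (length(dates) == 1L) dates <- rep(dates, length(lengths))
  if (length(dates) != length(lengths))
    stop("'lengths' and 'dates' must have the same length")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  lo_idx <- floor(lengths / bin_width)
  idx_range <- range(lo_idx)
  bin_lower <- seq(idx_range[1], idx_range[2]) * bin_width
  udates <- sort(unique(dates))
  catch <- vapply(udates, function(d) {
    tabulate(lo_idx[dates == d] - idx_range[1] + 1L, nbins = length(bin_lower))
  }, integer(length(bin_lower)))
  catch <- matrix(catch, nrow = length(bin_lower),
                  dimnames = list(NULL, format(udates, nsmall = 3)))
  structure(list(midLengths = bin_lower + bin_width / 2,
                 bin_lower = bin_lower, bin_width = bin_width,
                 dates = udates, catch = catch),
            class = "lfq")
}

#' @export
print.lfq <- function(x, ...) {
  cat(sprintf("Length-frequency data: %d bins (%g mm) x %d dates, %d individuals\n",
              nrow(x$catch), x$bin_width, ncol(x$catch), sum(x$catch)))
  invisible(x)
}

#' Write / read length-frequency CSV
#'
#' The exchange format has the bin lower edge (mm) in the first column
#' and one integer count column per sampling date; date columns are
#' named by decimal year.
#'
#' @param lfq An `"lfq"` object.
#' @param path File path.
#' @return `read_lfq` returns an `"lfq"` object; `write_lfq` returns
#'   `path` invisibly.
#' @export
write_lfq <- function(lfq, path) {
  df <- data.frame(bin_lower_mm = lfq$bin_lower, lfq$catch, check.names = FALSE)
  names(df)[-1] <- format(lfq$dates, nsmall = 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfq
#' @export
read_lfq <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  bin_lower <- df[[1]]
  w <- diff(bin_lower)
  if (length(w) && max(abs(w - w[1])) > 1e-8) stop("bins must have uniform width")
  width <- if (length(w)) w[1] else 1
  structure(list(midLengths = bin_lower + width / 2, bin_lower = bin_lower,
                 bin_width = width,
                 dates = as.numeric(names(df)[-1]),
                 catch = as.matrix(df[-1])),
            class = "lfq")
}

# Centered moving average with a window that shrinks at the histogram
# edges (mean over the available bins), so a flat column has MA == count
# everywhere.
moving_average_shrink <- function(x, ma) {
  h <- (ma - 1L) / 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Restructure a length-frequency histogram for ELEFAN scoring
#'
#' Transforms counts so cohort modes score positively and troughs
#' negatively, following the classic ELEFAN restructuring. Per date
#' column the frozen procedure is:
#' \enumerate{
#'   \item centered moving average over `ma` bins, the window shrinking
#'     at the edges (flat columns therefore restructure to all zeros);
#'   \item score = count / MA - 1, with 0/0 defined as 0;
#'   \item positive scores are capped at 5 (limits the dominance of
#'     spikes sitting on a near-empty background);
#'   \item isolated peaks (a positive bin whose within-range neighbours
#'     are both empty) are halved, de-emphasising single strays;
#'   \item the score of every empty bin is divided by the length of the
#'     contiguous run of empty bins it belongs to, so long gaps (the
#'     sparse tail of the distribution) do not dominate the negative
#'     mass;
#'   \item positive scores are divided by the column maximum so the
#'     largest positive is +1. Negative scores are left as is; they are
#'     bounded below by -1 by construction.
#' }
#'
#' @param lfq An `"lfq"` object.
#' @param ma Odd moving-average window, `3 <= ma <=` number of bins.
#' @return An object of class `"lfq_restructured"`: the `lfq` fields
#'   plus `rcounts` (score matrix), `ma` and `peak_runs`, a per-date
#'   list of data frames describing contiguous positive-score runs
#'   (`start`, `end` bin indices and `max_score`).
#' @export
restructure_lfq <- function(lfq, ma = 9) {
  stopifnot(inherits(lfq, "lfq"))
  if (ma %% 2 != 1 || ma < 3) stop("'ma' must be an odd integer >= 3")
  if (ma > nrow(lfq$catch)) stop("'ma' exceeds the number of length bins")
  scores <- apply(lfq$catch, 2, function(cnt) {
    mav <- moving_average_shrink(cnt, ma)
    r <- ifelse(mav > 0, cnt / mav - 1, 0)
    r[r > 5] <- 5
    pos <- which(r > 0)
    for (i in pos) {
      left <- if (i > 1L) cnt[i - 1L] else 0
      right <- if (i < length(cnt)) cnt[i + 1L] else 0
      if (left == 0 && right == 0) r[i] <- r[i] / 2
    }
    zr <- rle(cnt == 0)
    zlen <- rep(zr$lengths, zr$lengths)
    r <- ifelse(cnt == 0 & zlen > 0, r / zlen, r)
    r <- r * pmin(1, mav / (0.02 * sum(cnt)))
    mx <- max(r)
    if (mx > 0) r[r > 0] <- r[r > 0] / mx
    r
  })
  scores <- matrix(scores, nrow = nrow(lfq$catch),
                   dimnames = dimnames(lfq$catch))
  out <- unclass(lfq)
  out$rcounts <- scores
  out$ma <- ma
  out$peak_runs <- apply(scores, 2, positive_runs, simplify = FALSE)
  structure(out, class = c("lfq_restructured", "lfq"))
}

# contiguous runs of strictly positive scores in one column
positive_runs <- function(s) {
  pos <- s > 0
  if (!any(pos)) {
    return(data.frame(start = integer(0), end = integer(0),
                      max_score = numeric(0)))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             max_score = vapply(which(keep), function(k) {
               max(s[starts[k]:ends[k]])
             }, numeric(1)))
}
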