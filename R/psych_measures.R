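# The Towse & Neil collection of randomness measures for RNG-task
# sequences. Shared conventions: positions are 1-based; pair counting never
# wraps around (the pair formed by the last and first response is excluded),
# so a sequence of length L yields L - lag pairs at a given lag.

# condition signalled when a measure is undefined for an input (e.g. the
# repetition gap of a sequence without any repeated response); the batch
# scorer converts it to a missing value rather than a zero.
undefined_measure <- function(msg) {
  stop(structure(class = c("rngbench_undefined_measure", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Ordered-pair counts at a lag
#'
#' Counts ordered response pairs `(s_i, s_{i+lag})` over the declared
#' alphabet. Lag 1 gives adjacent pairs, lag 2 the interleaved pairs used by
#' the RNG2 index (in `4-1-5-6` the lag-2 pairs are `4-5` and `1-6`). The
#' wrap-around pair (last response followed by the first) is never counted,
#' so the total is `L - lag`.
#'
#' @param seq an [rng_sequence] or integer vector.
#' @param lag pair lag, a positive integer (1 or 2 in practice).
#' @param alphabet_size used when `seq` is a bare vector.
#' @return An `a x a` integer matrix `n[i, j]` of counts of pair `(i, j)`.
#' @export
pair_counts <- function(seq, lag = 1L, alphabet_size = 9L) {
  s <- as_rng_sequence(seq, alphabet_size)
  v <- s$values
  a <- s$alphabet_size
  lag <- as.integer(lag)
  if (lag < 1L) stop("'lag' must be a positive integer", call. = FALSE)
  if (length(v) < lag + 1L) {
    stop(sprintf("sequence of length %d has no pairs at lag %d",
                 length(v), lag), call. = FALSE)
  }
  first <- v[seq_len(length(v) - lag)]
  second <- v[(1L + lag):length(v)]
  m <- matrix(0L, a, a)
  tab <- table(factor(first, levels = seq_len(a)),
               factor(second, levels = seq_len(a)))
  m[] <- as.integer(tab)
  m
}

# x * log(x) with the 0 * log 0 := 0 convention, vectorized
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Redundancy index
#'
#' A transformed Shannon entropy of the single-response frequency
#' distribution over the declared alphabet:
#' `R = 100 * (1 - H / log2(a))` with `H = -sum(p_s * log2(p_s))`.
#' 0 means all admissible responses were used equally often; 100 means a
#' single response was used throughout.
#'
#' @param seq an [rng_sequence] or integer vector.
#' @param alphabet_size used when `seq` is a bare vector.
#' @return Index on the 0-100 scale.
#' @examples
#' redundancy_index(rep(1:9, each = 20))  # 0
#' redundancy_index(rep(5, 50))           # 100
#' @export
redundancy_index <- function(seq, alphabet_size = 9L) {
  s <- as_rng_sequence(seq, alphabet_size)
  a <- s$alphabet_size
  if (a < 2L) {
    stop("the redundancy index needs an alphabet of at least 2 responses",
         call. = FALSE)
  }
  p <- tabulate(s$values, nbins = a) / length(s$values)
  h <- -sum(xlogx(p)) / log(2)
  r <- 100 * (1 - h / log2(a))
  min(max(r, 0), 100)
}

#' RNG and RNG2 indices
#'
#' Measures inequality of transition probabilities between response pairs,
#' given the marginal distribution of the first pair member:
#' `100 * sum(n_ij * log(n_ij)) / sum(n_i. * log(n_i.))` over the pair-count
#' matrix at the requested lag (RNG index: lag 1, consecutive pairs; RNG2
#' index: lag 2, interleaved pairs separated by one response). 0 means
#' perfectly equal transition probabilities; 100 means every transition is
#' deterministic. When every row total is 0 or 1 the denominator vanishes
#' and the score is defined as 0.
#'
#' @inheritParams pair_counts
#' @return Index on the 0-100 scale.
#' @examples
#' rng_index(c(1, 2, 1, 2, 1, 2), alphabet_size = 9)        # 100
#' rng_index(c(4, 1, 5, 6), lag = 2)                        # RNG2 variant
#' @export
rng_index <- function(seq, lag = 1L, alphabet_size = 9L) {
  m <- pair_counts(seq, lag = lag, alphabet_size = alphabet_size)
  num <- sum(xlogx(m))
  den <- sum(xlogx(rowSums(m)))
  if (den == 0) return(0)
  100 * num / den
}

#' Null-score quotient (NSQ)
#'
#' The percentage of possible ordered response pairs that never occur as
#' lag-1 pairs: `100 * Z / a^2`, where `Z` counts absent cells of the
#' pair-count matrix. 0 means every possible pair occurs.
#'
#' @inheritParams pair_counts
#' @return Percentage in 0-100.
#' @examples
#' null_score_quotient(c(4, 1, 5, 6))  # 3 of 81 pairs present
#' @export
null_score_quotient <- function(seq, alphabet_size = 9L) {
  m <- pair_counts(seq, lag = 1L, alphabet_size = alphabet_size)
  a <- nrow(m)
  100 * sum(m == 0L) / a^2
}

#' Coupon score
#'
#' Mean number of responses needed to observe every admissible response at
#' least once: the sequence is scanned left to right, the count at each
#' completion of a full set is recorded, and the scan restarts; a trailing
#' incomplete segment is discarded. If the sequence never contains some
#' response the score is the sequence length plus one. Lower scores indicate
#' faster coverage of the alphabet (the human "cycling" tendency).
#'
#' @inheritParams pair_counts
#' @return Mean completion count, in `[a, L + 1]`.
#' @examples
#' coupon_score(c(1, 2, 2, 3, 1, 3, 2), alphabet_size = 3)  # mean of 4, 3
#' @export
coupon_score <- function(seq, alphabet_size = 9L) {
  s <- as_rng_sequence(seq, alphabet_size)
  v <- s$values
  a <- s$alphabet_size
  seen <- logical(a)
  n_seen <- 0L
  count <- 0L
  lengths <- integer(0)
  for (x in v) {
    count <- count + 1L
    if (!seen[x]) {
      seen[x] <- TRUE
      n_seen <- n_seen + 1L
    }
    if (n_seen == a) {
      lengths <- c(lengths, count)
      seen <- logical(a)
      n_seen <- 0L
      count <- 0L
    }
  }
  if (length(lengths) == 0L) return(length(v) + 1)
  mean(lengths)
}

#' Repetition gap
#'
#' Positional distance between successive occurrences of the same response,
#' pooled over all responses; returns the mean, median or mode of the gap
#' distribution. The median of an even gap count is the midpoint average;
#' modal ties break to the smallest gap. A sequence with no repeated
#' response has no gaps: the measure is undefined and an error of class
#' `rngbench_undefined_measure` is signalled (batch scoring reports it as
#' missing, never as zero).
#'
#' @inheritParams pair_counts
#' @param statistic one of `"mean"`, `"median"`, `"mode"`.
#' @return Gap statistic, in `[1, L - 1]`.
#' @examples
#' repetition_gap(c(1, 1, 2, 1))                    # gaps {1, 2}: mean 1.5
#' repetition_gap(c(1, 1, 2, 1), statistic = "mode")  # 1
#' @export
repetition_gap <- function(seq, statistic = c("mean", "median", "mode"),
                           alphabet_size = 9L) {
  statistic <- match.arg(statistic)
  s <- as_rng_sequence(seq, alphabet_size)
  v <- s$values
  gaps <- unlist(lapply(seq_len(s$alphabet_size), function(sym) {
    diff(which(v == sym))
  }), use.names = FALSE)
  if (length(gaps) == 0L) {
    undefined_measure("no response repeats anywhere; the repetition gap is undefined")
  }
  switch(statistic,
         mean = mean(gaps),
         median = stats::median(gaps),
         mode = {
           tab <- table(gaps)
           as.numeric(names(tab)[which.max(tab)])  # ties -> smallest gap
         })
}

#' Adjacency index
#'
#' Percentage of lag-1 pairs whose members are numerically adjacent:
#' ascending (`y = x + 1`, e.g. 3-4), descending (`y = x - 1`, e.g. 7-6), or
#' either (`combined`). There is no value wrap: 9 followed by 1 is not
#' adjacent. For an i.i.d. uniform source over 1..9 the expected combined
#' index is `100 * 16/81`.
#'
#' @inheritParams pair_counts
#' @param mode one of `"combined"`, `"ascending"`, `"descending"`.
#' @return Percentage in 0-100.
#' @examples
#' adjacency_index(c(7, 6, 4, 5))                      # 66.67
#' adjacency_index(1:3, mode = "ascending")            # 100
#' @export
adjacency_index <- function(seq, mode = c("combined", "ascending",
                                          "descending"),
                            alphabet_size = 9L) {
  mode <- match.arg(mode)
  s <- as_rng_sequence(seq, alphabet_size)
  v <- s$values
  if (length(v) < 2L) {
    stop("the adjacency index needs at least 2 responses", call. = FALSE)
  }
  d <- diff(v)
  hits <- switch(mode,
                 ascending = sum(d == 1L),
                 descending = sum(d == -1L),
                 combined = sum(abs(d) == 1L))
  100 * hits / (length(v) - 1L)
}

#' Turning point index
#'
#' Counts interior responses that are strict local maxima or minima
#' (`s[i-1] < s[i] > s[i+1]` or the reverse; tied neighbours produce no
#' turning point) and compares the count to the expectation for a random
#' sequence, `E = (2/3) * (L - 2)`, as `100 * observed / E`.
#'
#' @inheritParams pair_counts
#' @return Percentage of the expected turning-point count.
#' @examples
#' turning_point_index(c(1, 3, 5, 4, 3, 7))  # 2 turning points (5 and 3)
#' @export
turning_point_index <- function(seq, alphabet_size = 9L) {
  s <- as_rng_sequence(seq, alphabet_size)
  v <- s$values
  n <- length(v)
  if (n < 3L) {
    stop("the turning point index needs at least 3 responses", call. = FALSE)
  }
  mid <- v[2:(n - 1L)]
  obs <- sum((v[1:(n - 2L)] < mid & mid > v[3:n]) |
               (v[1:(n - 2L)] > mid & mid < v[3:n]))
  expected <- (2 / 3) * (n - 2L)
  100 * obs / expected
}

# maximal strictly ascending run lengths; an equal or smaller successor
# starts a new run, so 1-4-7-3-5 decomposes into lengths 3 and 2
run_lengths <- function(v) {
  if (length(v) == 1L) return(1L)
  breaks <- which(diff(v) <= 0L)
  diff(c(0L, breaks, length(v)))
}

#' Runs index
#'
#' Variance of the lengths of maximal strictly ascending runs. `1-4-7-3-5`
#' has runs `1-4-7` and `3-5` (lengths 3 and 2). 0 means all runs share one
#' length. The population variance (divide by the run count) is the
#' default; the sample variance is available as a switch since tool
#' implementations differ.
#'
#' @inheritParams pair_counts
#' @param variance `"population"` (default) or `"sample"`.
#' @return Variance of run lengths (0 when fewer than two runs).
#' @examples
#' runs_index(c(1, 4, 7, 3, 5))  # population variance of {3, 2} = 0.25
#' @export
runs_index <- function(seq, variance = c("population", "sample"),
                       alphabet_size = 9L) {
  variance <- match.arg(variance)
  s <- as_rng_sequence(seq, alphabet_size)
  rl <- run_lengths(s$values)
  if (length(rl) < 2L) return(0)
  if (variance == "population") {
    mean((rl - mean(rl))^2)
  } else {
    stats::var(rl)
  }
}

#' Phi index
#'
#' A span-`d` repetition score: over the `N_d = L - d + 1` blocks of length
#' `d`, `O_d` counts blocks whose first and last responses coincide. The
#' observed count is compared with the expectation propagated from blocks
#' one response shorter, `E_d = N_d * O_{d-1} / N_{d-1}` for `d >= 3`. At
#' the base span `d = 2` the one-shorter block degenerates (a single
#' response always "repeats" itself), so chance repetition from the
#' marginal response frequencies is used instead, with the unbiased
#' estimator `E_2 = N_2 * sum(count_s * (count_s - 1)) / (L * (L - 1))`
#' (an i.i.d. source then scores exactly zero on average). The score is
#' `100 * (O_d - E_d) / N_d`: negative values mean fewer repetitions at
#' that span than expected (e.g. human avoidance of immediate repeats at
#' `d = 2`), positive values more.
#'
#' @inheritParams pair_counts
#' @param d block span, an integer from 2 to 10; the sequence must be
#'   longer than `d`.
#' @return Signed score (percentage points of blocks).
#' @examples
#' phi_index(rep(1:3, 10), d = 2)  # < 0: no immediate repetitions at all
#' @export
phi_index <- function(seq, d, alphabet_size = 9L) {
  s <- as_rng_sequence(seq, alphabet_size)
  v <- s$values
  n <- length(v)
  d <- as.integer(d)
  if (d < 2L || d > 10L) stop("'d' must lie in 2..10", call. = FALSE)
  if (n < d + 1L) {
    stop(sprintf("sequence of length %d is too short for span %d", n, d),
         call. = FALSE)
  }
  n_d <- n - d + 1L
  o_d <- sum(v[seq_len(n_d)] == v[d:n])
  if (d == 2L) {
    # chance repetition from the marginal response frequencies, using the
    # unbiased estimator of sum(p^2) so the index is exactly mean-zero for
    # an i.i.d. source
    cnt <- tabulate(v, nbins = s$alphabet_size)
    e_d <- n_d * sum(cnt * (cnt - 1)) / (n * (n - 1))
  } else {
    n_prev <- n - d + 2L
    o_prev <- sum(v[seq_len(n_prev)] == v[(d - 1L):n])
    e_d <- n_d * o_prev / n_prev
  }
  100 * (o_d - e_d) / n_d
}
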