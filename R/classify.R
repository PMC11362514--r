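# The evaluation engine: per-measure logistic classification of sequence
# source (human vs random) scored by bootstrapped out-of-bag correct
# classification rates with percentile confidence intervals.

# Two-parameter logistic fit (intercept + slope) by iteratively reweighted
# least squares with a tiny ridge penalty. The penalty keeps the fit finite
# under perfect separation; threshold classification at 0.5 is insensitive
# to its magnitude. x is expected standardized.
fit_logistic_ridge <- function(x, y, lambda = 1e-6, max_iter = 50L,
                               tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtwx <- crossprod(X, w * X) + diag(lambda, 2L)
    beta_new <- drop(solve(xtwx, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

#' Bootstrapped correct classification rate for one measure
#'
#' Scores a single randomness measure's ability to separate human-generated
#' from random sequences. For each of `B` bootstrap iterations, a training
#' set of the full dataset size is drawn with replacement, a two-parameter
#' logistic regression of source on score is fitted to it, and the
#' sequences never drawn in that iteration (the out-of-bag set, on average
#' about 36.8% of the data) are classified at the probability threshold
#' 0.5; the fraction classified correctly is that iteration's rate.
#' Returned are all `B` out-of-bag rates, their mean, and the 2.5th/97.5th
#' percentile confidence interval. A measure whose interval covers 0.50
#' performs at chance.
#'
#' Degenerate draws are handled deterministically: training draws with zero
#' score variance or a single class carry no usable signal and record the
#' chance rate 0.5 for that iteration (so a constant measure scores exactly
#' at chance); perfect separation is tamed by a tiny ridge penalty that leaves
#' threshold decisions unchanged; iterations with an empty out-of-bag set
#' are redrawn. Predicted probabilities of exactly 0.5 classify as the
#' random source. Missing scores are excluded pairwise, with the exclusion
#' count recorded.
#'
#' @param scores numeric vector of per-sequence scores for one measure.
#' @param labels aligned source labels, `"human"` or `"random"`; both must
#'   occur.
#' @param B number of bootstrap iterations (study value 1000), at least 2.
#' @param seed integer seed for reproducibility; recorded in the result.
#' @return An object of class `rng_ccr`: list with `rates` (length `B`),
#'   `mean_rate`, `ci_lower`, `ci_upper`, `B`, `seed`, `n_used`,
#'   `n_excluded`.
#' @examples
#' set.seed(1)
#' r <- bootstrap_ccr(c(rnorm(30, 2), rnorm(30)),
#'                    rep(c("human", "random"), each = 30),
#'                    B = 50, seed = 7)
#' r$mean_rate
#' @export
bootstrap_ccr <- function(scores, labels, B = 1000L, seed = NULL) {
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must be aligned", call. = FALSE)
  }
  B <- as.integer(B)
  if (B < 2L) stop("'B' must be at least 2", call. = FALSE)
  labels <- as.character(labels)
  if (!all(labels %in% c("human", "random"))) {
    stop("labels must be 'human' or 'random'", call. = FALSE)
  }
  keep <- !is.na(scores)
  n_excluded <- sum(!keep)
  x <- as.numeric(scores[keep])
  y <- as.integer(labels[keep] == "human")
  n <- length(x)
  if (length(unique(y)) < 2L) {
    stop("both a human and a random class must be present", call. = FALSE)
  }

  rates <- with_local_seed(seed, function() {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- which(tabulate(idx, nbins = n) == 0L)
        if (length(oob) > 0L) break
      }
      x_tr <- x[idx]
      y_tr <- y[idx]
      if (stats::var(x_tr) == 0 || length(unique(y_tr)) < 2L) {
        # degenerate draw (no score variance, or one class only): the
        # measure carries no information, so the iteration records the
        # chance rate instead of a noisy majority vote
        return(0.5)
      }
      mu <- mean(x_tr)
      sd_tr <- stats::sd(x_tr)
      beta <- fit_logistic_ridge((x_tr - mu) / sd_tr, y_tr)
      p_oob <- stats::plogis(beta[1] + beta[2] * (x[oob] - mu) / sd_tr)
      pred <- as.integer(p_oob > 0.5)  # exactly 0.5 -> random source
      mean(pred == y[oob])
    }, numeric(1))
  })

  ci <- stats::quantile(rates, c(0.025, 0.975), names = FALSE)
  structure(
    list(rates = rates, mean_rate = mean(rates),
         ci_lower = ci[1L], ci_upper = ci[2L],
         B = B, seed = seed, n_used = n, n_excluded = n_excluded),
    class = "rng_ccr"
  )
}

#' @export
print.rng_ccr <- function(x, ...) {
  cat(sprintf(
    "<rng_ccr> mean CCR %.3f [%.3f, %.3f] over %d bootstrap iterations (n = %d%s)\n",
    x$mean_rate, x$ci_lower, x$ci_upper, x$B, x$n_used,
    if (x$n_excluded > 0L) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Common language effect size (CLES)
#'
#' The probability that a randomly selected score from the human sample
#' exceeds a randomly selected score from the random-sequence sample, with
#' ties counted as one half:
#' `(#\{h > r\} + 0.5 * #\{h = r\}) / (n_h * n_r)`. Computed through the
#' rank-sum (Mann-Whitney) identity, which handles ties via midranks.
#'
#' @param human_scores,random_scores nonempty numeric score vectors
#'   (missing values dropped).
#' @return Probability in `[0, 1]`.
#' @examples
#' cles(c(1, 3), 2)  # 0.5
#' @export
cles <- function(human_scores, random_scores) {
  h <- human_scores[!is.na(human_scores)]
  r <- random_scores[!is.na(random_scores)]
  if (length(h) == 0L || length(r) == 0L) {
    stop("both score vectors must be nonempty", call. = FALSE)
  }
  rk <- rank(c(h, r))
  u <- sum(rk[seq_along(h)]) - length(h) * (length(h) + 1) / 2
  u / (length(h) * length(r))
}

#' Run the full classification benchmark
#'
#' The complete evaluation pipeline: scores every sequence on every
#' requested battery cell at every prefix length ([score_sequences()]),
#' runs [bootstrap_ccr()] per cell, computes the CLES per cell, and flags
#' pairwise significant differences by the confidence-interval overlap
#' rule (two cells differ significantly when their 95% intervals do not
#' overlap).
#'
#' @param data an [rng_sequence_set] containing both human and random
#'   sequences.
#' @param lengths prefix lengths to sweep (study values 20, 50, 100, 200).
#' @param measures optional character vector of measure ids (see
#'   [measure_battery()]); default all.
#' @param ctm_table a [ctm_table]; required when CTM-based measures are in
#'   the battery.
#' @param B bootstrap iterations per cell (study value 1000).
#' @param seed master seed; per-cell seeds are derived from it
#'   deterministically, making the whole benchmark reproducible
#'   bit for bit.
#' @param block_lengths block sizes for the block-size-dependent measures.
#' @return An object of class `rng_benchmark`: list with `results` (one
#'   row per cell: mean rate, CI bounds, CLES, exclusion count), `scores`
#'   (the long per-sequence score table), `significance` (logical matrix
#'   of pairwise CI non-overlap), `B`, `seed`, `lengths`.
#' @export
run_benchmark <- function(data, lengths = c(20L, 50L, 100L, 200L),
                          measures = NULL, ctm_table = NULL, B = 1000L,
                          seed = NULL, block_lengths = 2:10) {
  stopifnot(inherits(data, "rng_sequence_set"))
  if (length(unique(data$source)) < 2L) {
    stop("'data' must contain both human and random sequences",
         call. = FALSE)
  }
  battery <- measure_battery(block_lengths = block_lengths,
                             measures = measures)
  if (any(battery$requires_ctm) && is.null(ctm_table)) {
    stop(paste("CTM-based measures requested but no 'ctm_table' supplied;",
               "pass one or build a synthetic one with synthetic_ctm_table()"),
         call. = FALSE)
  }
  scores <- score_sequences(data, battery = battery, lengths = lengths,
                            ctm_table = ctm_table)

  cells <- unique(scores[, c("measure", "variant", "prefix_length")])
  row.names(cells) <- NULL
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- scores$measure == cells$measure[i] &
      scores$variant == cells$variant[i] &
      scores$prefix_length == cells$prefix_length[i]
    sc <- scores$score[sel]
    lb <- scores$source[sel]
    cell_seed <- if (is.null(seed)) NULL else {
      as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    }
    ccr <- bootstrap_ccr(sc, lb, B = B, seed = cell_seed)
    res[[i]] <- data.frame(
      measure = cells$measure[i], variant = cells$variant[i],
      prefix_length = cells$prefix_length[i],
      mean_rate = ccr$mean_rate, ci_lower = ccr$ci_lower,
      ci_upper = ccr$ci_upper,
      cles = cles(sc[lb == "human"], sc[lb == "random"]),
      n_excluded = ccr$n_excluded, B = B,
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, res)
  row.names(results) <- NULL

  cell_names <- paste0(results$measure,
                       ifelse(nzchar(results$variant),
                              paste0("_", results$variant), ""),
                       "@", results$prefix_length)
  k <- nrow(results)
  sig <- matrix(FALSE, k, k, dimnames = list(cell_names, cell_names))
  for (i in seq_len(k)) {
    sig[i, ] <- ci_nonoverlap(results$ci_lower[i], results$ci_upper[i],
                              results$ci_lower, results$ci_upper)
  }
  structure(
    list(results = results, scores = scores, significance = sig,
         B = B, seed = seed, lengths = sort(unique(lengths))),
    class = "rng_benchmark"
  )
}

#' @export
print.rng_benchmark <- function(x, ...) {
  cat(sprintf(
    "<rng_benchmark> %d cells (%d prefix lengths), B = %d%s\n",
    nrow(x$results), length(x$lengths), x$B,
    if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  top <- x$results[order(-x$results$mean_rate), ][
    seq_len(min(5L, nrow(x$results))), ]
  cat("top cells by mean correct classification rate:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-22s L=%3d  %.3f [%.3f, %.3f]\n",
                paste0(top$measure[i],
                       ifelse(nzchar(top$variant[i]),
                              paste0("_", top$variant[i]), "")),
                top$prefix_length[i], top$mean_rate[i],
                top$ci_lower[i], top$ci_upper[i]))
  }
  invisible(x)
}

#' Confidence-interval non-overlap significance rule
#'
#' Two classification rates are considered significantly different when
#' their 95% percentile intervals do not overlap (e.g. one interval of
#' (0.70, 0.75) against one of (0.80, 0.85)). Vectorized over the second
#' interval.
#'
#' @param lo1,hi1 bounds of the first interval.
#' @param lo2,hi2 bounds of the second interval(s).
#' @return Logical: `TRUE` where the intervals do not overlap.
#' @export
ci_nonoverlap <- function(lo1, hi1, lo2, hi2) {
  hi1 < lo2 | hi2 < lo1
}

#' Pairs of cells with significantly different classification rates
#'
#' Applies the confidence-interval overlap rule: two benchmark cells are
#' flagged as significantly different when their 95% percentile intervals
#' do not overlap. No multiple-testing correction is applied.
#'
#' @param x an `rng_benchmark` object.
#' @return A data.frame with one row per flagged unordered pair (`cell_a`,
#'   `cell_b`, and the direction `better`).
#' @export
significant_pairs <- function(x) {
  stopifnot(inherits(x, "rng_benchmark"))
  sig <- x$significance
  idx <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(cell_a = character(0), cell_b = character(0),
                      better = character(0), stringsAsFactors = FALSE))
  }
  nm <- rownames(sig)
  data.frame(
    cell_a = nm[idx[, 1L]],
    cell_b = nm[idx[, 2L]],
    better = ifelse(x$results$mean_rate[idx[, 1L]] >
                      x$results$mean_rate[idx[, 2L]],
                    nm[idx[, 1L]], nm[idx[, 2L]]),
    stringsAsFactors = FALSE
  )
}
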