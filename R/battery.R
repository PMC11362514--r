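# Batch scoring: the measure battery as a registry of (measure, variant)
# cells and a long-format scorer feeding the classification benchmark.

#' The measure battery
#'
#' Enumerates every (measure, variant) cell of the full battery: the
#' psychological collection (redundancy, RNG, RNG2, NSQ, coupon score,
#' repetition gap as mean/median/mode, adjacency as
#' ascending/descending/combined, turning point, runs, phi over spans
#' 2..10), block entropy over block sizes 2..10, and the algorithmic-
#' complexity group (coding-theorem window means and BDM over block sizes
#' 2..10, LZ76 phrase count, DEFLATE byte count).
#'
#' @param block_lengths block sizes for the phi index, block entropy and
#'   the CTM-based measures (default 2:10).
#' @param measures optional character vector of measure ids to keep
#'   (default: all).
#' @return A data.frame with columns `measure`, `variant` (empty string
#'   when the measure has no variant) and `requires_ctm`.
#' @export
measure_battery <- function(block_lengths = 2:10, measures = NULL) {
  block_lengths <- as.integer(block_lengths)
  rows <- rbind(
    data.frame(measure = "redundancy", variant = "", requires_ctm = FALSE),
    data.frame(measure = "rng", variant = "", requires_ctm = FALSE),
    data.frame(measure = "rng2", variant = "", requires_ctm = FALSE),
    data.frame(measure = "nsq", variant = "", requires_ctm = FALSE),
    data.frame(measure = "coupon", variant = "", requires_ctm = FALSE),
    data.frame(measure = "repetition_gap",
               variant = c("mean", "median", "mode"), requires_ctm = FALSE),
    data.frame(measure = "adjacency",
               variant = c("ascending", "descending", "combined"),
               requires_ctm = FALSE),
    data.frame(measure = "turning_point", variant = "",
               requires_ctm = FALSE),
    data.frame(measure = "runs", variant = "", requires_ctm = FALSE),
    data.frame(measure = "phi", variant = as.character(block_lengths),
               requires_ctm = FALSE),
    data.frame(measure = "block_entropy",
               variant = as.character(block_lengths), requires_ctm = FALSE),
    data.frame(measure = "acss_mean", variant = as.character(block_lengths),
               requires_ctm = TRUE),
    data.frame(measure = "bdm", variant = as.character(block_lengths),
               requires_ctm = TRUE),
    data.frame(measure = "lz76", variant = "", requires_ctm = FALSE),
    data.frame(measure = "deflate_bytes", variant = "",
               requires_ctm = FALSE)
  )
  if (!is.null(measures)) {
    unknown <- setdiff(measures, unique(rows$measure))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown measure id(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    rows <- rows[rows$measure %in% measures, , drop = FALSE]
  }
  row.names(rows) <- NULL
  rows
}

# score one sequence on one battery cell; undefined measures -> NA
score_cell <- function(measure, variant, s, ctm) {
  res <- tryCatch(
    switch(measure,
      redundancy = redundancy_index(s),
      rng = rng_index(s, lag = 1L),
      rng2 = rng_index(s, lag = 2L),
      nsq = null_score_quotient(s),
      coupon = coupon_score(s),
      repetition_gap = repetition_gap(s, statistic = variant),
      adjacency = adjacency_index(s, mode = variant),
      turning_point = turning_point_index(s),
      runs = runs_index(s),
      phi = phi_index(s, d = as.integer(variant)),
      block_entropy = block_entropy(s, k = as.integer(variant)),
      acss_mean = acss_mean_complexity(s, k = as.integer(variant), ctm),
      bdm = bdm(s, k = as.integer(variant), ctm),
      lz76 = lz76_complexity(s),
      deflate_bytes = deflate_length(s),
      stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
    ),
    rngbench_undefined_measure = function(e) NA_real_
  )
  as.numeric(res)
}

#' Score every sequence on every battery cell and prefix length
#'
#' Produces the long-format per-sequence score table underlying the
#' benchmark: one row per (measure, variant, prefix length, sequence).
#' Undefined measures (e.g. the repetition gap of a sequence without any
#' repeat) yield `NA` scores, never zeros.
#'
#' @param data an [rng_sequence_set].
#' @param battery battery cells as returned by [measure_battery()]
#'   (default: the full battery).
#' @param lengths prefix lengths to sweep (default: the full sequence
#'   length only). Must be nondecreasing and at most the shortest sequence.
#' @param ctm_table a [ctm_table]; required when the battery contains
#'   CTM-based measures.
#' @return A data.frame with columns `measure`, `variant`,
#'   `prefix_length`, `sequence_id`, `source`, `score`.
#' @export
score_sequences <- function(data, battery = measure_battery(),
                            lengths = NULL, ctm_table = NULL) {
  stopifnot(inherits(data, "rng_sequence_set"))
  min_len <- min(vapply(data$sequences, length, integer(1)))
  if (is.null(lengths)) lengths <- min_len
  lengths <- as.integer(lengths)
  if (any(lengths < 2L) || any(lengths > min_len)) {
    stop(sprintf("prefix lengths must lie in 2..%d (the shortest sequence)",
                 min_len), call. = FALSE)
  }
  if (is.unsorted(lengths)) {
    stop("prefix lengths must be nondecreasing", call. = FALSE)
  }
  if (any(battery$requires_ctm) && is.null(ctm_table)) {
    stop(paste("the battery contains CTM-based measures but no 'ctm_table'",
               "was supplied; pass one or use synthetic_ctm_table()"),
         call. = FALSE)
  }
  ids <- vapply(data$sequences, function(s) s$id, character(1))
  out <- vector("list", length(lengths))
  for (li in seq_along(lengths)) {
    trunc <- truncate_prefix(data, lengths[li])
    scores <- matrix(NA_real_, nrow = nrow(battery),
                     ncol = length(trunc$sequences))
    for (si in seq_along(trunc$sequences)) {
      s <- trunc$sequences[[si]]
      for (bi in seq_len(nrow(battery))) {
        scores[bi, si] <- score_cell(battery$measure[bi],
                                     battery$variant[bi], s, ctm_table)
      }
    }
    out[[li]] <- data.frame(
      measure = rep(battery$measure, times = length(ids)),
      variant = rep(battery$variant, times = length(ids)),
      prefix_length = lengths[li],
      sequence_id = rep(ids, each = nrow(battery)),
      source = rep(data$source, each = nrow(battery)),
      score = as.vector(scores),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
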