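test_that("perfectly separated scores classify almost perfectly", {
  set.seed(10)
  scores <- c(stats::runif(40, 10, 11), stats::runif(40, 0, 1))
  labels <- rep(c("human", "random"), each = 40)
  r <- bootstrap_ccr(scores, labels, B = 100, seed = 5)
  expect_gt(r$mean_rate, 0.98)
  expect_gt(r$ci_lower, 0.95)
  expect_lte(r$ci_upper, 1)
})

test_that("scores from one common distribution perform at chance", {
  set.seed(11)
  scores <- stats::rnorm(200)
  labels <- rep(c("human", "random"), each = 100)
  r <- bootstrap_ccr(scores, labels, B = 200, seed = 6)
  expect_lte(r$ci_lower, 0.5)
  expect_gte(r$ci_upper, 0.5)
})

test_that("constant scores fall back to exact chance under balanced classes", {
  scores <- rep(3.7, 80)
  labels <- rep(c("human", "random"), 40)
  r <- bootstrap_ccr(scores, labels, B = 50, seed = 7)
  expect_true(all(r$rates == 0.5))
  expect_equal(r$mean_rate, 0.5)
})

test_that("bootstrap_ccr validates input and records exclusions", {
  expect_error(bootstrap_ccr(1:10, rep("human", 10), B = 100),
               "both a human and a random class")
  expect_error(bootstrap_ccr(1:4, rep(c("human", "random"), 2), B = 1),
               "at least 2")
  expect_error(bootstrap_ccr(1:4, c("human", "random", "robot", "human")),
               "human.*random")
  set.seed(12)
  scores <- c(stats::rnorm(30, 2), stats::rnorm(30), rep(NA_real_, 5))
  labels <- c(rep("human", 30), rep("random", 30), rep("human", 5))
  r <- bootstrap_ccr(scores, labels, B = 50, seed = 8)
  expect_equal(r$n_excluded, 5L)
  expect_equal(r$n_used, 60L)
})

test_that("bootstrap_ccr is reproducible and label-symmetric", {
  set.seed(13)
  scores <- c(stats::rnorm(50, 1), stats::rnorm(50))
  labels <- rep(c("human", "random"), each = 50)
  r1 <- bootstrap_ccr(scores, labels, B = 100, seed = 99)
  r2 <- bootstrap_ccr(scores, labels, B = 100, seed = 99)
  expect_identical(r1$rates, r2$rates)
  swapped <- ifelse(labels == "human", "random", "human")
  r3 <- bootstrap_ccr(scores, swapped, B = 100, seed = 99)
  expect_equal(r1$rates, r3$rates, tolerance = 1e-12)
})

test_that("CLES matches its tie convention and the exhaustive-pair oracle", {
  expect_equal(cles(5, 5), 0.5)
  expect_equal(cles(c(10, 11), c(1, 2)), 1)
  expect_equal(cles(c(1, 3), 2), 0.5)
  set.seed(14)
  for (rep in 1:25) {
    h <- sample(1:6, sample(3:30, 1), replace = TRUE)
    r <- sample(1:6, sample(3:30, 1), replace = TRUE)
    expect_equal(cles(h, r), o_cles(h, r))
    expect_gte(cles(h, r), 0)
    expect_lte(cles(h, r), 1)
  }
  expect_error(cles(numeric(0), 1), "nonempty")
})

test_that("the CI-overlap rule flags exactly the non-overlapping pairs", {
  expect_true(ci_nonoverlap(0.70, 0.75, 0.80, 0.85))
  expect_true(ci_nonoverlap(0.80, 0.85, 0.70, 0.75))
  expect_false(ci_nonoverlap(0.70, 0.81, 0.80, 0.85))
  expect_false(ci_nonoverlap(0.70, 0.80, 0.80, 0.85))  # touching overlaps
})

test_that("run_benchmark produces one structurally sound row per cell", {
  human <- generate_human_like(25, length = 60, seed = 41)
  random <- generate_uniform(25, length = 60, seed = 42)
  data <- rng_sequence_set(c(human$sequences, random$sequences),
                           c(human$source, random$source))
  tab <- synthetic_ctm_table(data, block_lengths = 2:3)
  bench <- run_benchmark(data, lengths = c(20L, 60L),
                         measures = c("coupon", "repetition_gap", "acss_mean",
                                      "runs"),
                         ctm_table = tab, B = 60, seed = 7,
                         block_lengths = 2:3)
  res <- bench$results
  # cells: coupon(1) + repetition_gap(3) + acss(2) + runs(1) = 7, x2 lengths
  expect_equal(nrow(res), 14L)
  expect_true(all(res$mean_rate >= 0 & res$mean_rate <= 1))
  expect_true(all(res$ci_lower <= res$ci_upper))
  expect_true(all(res$cles >= 0 & res$cles <= 1))
  expect_true(all(res$B == 60L))
  expect_equal(dim(bench$significance), c(14L, 14L))
  expect_equal(nrow(bench$scores), 14L * 50L)
  # bit-for-bit reproducibility of the whole benchmark under one seed
  bench2 <- run_benchmark(data, lengths = c(20L, 60L),
                          measures = c("coupon", "repetition_gap",
                                       "acss_mean", "runs"),
                          ctm_table = tab, B = 60, seed = 7,
                          block_lengths = 2:3)
  expect_identical(bench$results, bench2$results)
  expect_identical(bench$scores, bench2$scores)
})

test_that("run_benchmark enforces its configuration contracts", {
  onesided <- generate_uniform(10, length = 30, seed = 1)
  expect_error(run_benchmark(onesided, lengths = 20L, B = 10),
               "both human and random")
  human <- generate_human_like(5, length = 30, seed = 2)
  data <- rng_sequence_set(c(human$sequences, onesided$sequences[1:5]),
                           c(human$source, rep("random", 5)))
  expect_error(run_benchmark(data, lengths = 20L,
                             measures = c("bdm"), B = 10),
               "ctm_table")
  expect_error(run_benchmark(data, lengths = c(20L, 50L),
                             measures = "coupon", B = 10),
               "prefix lengths")
  expect_error(run_benchmark(data, lengths = 20L, measures = "poker",
                             B = 10),
               "unknown measure")
})

test_that("a separable and a chance measure get flagged as different", {
  human <- generate_human_like(
    60, length = 100, seed = 51,
    params = human_bias_params(0.2, 1, 1.5, 0))
  random <- generate_uniform(60, length = 100, seed = 52)
  data <- rng_sequence_set(c(human$sequences, random$sequences),
                           c(human$source, random$source))
  bench <- run_benchmark(data, lengths = 100L,
                         measures = c("coupon", "runs"), B = 150, seed = 3)
  pairs <- significant_pairs(bench)
  expect_true("coupon@100" %in% pairs$better)
  coupon_row <- bench$results[bench$results$measure == "coupon", ]
  runs_row <- bench$results[bench$results$measure == "runs", ]
  expect_gt(coupon_row$mean_rate, runs_row$mean_rate)
})

test_that("undefined scores are excluded per cell with counts in the report", {
  # short repeat-free sequences make the repetition gap undefined
  seqs <- c(
    list(rng_sequence(c(1, 2, 3, 4), id = "norep")),
    generate_human_like(20, length = 4, seed = 61)$sequences,
    generate_uniform(20, length = 4, seed = 62)$sequences)
  data <- rng_sequence_set(seqs, c("human", rep("human", 20),
                                   rep("random", 20)))
  sc <- score_sequences(data,
                        battery = measure_battery(measures = "repetition_gap"),
                        lengths = 4L)
  expect_true(anyNA(sc$score))
  expect_false(any(sc$score == 0, na.rm = TRUE))
})
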