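# Frozen worked examples for the psychological battery, followed by
# oracle-equivalence and calibration properties.

test_that("redundancy index hits its documented endpoints and Shannon arithmetic", {
  expect_equal(redundancy_index(rep(1:9, each = 20)), 0)
  expect_equal(redundancy_index(rep(4, 57)), 100)
  # a = 2, counts (3, 1): H = 0.8113, R = 18.87
  expect_equal(redundancy_index(c(1, 1, 1, 2), alphabet_size = 2),
               100 * (1 + 0.75 * log2(0.75) + 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(round(redundancy_index(c(1, 1, 1, 2), alphabet_size = 2), 2),
               18.87)
  expect_error(redundancy_index(c(1, 1), alphabet_size = 1), "at least 2")
})

test_that("RNG and RNG2 indices span their 0-100 range as documented", {
  db <- de_bruijn_sequence(9)
  expect_equal(rng_index(db), 0)
  expect_equal(rng_index(c(1, 2, 1, 2, 1, 2)), 100)
  # lag-2 pairs of 4-1-5-6 are exactly 4-5 and 1-6
  m <- pair_counts(c(4, 1, 5, 6), lag = 2)
  expect_equal(sum(m), 2L)
  expect_equal(m[4, 5], 1L)
  expect_equal(m[1, 6], 1L)
  expect_error(rng_index(c(1, 2), lag = 2), "no pairs")
})

test_that("null-score quotient counts absent ordered pairs over a^2", {
  expect_equal(null_score_quotient(de_bruijn_sequence(9)), 0)
  expect_equal(null_score_quotient(c(4, 1, 5, 6)), 100 * 78 / 81)
  expect_equal(null_score_quotient(c(1, 1, 1)), 100 * 80 / 81)
})

test_that("coupon score scans completed sets and penalizes missing responses", {
  no7 <- rep(c(1:6, 8:9), length.out = 200)
  expect_equal(coupon_score(no7), 201)
  expect_equal(coupon_score(1:9), 9)
  expect_equal(coupon_score(c(1, 2, 2, 3, 1, 3, 2), alphabet_size = 3), 3.5)
})

test_that("repetition gap pools per-response gaps; undefined without repeats", {
  expect_equal(repetition_gap(c(1, 2, 1)), 2)
  expect_equal(repetition_gap(c(1, 2, 1), "median"), 2)
  expect_equal(repetition_gap(c(1, 2, 1), "mode"), 2)
  expect_equal(repetition_gap(c(1, 1, 2, 1)), 1.5)
  expect_equal(repetition_gap(c(1, 1, 2, 1), "median"), 1.5)
  expect_equal(repetition_gap(c(1, 1, 2, 1), "mode"), 1)
  expect_error(repetition_gap(c(1, 2, 3, 4)),
               class = "rngbench_undefined_measure")
})

test_that("adjacency, turning point and runs indices match their worked examples", {
  expect_equal(adjacency_index(1:3, mode = "ascending"), 100)
  expect_equal(adjacency_index(1:3, mode = "descending"), 0)
  expect_equal(adjacency_index(c(7, 6, 4, 5)), 100 * 2 / 3)
  # no wrap: 9 -> 1 is not adjacent
  expect_equal(adjacency_index(c(9, 1, 9)), 0)

  # 1-3-5-4-3-7 has two turning points (5 and 3)
  expect_equal(turning_point_index(c(1, 3, 5, 4, 3, 7)),
               100 * 2 / ((2 / 3) * 4))
  expect_equal(turning_point_index(1:9), 0)
  expect_equal(turning_point_index(c(1, 2, 1, 2, 1)), 150)

  # 1-4-7-3-5 decomposes into ascending runs of lengths 3 and 2
  expect_equal(runs_index(c(1, 4, 7, 3, 5)), 0.25)
  expect_equal(runs_index(c(1, 4, 7, 3, 5), variance = "sample"), 0.5)
  expect_equal(runs_index(1:5), 0)
  expect_equal(runs_index(c(9, 8, 7)), 0)
  # equal successor breaks a run
  expect_equal(rngbench:::run_lengths(c(1, 2, 2, 3)), c(2L, 2L))
})

test_that("phi index is zero under saturation and negative under repeat avoidance", {
  for (d in 3:6) expect_equal(phi_index(rep(7, 30), d = d), 0)
  expect_lt(phi_index(rep(1:3, 10), d = 2), 0)
  expect_error(phi_index(1:4, d = 4), "too short")
  expect_error(phi_index(rep(1:5, 4), d = 11), "2..10")
})

test_that("every psychological measure agrees with a brute-force oracle", {
  set.seed(421)
  for (rep in 1:100) {
    s <- random_test_sequence()
    v <- s$values
    a <- s$alphabet_size
    expect_equal(redundancy_index(s), o_redundancy(v, a))
    expect_equal(rng_index(s, lag = 1), o_rng(v, 1L, a))
    if (length(v) >= 3) expect_equal(rng_index(s, lag = 2), o_rng(v, 2L, a))
    expect_equal(null_score_quotient(s), o_nsq(v, a))
    expect_equal(coupon_score(s), o_coupon(v, a))
    for (st in c("mean", "median", "mode")) {
      got <- tryCatch(repetition_gap(s, st),
                      rngbench_undefined_measure = function(e) NA_real_)
      expect_equal(got, o_repgap(v, st))
    }
    for (md in c("ascending", "descending", "combined")) {
      expect_equal(adjacency_index(s, mode = md), o_adjacency(v, md))
    }
    expect_equal(turning_point_index(s), o_turning(v))
    expect_equal(runs_index(s), o_runs(v))
    expect_equal(runs_index(s, variance = "sample"), o_runs(v, "sample"))
    for (d in 2:min(4, length(v) - 1)) {
      expect_equal(phi_index(s, d = d), o_phi(v, d, a))
    }
  }
})

test_that("range and pair-count invariants hold on random inputs", {
  set.seed(97)
  for (rep in 1:40) {
    s <- random_test_sequence(lo = 10)
    v <- s$values
    expect_gte(redundancy_index(s), 0)
    expect_lte(redundancy_index(s), 100)
    for (lag in 1:2) {
      r <- rng_index(s, lag = lag)
      expect_gte(r, 0)
      expect_lte(r, 100)
      expect_equal(sum(pair_counts(s, lag = lag)), length(v) - lag)
    }
    expect_gte(null_score_quotient(s), 0)
    expect_lte(null_score_quotient(s), 100)
    cs <- coupon_score(s)
    expect_gte(cs, s$alphabet_size)
    expect_lte(cs, length(v) + 1)
    gap <- tryCatch(repetition_gap(s),
                    rngbench_undefined_measure = function(e) NA_real_)
    if (!is.na(gap)) {
      expect_gte(gap, 1)
      expect_lte(gap, length(v) - 1)
    }
    adj <- adjacency_index(s)
    expect_gte(adj, 0)
    expect_lte(adj, 100)
  }
})

test_that("RNG index is relabeling-invariant while the adjacency index is not", {
  set.seed(1234)
  changed <- FALSE
  for (rep in 1:25) {
    s <- random_test_sequence(lo = 15)
    perm <- sample(9)
    relab <- rng_sequence(perm[s$values], alphabet_size = 9)
    expect_equal(rng_index(relab), rng_index(s), tolerance = 1e-12)
    expect_equal(rng_index(relab, lag = 2), rng_index(s, lag = 2),
                 tolerance = 1e-12)
    if (abs(adjacency_index(relab) - adjacency_index(s)) > 1e-9) {
      changed <- TRUE
    }
  }
  expect_true(changed)  # adjacency depends on numeric neighbourhood
})

test_that("i.i.d. uniform calibration: adjacency mean near 16/81, phi means near 0", {
  set.seed(2024)
  n <- 1000L
  pop <- generate_uniform(n, length = 200, seed = 515)
  adj <- vapply(pop$sequences, function(s) adjacency_index(s), numeric(1))
  se <- stats::sd(adj) / sqrt(n)
  expect_lt(abs(mean(adj) - 100 * 16 / 81), 3 * se)
  for (d in 2:10) {
    ph <- vapply(pop$sequences, function(s) phi_index(s, d = d), numeric(1))
    se <- stats::sd(ph) / sqrt(n)
    expect_lt(abs(mean(ph)), 3 * se)
  }
})
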