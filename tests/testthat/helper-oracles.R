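# Independent brute-force reimplementations of every measure, written as
# naive nested loops straight from the definitions. They deliberately share
# no code with the package implementations and serve as oracles in
# equivalence tests.

o_pair_counts <- function(v, lag, a) {
  m <- matrix(0L, a, a)
  for (i in seq_len(length(v) - lag)) {
    m[v[i], v[i + lag]] <- m[v[i], v[i + lag]] + 1L
  }
  m
}

o_redundancy <- function(v, a) {
  h <- 0
  for (s in 1:a) {
    p <- sum(v == s) / length(v)
    if (p > 0) h <- h - p * log2(p)
  }
  100 * (1 - h / log2(a))
}

o_rng <- function(v, lag, a) {
  m <- o_pair_counts(v, lag, a)
  num <- 0
  den <- 0
  for (i in 1:a) {
    for (j in 1:a) if (m[i, j] > 0) num <- num + m[i, j] * log(m[i, j])
    ri <- sum(m[i, ])
    if (ri > 0) den <- den + ri * log(ri)
  }
  if (den == 0) 0 else 100 * num / den
}

o_nsq <- function(v, a) {
  m <- o_pair_counts(v, 1L, a)
  z <- 0L
  for (i in 1:a) for (j in 1:a) if (m[i, j] == 0L) z <- z + 1L
  100 * z / a^2
}

o_coupon <- function(v, a) {
  seen <- integer(0)
  count <- 0L
  lens <- integer(0)
  for (x in v) {
    count <- count + 1L
    seen <- union(seen, x)
    if (length(seen) == a) {
      lens <- c(lens, count)
      seen <- integer(0)
      count <- 0L
    }
  }
  if (length(lens) == 0L) length(v) + 1 else mean(lens)
}

o_repgap <- function(v, stat) {
  gaps <- integer(0)
  for (i in seq_along(v)) {
    for (j in seq_along(v)) {
      if (j > i && v[j] == v[i]) {
        gaps <- c(gaps, j - i)
        break
      }
    }
  }
  if (length(gaps) == 0L) return(NA_real_)
  if (stat == "mean") return(mean(gaps))
  if (stat == "median") return(stats::median(gaps))
  best <- NA_integer_
  best_n <- -1L
  for (g in sort(unique(gaps))) {
    ng <- sum(gaps == g)
    if (ng > best_n) {
      best <- g
      best_n <- ng
    }
  }
  as.numeric(best)
}

o_adjacency <- function(v, mode) {
  hits <- 0L
  for (i in seq_len(length(v) - 1L)) {
    up <- v[i + 1L] == v[i] + 1L
    dn <- v[i + 1L] == v[i] - 1L
    hit <- switch(mode, ascending = up, descending = dn,
                  combined = up || dn)
    if (hit) hits <- hits + 1L
  }
  100 * hits / (length(v) - 1L)
}

o_turning <- function(v) {
  obs <- 0L
  for (i in 2:(length(v) - 1L)) {
    if ((v[i - 1L] < v[i] && v[i] > v[i + 1L]) ||
        (v[i - 1L] > v[i] && v[i] < v[i + 1L])) obs <- obs + 1L
  }
  100 * obs / ((2 / 3) * (length(v) - 2L))
}

o_runs <- function(v, type = "population") {
  lens <- integer(0)
  cur <- 1L
  for (i in seq_len(length(v) - 1L)) {
    if (v[i + 1L] > v[i]) {
      cur <- cur + 1L
    } else {
      lens <- c(lens, cur)
      cur <- 1L
    }
  }
  lens <- c(lens, cur)
  if (length(lens) < 2L) return(0)
  if (type == "population") mean((lens - mean(lens))^2) else stats::var(lens)
}

o_phi <- function(v, d, a) {
  n <- length(v)
  n_d <- n - d + 1L
  o_d <- 0L
  for (i in seq_len(n_d)) if (v[i] == v[i + d - 1L]) o_d <- o_d + 1L
  if (d == 2L) {
    e_d <- 0
    for (s in 1:a) {
      cs <- sum(v == s)
      e_d <- e_d + cs * (cs - 1)
    }
    e_d <- n_d * e_d / (n * (n - 1))
  } else {
    n_p <- n - d + 2L
    o_p <- 0L
    for (i in seq_len(n_p)) if (v[i] == v[i + d - 2L]) o_p <- o_p + 1L
    e_d <- n_d * o_p / n_p
  }
  100 * (o_d - e_d) / n_d
}

o_block_entropy <- function(v, k) {
  w <- length(v) - k + 1L
  keys <- character(w)
  for (i in seq_len(w)) keys[i] <- paste(v[i:(i + k - 1L)], collapse = ".")
  h <- 0
  for (key in unique(keys)) {
    p <- sum(keys == key) / w
    h <- h - p * log2(p)
  }
  h
}

o_canonical <- function(block) {
  seen <- integer(0)
  out <- integer(length(block))
  for (i in seq_along(block)) {
    pos <- match(block[i], seen)
    if (is.na(pos)) {
      seen <- c(seen, block[i])
      pos <- length(seen)
    }
    out[i] <- pos - 1L
  }
  paste(out, collapse = "")
}

o_acss_mean <- function(v, k, entries) {
  w <- length(v) - k + 1L
  vals <- numeric(w)
  for (i in seq_len(w)) {
    vals[i] <- entries[[o_canonical(v[i:(i + k - 1L)])]]
  }
  mean(vals)
}

o_bdm <- function(v, k, entries) {
  w <- length(v) - k + 1L
  keys <- character(w)
  for (i in seq_len(w)) keys[i] <- o_canonical(v[i:(i + k - 1L)])
  total <- 0
  for (key in unique(keys)) {
    total <- total + entries[[key]] + log2(sum(keys == key))
  }
  total
}

# exhaustive-history parse by direct substring search: a phrase grows while
# it can be copied from the history (i.e. occurs in the text up to the
# character before the phrase's current end)
o_lz76 <- function(v) {
  s <- paste(v, collapse = "")
  n <- nchar(s)
  count <- 0L
  p <- 1L
  while (p <= n) {
    q <- p
    while (q < n &&
           grepl(substr(s, p, q), substr(s, 1, q - 1L), fixed = TRUE)) {
      q <- q + 1L
    }
    count <- count + 1L
    p <- q + 1L
  }
  count
}

o_cles <- function(h, r) {
  comp <- outer(h, r, ">") + 0.5 * outer(h, r, "==")
  mean(comp)
}

# fixture table used across CTM tests: every canonical block of lengths
# 2..4, with complexity = number of distinct symbols (strictly positive and
# monotone in symbol richness)
fixture_ctm <- function(alphabet_size = 9L) {
  keys <- character(0)
  for (k in 2:4) {
    grid <- do.call(expand.grid, rep(list(1:k), k))
    keys <- c(keys, unique(apply(grid, 1, canonicalize_block)))
  }
  keys <- unique(keys)
  vals <- vapply(strsplit(keys, ""), function(x) length(unique(x)),
                 numeric(1))
  names(vals) <- keys
  ctm_table(vals, alphabet_size = alphabet_size, max_block_length = 4L)
}

# random test sequence of length between lo and hi on alphabet 1..a
random_test_sequence <- function(lo = 5L, hi = 50L, a = 9L) {
  n <- sample(lo:hi, 1L)
  rng_sequence(sample.int(a, n, replace = TRUE), alphabet_size = a)
}
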