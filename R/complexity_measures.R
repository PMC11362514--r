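#' Averaged algorithmic complexity over short blocks
#'
#' Slides a window of length `k` over the sequence, canonicalizes each
#' window (coding-theorem tables index permutation classes; see
#' [canonicalize_block()]), looks its complexity up in `table`, and returns
#' the mean of the `W = L - k + 1` values in bits. The coding-theorem
#' method approximates Kolmogorov-Chaitin complexity for short strings and
#' is consumed here as a lookup table input.
#'
#' @param seq an [rng_sequence] or integer vector.
#' @param k window length, integer in 2..10 (10 is the cutoff up to which
#'   coding-theorem tables for nine-symbol alphabets are complete).
#' @param table a [ctm_table] covering the sequence alphabet and length `k`.
#' @param alphabet_size used when `seq` is a bare vector.
#' @return Mean complexity in bits.
#' @export
acss_mean_complexity <- function(seq, k, table, alphabet_size = 9L) {
  keys <- ctm_window_keys(seq, k, table, alphabet_size)
  mean(ctm_lookup(table, keys))
}

#' Block decomposition method (BDM)
#'
#' Complexity of a sequence assembled from the coding-theorem complexities
#' of its distinct canonical length-`k` windows plus a logarithmic penalty
#' for multiplicity: over distinct blocks `b` with multiplicities `m_b`,
#' `BDM = sum(K(b) + log2(m_b))`. Repeating a block therefore adds only
#' `log2` of its frequency after the first occurrence, not its full
#' complexity again.
#'
#' @inheritParams acss_mean_complexity
#' @return BDM score in bits.
#' @export
bdm <- function(seq, k, table, alphabet_size = 9L) {
  keys <- ctm_window_keys(seq, k, table, alphabet_size)
  mult <- table(keys)
  uk <- names(mult)
  sum(ctm_lookup(table, uk) + log2(as.numeric(mult)))
}

# shared validation + canonical rolling-window keys for the CTM measures
ctm_window_keys <- function(seq, k, table, alphabet_size) {
  stopifnot(inherits(table, "ctm_table"))
  s <- as_rng_sequence(seq, alphabet_size)
  k <- as.integer(k)
  if (k < 2L || k > 10L) stop("'k' must lie in 2..10", call. = FALSE)
  if (k > length(s$values)) {
    stop(sprintf("window size %d exceeds the sequence length %d",
                 k, length(s$values)), call. = FALSE)
  }
  if (s$alphabet_size != table$alphabet_size) {
    stop(sprintf(
      "table alphabet size %d does not match the sequence alphabet size %d",
      table$alphabet_size, s$alphabet_size), call. = FALSE)
  }
  if (k > table$max_block_length) {
    stop(sprintf("table only covers blocks up to length %d",
                 table$max_block_length), call. = FALSE)
  }
  canonicalize_rows(rolling_windows(s$values, k))
}

#' Lempel-Ziv (1976) complexity
#'
#' Number of phrases in the exhaustive-history parse of the sequence,
#' computed with the Kaspar-Schuster pointer algorithm: each new phrase is
#' the shortest extension that cannot be reproduced by copying from the
#' prior history. Fewer phrases mean a more compressible, less random
#' sequence. The raw phrase count is returned without normalization.
#'
#' @inheritParams acss_mean_complexity
#' @return Integer phrase count, at least 1.
#' @examples
#' lz76_complexity(rep(1, 6))             # 2
#' lz76_complexity(rep(c(1, 2), 4))       # 3
#' @export
lz76_complexity <- function(seq, alphabet_size = 9L) {
  v <- as_rng_sequence(seq, alphabet_size)$values
  n <- length(v)
  if (n == 1L) return(1L)
  cmpl <- 1L
  l <- 1L
  i <- 0L
  k <- 1L
  k_max <- 1L
  repeat {
    if (v[i + k] == v[l + k]) {
      k <- k + 1L
      if (l + k > n) {
        cmpl <- cmpl + 1L
        break
      }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cmpl <- cmpl + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L
        k <- 1L
        k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cmpl
}

#' DEFLATE compressed length
#'
#' Encodes each response as one ASCII character (mirroring compression of
#' the printed digit string), compresses the result with R's
#' `memCompress(type = "gzip")` (a zlib-wrapped DEFLATE stream with no file
#' header or timestamp, hence deterministic for a fixed input), and returns
#' the compressed byte count. The absolute byte count carries container
#' overhead and is meaningful only as an ordinal score: systematic
#' sequences compress shorter than random ones.
#'
#' @inheritParams acss_mean_complexity
#' @return Compressed length in bytes.
#' @export
deflate_length <- function(seq, alphabet_size = 9L) {
  v <- as_rng_sequence(seq, alphabet_size)$values
  txt <- intToUtf8(v + 48L)  # 1..9 -> '1'..'9'; larger alphabets -> ':'...
  length(memCompress(charToRaw(txt), type = "gzip"))
}
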