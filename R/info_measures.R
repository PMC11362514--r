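#' Block entropy
#'
#' Shannon entropy (bits) of the distribution of overlapping length-`k`
#' windows of a sequence: the `W = L - k + 1` rolling windows (step 1, no
#' circular wrap) are counted and `H_k = -sum(p_b * log2(p_b))` is computed
#' over their relative frequencies. High values indicate an even use of
#' length-`k` response blocks; a sequence consisting of one response has
#' entropy 0. The supported block range is 2..10 (size 1 is excluded as
#' redundant with the redundancy index, which is a transformed single-
#' response entropy).
#'
#' @param seq an [rng_sequence] or integer vector.
#' @param k block (window) size, integer in 2..10 and at most the sequence
#'   length.
#' @param alphabet_size used when `seq` is a bare vector.
#' @return Entropy in bits, in `[0, log2(min(a^k, W))]`.
#' @examples
#' block_entropy(rep(4, 30), k = 3)           # 0
#' block_entropy(c(1, 2, 1, 2, 1, 2), k = 2)  # 0.971
#' @export
block_entropy <- function(seq, k, alphabet_size = 9L) {
  s <- as_rng_sequence(seq, alphabet_size)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L || k > 10L) {
    stop("block size 'k' must lie in 2..10", call. = FALSE)
  }
  v <- s$values
  if (k > length(v)) {
    stop(sprintf("block size %d exceeds the sequence length %d",
                 k, length(v)), call. = FALSE)
  }
  w <- rolling_windows(v, k)
  keys <- do.call(paste, c(split(w, col(w)), sep = ","))
  p <- as.numeric(table(keys)) / nrow(w)
  -sum(xlogx(p)) / log(2)
}
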