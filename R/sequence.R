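#' Construct a response sequence
#'
#' The universal input unit of the package: an ordered vector of integer
#' responses on a declared finite alphabet `1..alphabet_size`, as produced
#' one response at a time in a random number generation (RNG) task. The
#' alphabet is declared rather than inferred because several measures (e.g.
#' the redundancy index) must know the full set of admissible responses even
#' when a participant never used some of them; the task default is the
#' digits 1 to 9.
#'
#' @param values integer vector of responses; every value must lie in
#'   `1..alphabet_size` and the sequence must contain at least one response.
#' @param alphabet_size integer, number of admissible responses (default 9).
#' @param id opaque character label for the sequence.
#' @return An object of class `rng_sequence` with fields `values`,
#'   `alphabet_size` and `id`.
#' @examples
#' s <- rng_sequence(c(4, 1, 5, 6))
#' length(s)
#' @export
rng_sequence <- function(values, alphabet_size = 9L, id = "s1") {
  if (length(values) < 1L) {
    stop("a sequence must contain at least one response", call. = FALSE)
  }
  if (anyNA(values) || any(values != as.integer(values))) {
    stop("sequence values must be integers with no missing entries",
         call. = FALSE)
  }
  alphabet_size <- as.integer(alphabet_size)
  if (length(alphabet_size) != 1L || is.na(alphabet_size) ||
      alphabet_size < 1L) {
    stop("'alphabet_size' must be a single positive integer", call. = FALSE)
  }
  values <- as.integer(values)
  if (any(values < 1L) || any(values > alphabet_size)) {
    bad <- which(values < 1L | values > alphabet_size)[1L]
    stop(sprintf(
      "response %d at position %d lies outside the alphabet 1..%d",
      values[bad], bad, alphabet_size), call. = FALSE)
  }
  structure(
    list(values = values, alphabet_size = alphabet_size,
         id = as.character(id)),
    class = "rng_sequence"
  )
}

#' Coerce to an rng_sequence
#'
#' Plain integer vectors are accepted wherever a sequence is expected; this
#' helper performs that coercion with a declared alphabet.
#'
#' @param x an `rng_sequence` or a bare integer vector.
#' @param alphabet_size alphabet size used when coercing a bare vector;
#'   ignored (with the stored value kept) when `x` is already a sequence.
#' @return An `rng_sequence`.
#' @export
as_rng_sequence <- function(x, alphabet_size = 9L) {
  if (inherits(x, "rng_sequence")) return(x)
  rng_sequence(x, alphabet_size = alphabet_size)
}

#' @export
length.rng_sequence <- function(x) length(x$values)

#' @export
print.rng_sequence <- function(x, ...) {
  v <- x$values
  shown <- paste(utils::head(v, 15L), collapse = "-")
  if (length(v) > 15L) shown <- paste0(shown, "-...")
  cat(sprintf("<rng_sequence '%s'> length %d, alphabet 1..%d: %s\n",
              x$id, length(v), x$alphabet_size, shown))
  invisible(x)
}

#' Construct a labeled collection of sequences
#'
#' The benchmark input: sequences tagged with their generating source,
#' either `"human"` (a participant in an RNG task, or the human-biased
#' generator) or `"random"` (a random source, or the uniform generator).
#' All members must share one alphabet.
#'
#' @param sequences list of [rng_sequence] objects.
#' @param source character vector of per-sequence labels, each `"human"` or
#'   `"random"`, recycled if of length 1.
#' @return An object of class `rng_sequence_set`.
#' @examples
#' set <- rng_sequence_set(
#'   list(rng_sequence(c(1, 2, 3), id = "a"),
#'        rng_sequence(c(3, 3, 1), id = "b")),
#'   source = c("human", "random"))
#' length(set)
#' @export
rng_sequence_set <- function(sequences, source) {
  if (!is.list(sequences) || length(sequences) == 0L ||
      !all(vapply(sequences, inherits, logical(1), "rng_sequence"))) {
    stop("'sequences' must be a non-empty list of rng_sequence objects",
         call. = FALSE)
  }
  if (length(source) == 1L) source <- rep(source, length(sequences))
  if (length(source) != length(sequences)) {
    stop("'source' must have one label per sequence", call. = FALSE)
  }
  source <- as.character(source)
  if (!all(source %in% c("human", "random"))) {
    stop("source labels must be 'human' or 'random'", call. = FALSE)
  }
  alphas <- vapply(sequences, function(s) s$alphabet_size, integer(1))
  if (length(unique(alphas)) != 1L) {
    stop("all sequences in a set must share the same alphabet_size",
         call. = FALSE)
  }
  structure(
    list(sequences = sequences, source = source,
         alphabet_size = alphas[1L]),
    class = "rng_sequence_set"
  )
}

#' @export
length.rng_sequence_set <- function(x) length(x$sequences)

#' @export
print.rng_sequence_set <- function(x, ...) {
  tab <- table(factor(x$source, levels = c("human", "random")))
  lens <- range(vapply(x$sequences, length, integer(1)))
  cat(sprintf(
    "<rng_sequence_set> %d sequences (%d human, %d random), alphabet 1..%d, lengths %d..%d\n",
    length(x), tab[["human"]], tab[["random"]], x$alphabet_size,
    lens[1L], lens[2L]))
  invisible(x)
}

#' @export
as.data.frame.rng_sequence_set <- function(x, ...) {
  lens <- vapply(x$sequences, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("sequences must share one length to be laid out as a table",
         call. = FALSE)
  }
  mat <- do.call(rbind, lapply(x$sequences, function(s) s$values))
  colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  ids <- vapply(x$sequences, function(s) s$id, character(1))
  data.frame(id = ids, source = x$source, mat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Truncate a sequence (or every sequence in a set) to its first n responses
#'
#' Length sweeps analyse the first 20, 50 and 100 digits of full 200-digit
#' sequences; prefix truncation is the primitive behind those sweeps. The
#' alphabet and id are preserved.
#'
#' @param x an [rng_sequence] or [rng_sequence_set].
#' @param n number of leading responses to keep, `1 <= n <= length`.
#' @return Object of the same class as `x`.
#' @examples
#' truncate_prefix(rng_sequence(c(5, 2, 9, 1)), 2)
#' @export
truncate_prefix <- function(x, n) {
  UseMethod("truncate_prefix")
}

#' @export
truncate_prefix.rng_sequence <- function(x, n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > length(x$values)) {
    stop(sprintf(
      "prefix length must lie in 1..%d (the sequence length), got %s",
      length(x$values), deparse(substitute(n))), call. = FALSE)
  }
  rng_sequence(x$values[seq_len(n)], alphabet_size = x$alphabet_size,
               id = x$id)
}

#' @export
truncate_prefix.rng_sequence_set <- function(x, n) {
  rng_sequence_set(lapply(x$sequences, truncate_prefix, n = n),
                   source = x$source)
}

# internal accessors used by every measure
seq_values <- function(x) as_rng_sequence(x)$values
seq_alpha  <- function(x) as_rng_sequence(x)$alphabet_size

#' Linearized de Bruijn sequence of order 2
#'
#' Builds a sequence over `1..alphabet_size` in which every ordered response
#' pair occurs exactly once as a lag-1 pair (length `alphabet_size^2 + 1`).
#' This is the analytic extreme case for pair-based measures: the RNG index
#' and the null-score quotient both attain 0 on it. The sequence is the
#' Eulerian circuit of the complete transition graph (self-loops included),
#' found with Hierholzer's algorithm, and is deterministic.
#'
#' @param alphabet_size alphabet size (default 9, giving an 82-digit
#'   sequence covering all 81 ordered pairs).
#' @param id sequence label.
#' @return An [rng_sequence].
#' @examples
#' db <- de_bruijn_sequence(3)
#' length(db)  # 10: all 9 ordered pairs occur once
#' @export
de_bruijn_sequence <- function(alphabet_size = 9L, id = "debruijn2") {
  a <- as.integer(alphabet_size)
  if (a < 2L) stop("'alphabet_size' must be at least 2", call. = FALSE)
  unused <- matrix(TRUE, a, a)
  stack <- 1L
  circuit <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    nxt <- which(unused[v, ])
    if (length(nxt) > 0L) {
      w <- nxt[1L]
      unused[v, w] <- FALSE
      stack <- c(stack, w)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  rng_sequence(rev(circuit), alphabet_size = a, id = id)
}
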