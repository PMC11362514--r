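# Symbols used to render canonical block strings: supports up to 62 distinct
# responses within one block, far beyond the task alphabets in use.
.canon_symbols <- c(0:9, letters, LETTERS)

#' Canonicalize a block of responses
#'
#' Relabels the symbols of a block by order of first occurrence to
#' `0,1,2,...` and renders the result as a string: `4-1-5-4` becomes
#' `"0120"`. Published coding-theorem complexity tables are invariant under
#' relabeling of the alphabet and index these permutation classes, so every
#' lookup goes through this canonical form.
#'
#' @param block integer (or character) vector of symbols, nonempty.
#' @return Canonical string.
#' @examples
#' canonicalize_block(c(4, 1, 5, 4))  # "0120"
#' canonicalize_block(c(9, 9, 9))     # "000"
#' @export
canonicalize_block <- function(block) {
  if (length(block) == 0L) stop("block must be nonempty", call. = FALSE)
  idx <- match(block, unique(block))
  if (max(idx) > length(.canon_symbols)) {
    stop("block has more distinct symbols than can be rendered",
         call. = FALSE)
  }
  paste(.canon_symbols[idx], collapse = "")
}

# Canonicalize every row of a windows matrix (rows = rolling windows in
# left-to-right order). Vectorized over rows.
canonicalize_rows <- function(mat) {
  vapply(seq_len(nrow(mat)), function(i) canonicalize_block(mat[i, ]),
         character(1))
}

# Rolling windows of width k as a matrix with one window per row, columns in
# sequence order (embed() yields reversed columns, so re-order).
rolling_windows <- function(values, k) {
  if (k > length(values)) {
    stop(sprintf("window size %d exceeds sequence length %d",
                 k, length(values)), call. = FALSE)
  }
  if (k == 1L) return(matrix(values, ncol = 1L))
  stats::embed(values, k)[, k:1, drop = FALSE]
}

#' Construct a coding-theorem complexity table
#'
#' A mapping from canonical short strings (see [canonicalize_block()]) to
#' algorithmic-complexity values in bits, with the alphabet size and maximum
#' block length it covers. Values must be positive and keys canonical; a
#' hashed index is built once for fast window lookup.
#'
#' @param entries named numeric vector: names are canonical strings, values
#'   complexities in bits.
#' @param alphabet_size alphabet the table covers.
#' @param max_block_length longest key admitted.
#' @return An object of class `ctm_table`.
#' @export
ctm_table <- function(entries, alphabet_size, max_block_length) {
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("'entries' must be a fully named numeric vector", call. = FALSE)
  }
  if (anyNA(entries) || any(entries <= 0)) {
    stop("all complexity values must be positive", call. = FALSE)
  }
  keys <- names(entries)
  canon <- vapply(strsplit(keys, ""), canonicalize_block, character(1))
  if (any(canon != keys)) {
    bad <- keys[canon != keys][1L]
    stop(sprintf("key '%s' is not in first-occurrence canonical form", bad),
         call. = FALSE)
  }
  max_block_length <- as.integer(max_block_length)
  if (any(nchar(keys) > max_block_length)) {
    bad <- keys[nchar(keys) > max_block_length][1L]
    stop(sprintf("key '%s' exceeds max_block_length %d",
                 bad, max_block_length), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicate canonical keys in table", call. = FALSE)
  }
  index <- new.env(hash = TRUE, parent = emptyenv(),
                   size = length(entries))
  for (i in seq_along(entries)) assign(keys[i], entries[[i]], envir = index)
  structure(
    list(entries = entries, alphabet_size = as.integer(alphabet_size),
         max_block_length = max_block_length, index = index),
    class = "ctm_table"
  )
}

#' @export
print.ctm_table <- function(x, ...) {
  cat(sprintf(
    "<ctm_table> %d canonical blocks, alphabet size %d, max block length %d\n",
    length(x$entries), x$alphabet_size, x$max_block_length))
  invisible(x)
}

#' Look up complexity values for canonical keys
#'
#' @param table a [ctm_table].
#' @param keys character vector of canonical strings.
#' @return Numeric vector of complexities (bits); an error names the first
#'   key absent from the table.
#' @export
ctm_lookup <- function(table, keys) {
  stopifnot(inherits(table, "ctm_table"))
  hits <- mget(keys, envir = table$index, ifnotfound = NA_real_)
  vals <- unlist(hits, use.names = FALSE)
  if (anyNA(vals)) {
    stop(sprintf("block '%s' is missing from the complexity table",
                 keys[which(is.na(vals))[1L]]), call. = FALSE)
  }
  vals
}

#' Load a coding-theorem complexity table from TSV
#'
#' Expected format: header lines `#alphabet=<a>` and `#maxlen=<m>`, then one
#' `canonical-string<TAB>complexity` row per block. Keys are verified to be
#' canonical and values positive. The published acss-style tables can be
#' exported to this format; the packaged fixtures are synthetic.
#'
#' @param path TSV file path.
#' @return A [ctm_table].
#' @export
load_ctm_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("complexity table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^#", lines, value = TRUE)
  a_line <- grep("^#alphabet=", hdr, value = TRUE)
  m_line <- grep("^#maxlen=", hdr, value = TRUE)
  if (length(a_line) != 1L || length(m_line) != 1L) {
    stop("table header must contain exactly one '#alphabet=' and one '#maxlen=' line",
         call. = FALSE)
  }
  a <- as.integer(sub("^#alphabet=", "", a_line))
  m <- as.integer(sub("^#maxlen=", "", m_line))
  rows <- lines[!grepl("^#", lines)]
  if (length(rows) == 0L) stop("complexity table has no rows", call. = FALSE)
  parts <- strsplit(rows, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    bad <- which(lengths(parts) != 2L)[1L]
    stop(sprintf("malformed table row %d (expected key<TAB>value)", bad),
         call. = FALSE)
  }
  keys <- vapply(parts, `[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric complexity for key '%s'",
                 keys[which(is.na(vals))[1L]]), call. = FALSE)
  }
  if (any(vals <= 0)) {
    stop(sprintf("nonpositive complexity for key '%s'",
                 keys[which(vals <= 0)[1L]]), call. = FALSE)
  }
  names(vals) <- keys
  ctm_table(vals, alphabet_size = a, max_block_length = m)
}

#' Write a complexity table to TSV
#'
#' @param table a [ctm_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ctm_table <- function(table, path) {
  stopifnot(inherits(table, "ctm_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#alphabet=%d", table$alphabet_size),
               sprintf("#maxlen=%d", table$max_block_length)), con)
  writeLines(sprintf("%s\t%s", names(table$entries),
                     format(table$entries, digits = 15, trim = TRUE,
                            scientific = FALSE)),
             con)
  invisible(path)
}

#' Build a synthetic complexity table covering a dataset
#'
#' Published coding-theorem tables are external inputs. When none is
#' available, this constructor builds a clearly synthetic surrogate table
#' covering every canonical block that occurs in `data` at the requested
#' block lengths. The surrogate value for a canonical block `b` of length
#' `k` with `d` distinct symbols is
#' `lz76_complexity(b) * log2(1 + d) + log2(k)` bits: it increases with the
#' phrase-level irregularity of the block and with the number of distinct
#' symbols used, qualitatively matching the behaviour of coding-theorem
#' complexities (repetitive blocks cheap, symbol-rich irregular blocks
#' expensive). It is a stand-in for benchmarking machinery, not an
#' approximation of true algorithmic complexity, and is labelled synthetic
#' wherever it appears.
#'
#' @param data an [rng_sequence_set], [rng_sequence], or list of sequences.
#' @param block_lengths integer vector of block lengths to cover
#'   (default 2:10).
#' @return A [ctm_table].
#' @export
synthetic_ctm_table <- function(data, block_lengths = 2:10) {
  if (inherits(data, "rng_sequence")) data <- list(data)
  if (inherits(data, "rng_sequence_set")) {
    alpha <- data$alphabet_size
    data <- data$sequences
  } else {
    data <- lapply(data, as_rng_sequence)
    alpha <- max(vapply(data, function(s) s$alphabet_size, integer(1)))
  }
  block_lengths <- sort(unique(as.integer(block_lengths)))
  keys <- character(0)
  for (k in block_lengths) {
    for (s in data) {
      if (length(s$values) < k) next
      keys <- c(keys, canonicalize_rows(rolling_windows(s$values, k)))
    }
    keys <- unique(keys)
  }
  if (length(keys) == 0L) {
    stop("no blocks of the requested lengths occur in the data",
         call. = FALSE)
  }
  vals <- vapply(strsplit(keys, ""), function(sym) {
    codes <- match(sym, unique(sym))
    lz76_complexity(rng_sequence(codes, alphabet_size = max(codes))) *
      log2(1 + length(unique(sym))) + log2(length(sym))
  }, numeric(1))
  names(vals) <- keys
  ctm_table(vals, alphabet_size = alpha,
            max_block_length = max(block_lengths))
}
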