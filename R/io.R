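#' Read a sequence collection from a delimited text file
#'
#' The on-disk format is CSV with one sequence per row: an id column, a
#' source column (`human` or `random`), then the responses `v1..vL`. A
#' header row is expected by default (as written by [write_sequences()]).
#' Because deposited RNG datasets differ in column layout, the id/source
#' column positions can be remapped.
#'
#' @param path file path.
#' @param alphabet_size declared alphabet size (default 9). Ignored when
#'   `infer_alphabet = TRUE`.
#' @param infer_alphabet if `TRUE`, the alphabet size is the maximum
#'   observed response. Opt-in only: measures such as the redundancy index
#'   need the task alphabet even when some responses were never used.
#' @param header whether the first line is a header row.
#' @param sep field separator.
#' @param id_col,source_col 1-based positions of the id and source columns;
#'   all remaining columns are read as responses in order.
#' @return An [rng_sequence_set] preserving row order.
#' @export
read_sequences <- function(path, alphabet_size = 9L, infer_alphabet = FALSE,
                           header = TRUE, sep = ",",
                           id_col = 1L, source_col = 2L) {
  if (!file.exists(path)) {
    stop(sprintf("sequence file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header) lines <- lines[-1L]
  if (length(lines) == 0L) {
    stop(sprintf("no sequence rows in %s", path), call. = FALSE)
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(fields)
  if (length(unique(nfield)) != 1L) {
    bad <- which(nfield != nfield[1L])[1L]
    stop(sprintf(
      "ragged file: row %d has %d fields where row 1 has %d",
      bad, nfield[bad], nfield[1L]), call. = FALSE)
  }
  meta_cols <- c(id_col, source_col)
  if (nfield[1L] <= max(meta_cols)) {
    stop("rows contain no response columns beyond id/source", call. = FALSE)
  }
  value_cols <- setdiff(seq_len(nfield[1L]), meta_cols)

  parse_row <- function(row, toks) {
    vals <- trimws(toks[value_cols])
    ok <- grepl("^[0-9]+$", vals)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf(
        "row %d, response column %d: token '%s' is not an integer",
        row, bad, vals[bad]), call. = FALSE)
    }
    as.integer(vals)
  }
  values <- lapply(seq_along(fields),
                   function(i) parse_row(i, fields[[i]]))
  if (infer_alphabet) {
    alphabet_size <- max(vapply(values, max, integer(1)))
  }
  seqs <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    if (any(v < 1L | v > alphabet_size)) {
      bad <- which(v < 1L | v > alphabet_size)[1L]
      stop(sprintf(
        "row %d, response column %d: value %d outside the alphabet 1..%d",
        i, bad, v[bad], alphabet_size), call. = FALSE)
    }
    rng_sequence(v, alphabet_size = alphabet_size,
                 id = trimws(fields[[i]][id_col]))
  })
  source <- trimws(vapply(fields, `[`, character(1), source_col))
  rng_sequence_set(seqs, source = source)
}

#' Write a sequence collection to CSV
#'
#' Inverse of [read_sequences()]: writes a header `id,source,v1..vL` and one
#' row per sequence. All sequences must share one length.
#'
#' @param x an [rng_sequence_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path) {
  stopifnot(inherits(x, "rng_sequence_set"))
  df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' Configurations are YAML key-value files (seed, alphabet, prefix lengths,
#' bootstrap count, generator parameters). The file is read as-is; keys are
#' interpreted by the consumer (e.g. the command-line wrapper).
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' Write an analysis configuration file
#'
#' @param config named list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
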