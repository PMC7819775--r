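#' Word vector store
#'
#' Wraps a numeric matrix of word vectors (one row per word, rownames are the
#' words). Lookup of an absent word is distinguishable from a zero vector:
#' absent words are simply not rows of the matrix.
#'
#' @param vectors Numeric matrix with one row per word; rownames are words.
#' @return Object of class `"word_vector_store"` with elements `vectors`
#'   and `dimension`.
#' @export
word_vector_store <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (nrow(vectors) > 0L && is.null(rownames(vectors))) {
    stop("vector matrix must have words as rownames", call. = FALSE)
  }
  structure(list(vectors = vectors, dimension = ncol(vectors)),
            class = "word_vector_store")
}

#' @export
print.word_vector_store <- function(x, ...) {
  cat(sprintf("<word_vector_store: %d words, dimension %d>\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' The file starts with a header line `"<vocab_size> <dimension>"` followed by
#' one `"word v1 ... vD"` row per word. A duplicated word keeps the last
#' occurrence, with a warning.
#'
#' @param path Path to a word2vec-format text file.
#' @return A [word_vector_store()].
#' @export
load_word_vectors <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1L) stop("empty word-vector file", call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("malformed word2vec header: '", lines[1L], "'", call. = FALSE)
  }
  n <- as.integer(header[1L])
  d <- as.integer(header[2L])
  rows <- lines[-1L]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != n) {
    stop(sprintf("header announces %d words but file has %d rows", n,
                 length(rows)), call. = FALSE)
  }
  words <- character(n)
  mat <- matrix(0, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      stop(sprintf("row %d ('%s'): expected %d values, found %d",
                   i + 1L, parts[1L], d, length(parts) - 1L), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) {
      stop(sprintf("row %d: non-numeric vector component", i + 1L),
           call. = FALSE)
    }
    words[i] <- parts[1L]
    mat[i, ] <- vals
  }
  if (anyDuplicated(words)) {
    warning("duplicate words in vector file; keeping last occurrence",
            call. = FALSE)
    keep <- !duplicated(words, fromLast = TRUE)
    words <- words[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  rownames(mat) <- words
  word_vector_store(mat)
}

#' Write word vectors in word2vec text format
#'
#' @param store A [word_vector_store()].
#' @param path Output file path.
#' @param digits Significant digits used when printing components.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(store, path, digits = 17L) {
  mat <- store$vectors
  header <- sprintf("%d %d", nrow(mat), ncol(mat))
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(rownames(mat)[i],
          paste(formatC(mat[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Corpus word-frequency table
#'
#' Counts every token of every message of every chat (after normalization)
#' and derives relative frequencies p(w) = count(w) / total, the quantity the
#' SIF weight a / (a + p(w)) is built on.
#'
#' @param chats List of normalized `chat` objects.
#' @return Object of class `"frequency_table"`: list with `counts` (named
#'   integer vector), `total`, and `p` (named numeric vector summing to 1).
#' @export
compute_word_frequencies <- function(chats) {
  toks <- unlist(lapply(chats, function(ch) tokenize(ch$messages$text)),
                 use.names = FALSE)
  if (length(toks) == 0L) {
    stop("corpus contains no tokens; frequencies undefined", call. = FALSE)
  }
  tab <- table(toks)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  total <- sum(counts)
  structure(list(counts = counts, total = total, p = counts / total),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table: %d distinct words, %d tokens>\n",
              length(x$counts), x$total))
  invisible(x)
}
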