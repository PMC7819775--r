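#' Tokenize a normalized text
#'
#' Splits on whitespace, strips the retained punctuation characters
#' (`. , ? ! ' -`) from token edges (internal punctuation such as a hyphen in
#' a compound is kept), and drops empty tokens. Expects input already passed
#' through [normalize_text()].
#'
#' @param text Character vector of normalized texts.
#' @return Character vector of tokens (texts are concatenated).
#' @examples
#' tokenize("hoi!! hoe gaat het?")  # "hoi" "hoe" "gaat" "het"
#' @export
tokenize <- function(text) {
  toks <- unlist(strsplit(text, "\\s+"), use.names = FALSE)
  toks <- gsub("^[.,?!'-]+|[.,?!'-]+$", "", toks)
  toks[nzchar(toks)]
}

#' Embedding configuration
#'
#' @param sif_a SIF smoothing constant a in the weight a / (a + p(w));
#'   default 1e-3. Smaller values down-weight frequent words more
#'   aggressively; as a grows the embedding approaches a plain mean.
#' @param remove_common_component If `TRUE`, the first principal component of
#'   the corpus embedding matrix is removed from every embedding after
#'   averaging (off by default; the weighted average alone is the default
#'   pipeline).
#' @return A list of class `"embedding_config"`. The out-of-vocabulary
#'   policy is fixed to `"skip"`: tokens without a vector or corpus
#'   frequency contribute nothing, and the average is over kept tokens only.
#' @export
embedding_config <- function(sif_a = 1e-3, remove_common_component = FALSE) {
  stopifnot(is.numeric(sif_a), length(sif_a) == 1L, sif_a > 0)
  structure(list(sif_a = as.numeric(sif_a), oov_policy = "skip",
                 remove_common_component = isTRUE(remove_common_component)),
            class = "embedding_config")
}

#' Smooth-inverse-frequency embedding of a token sequence
#'
#' Computes `v = (1/n) * sum over kept tokens of [a / (a + p(w))] * vec(w)`,
#' where the kept tokens are those present in both the vector store and the
#' frequency table and n is their count. The weight is strictly decreasing in
#' p(w), so rarer (more informative) words contribute more. Tokens outside
#' the vocabulary are skipped; if no token survives, the zero vector is
#' returned with a warning.
#'
#' @param tokens Character vector of tokens (see [tokenize()]).
#' @param store A [word_vector_store()].
#' @param freqs A [compute_word_frequencies()] table.
#' @param config An [embedding_config()].
#' @return Numeric vector of the store's dimension, with attribute
#'   `token_count` (number of tokens actually embedded).
#' @export
sif_embed <- function(tokens, store, freqs, config = embedding_config()) {
  a <- config$sif_a
  kept <- tokens[tokens %in% rownames(store$vectors) &
                   tokens %in% names(freqs$p)]
  n <- length(kept)
  if (n == 0L) {
    warning("no embeddable tokens; returning zero vector", call. = FALSE)
    return(structure(numeric(store$dimension), token_count = 0L))
  }
  wts <- a / (a + freqs$p[kept])
  v <- colSums(store$vectors[kept, , drop = FALSE] * wts) / n
  structure(as.numeric(v), token_count = n)
}

#' Embed every window of a segmented corpus
#'
#' Each window's text is the concatenation of its messages' normalized texts;
#' the concatenation is tokenized and passed through [sif_embed()]. Windows
#' with no embeddable tokens yield zero vectors (flagged by token_count 0 and
#' excluded from ranking at query time).
#'
#' @param windows List of windows from [segment_corpus()].
#' @param store A [word_vector_store()].
#' @param freqs A [compute_word_frequencies()] table.
#' @param config An [embedding_config()].
#' @return List with `matrix` (#windows x dimension), and `metadata`
#'   (data frame with `chat_id`, `start`, `token_count`, one row per window,
#'   same order as input).
#' @export
embed_windows <- function(windows, store, freqs,
                          config = embedding_config()) {
  nw <- length(windows)
  mat <- matrix(0, nrow = nw, ncol = store$dimension)
  token_count <- integer(nw)
  for (i in seq_len(nw)) {
    toks <- tokenize(paste(windows[[i]]$texts, collapse = " "))
    v <- suppressWarnings(sif_embed(toks, store, freqs, config))
    mat[i, ] <- v
    token_count[i] <- attr(v, "token_count")
  }
  if (any(token_count == 0L) && nw > 0L) {
    warning(sum(token_count == 0L),
            " window(s) had no embeddable tokens (zero vectors)",
            call. = FALSE)
  }
  metadata <- data.frame(
    chat_id = vapply(windows, `[[`, character(1), "chat_id"),
    start = vapply(windows, `[[`, integer(1), "start"),
    token_count = token_count,
    stringsAsFactors = FALSE
  )
  if (config$remove_common_component && nw > 1L) {
    mat <- remove_first_component(mat)
  }
  list(matrix = mat, metadata = metadata)
}

# Remove the projection onto the first principal direction of the embedding
# matrix (no centering, following the usual SIF post-processing).
remove_first_component <- function(mat) {
  nonzero <- rowSums(mat != 0) > 0
  if (sum(nonzero) < 2L) return(mat)
  sv <- svd(mat[nonzero, , drop = FALSE], nu = 0, nv = 1)
  u <- sv$v[, 1L]
  mat - (mat %*% u) %*% t(u)
}

#' Embed the tail of an ongoing conversation
#'
#' Applies the identical normalize-tokenize-SIF pipeline used for the corpus
#' to the last `context_size` messages of the ongoing chat (all of them if
#' the chat is shorter).
#'
#' @param ongoing A `chat` object (the live conversation; raw text is
#'   normalized here).
#' @param store,freqs,config As in [sif_embed()].
#' @param context_size Number of trailing messages to embed, default 5.
#' @return Numeric query vector with attribute `token_count`.
#' @export
embed_query <- function(ongoing, store, freqs, config = embedding_config(),
                        context_size = 5L) {
  stopifnot(context_size >= 1L)
  m <- n_messages(ongoing)
  if (m == 0L) stop("ongoing chat has no messages", call. = FALSE)
  tail_idx <- (max(1L, m - as.integer(context_size) + 1L)):m
  txt <- normalize_text(ongoing$messages$text[tail_idx])
  toks <- tokenize(txt)
  v <- suppressWarnings(sif_embed(toks, store, freqs, config))
  if (attr(v, "token_count") == 0L) {
    stop("query has no embeddable content", call. = FALSE)
  }
  v
}
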