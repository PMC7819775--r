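#' Fit a content-based chat-segment recommender
#'
#' The central constructor of the package. Given a chat corpus and pretrained
#' word vectors it runs the full preparation pipeline: normalize all message
#' text, drop chats with fewer than `min_interactions` messages, tabulate
#' corpus word frequencies, segment every retained chat into overlapping
#' windows (stride 1), and embed each window by smooth-inverse-frequency
#' (SIF) weighted word-vector averaging. The result holds the embedding
#' index plus everything needed to answer queries and display matches.
#'
#' Use [predict.chat_recommender()] to retrieve, for an ongoing conversation,
#' the `top_k` most cosine-similar past windows to its last `context_size`
#' messages.
#'
#' @param corpus List of `chat` objects, or the path of a JSONL transcript
#'   file (see [read_corpus()]).
#' @param vectors A [word_vector_store()], or the path of a word2vec-format
#'   text file.
#' @param window_size Messages per window, default 5.
#' @param min_interactions Minimum chat length retained, default 20.
#' @param sif_a SIF smoothing constant, default 1e-3.
#' @param remove_common_component Remove the first principal component of the
#'   corpus embedding matrix (off by default).
#' @param keep_corpus Keep the filtered, normalized corpus inside the object
#'   so matched windows can be displayed with full context (default `TRUE`).
#' @return Object of class `"chat_recommender"`: list with `index` (an
#'   `embedding_index`), `store`, `freqs`, `seg_config`, `emb_config`, and
#'   (optionally) `corpus`.
#' @examples
#' sim <- simulate_helpline(synthetic_config(n_chats = 20, seed = 1))
#' rec <- chat_recommender(sim$chats, sim$store)
#' q <- generate_query(synthetic_config(n_chats = 20, seed = 1),
#'                     topic = 1, seed = 2)
#' predict(rec, q)
#' @export
chat_recommender <- function(corpus, vectors, window_size = 5L,
                             min_interactions = 20L, sif_a = 1e-3,
                             remove_common_component = FALSE,
                             keep_corpus = TRUE) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (is.character(vectors)) vectors <- load_word_vectors(vectors)
  stopifnot(inherits(vectors, "word_vector_store"))
  seg_config <- segmentation_config(window_size = window_size,
                                    min_interactions = min_interactions)
  emb_config <- embedding_config(sif_a = sif_a,
                                 remove_common_component =
                                   remove_common_component)
  corpus <- normalize_corpus(corpus)
  corpus <- filter_chats(corpus, seg_config$min_interactions)
  if (length(corpus) == 0L) {
    stop("no chats survive the minimum-length filter", call. = FALSE)
  }
  freqs <- compute_word_frequencies(corpus)
  windows <- segment_corpus(corpus, seg_config)
  embeddings <- suppressWarnings(
    embed_windows(windows, vectors, freqs, emb_config))
  index <- build_index(embeddings, seg_config, emb_config)
  structure(
    list(index = index, store = vectors, freqs = freqs,
         seg_config = seg_config, emb_config = emb_config,
         corpus = if (keep_corpus) corpus else NULL),
    class = "chat_recommender"
  )
}

#' @export
print.chat_recommender <- function(x, ...) {
  cat("Content-based chat-segment recommender\n")
  cat(sprintf("  corpus:  %d chats, %d windows of %d messages\n",
              length(unique(x$index$metadata$chat_id)),
              nrow(x$index$matrix), x$seg_config$window_size))
  cat(sprintf("  vectors: %d words, dimension %d\n",
              nrow(x$store$vectors), x$store$dimension))
  cat(sprintf("  SIF a = %g%s\n", x$emb_config$sif_a,
              if (x$emb_config$remove_common_component)
                ", common component removed" else ""))
  invisible(x)
}

#' @export
summary.chat_recommender <- function(object, ...) {
  meta <- object$index$metadata
  res <- list(
    n_chats = length(unique(meta$chat_id)),
    n_windows = nrow(meta),
    n_rankable = sum(object$index$rankable),
    dimension = object$store$dimension,
    vocab_size = nrow(object$store$vectors),
    corpus_vocab = length(object$freqs$counts),
    total_tokens = object$freqs$total,
    mean_tokens_per_window = mean(meta$token_count),
    sif_a = object$emb_config$sif_a
  )
  class(res) <- "summary.chat_recommender"
  res
}

#' @export
print.summary.chat_recommender <- function(x, ...) {
  cat("chat_recommender summary\n")
  cat(sprintf("  chats indexed:        %d\n", x$n_chats))
  cat(sprintf("  windows:              %d (%d rankable)\n",
              x$n_windows, x$n_rankable))
  cat(sprintf("  embedding dimension:  %d\n", x$dimension))
  cat(sprintf("  vector vocabulary:    %d words\n", x$vocab_size))
  cat(sprintf("  corpus vocabulary:    %d words / %d tokens\n",
              x$corpus_vocab, x$total_tokens))
  cat(sprintf("  tokens per window:    %.1f (mean embedded)\n",
              x$mean_tokens_per_window))
  cat(sprintf("  SIF a:                %g\n", x$sif_a))
  invisible(x)
}

#' Recommend similar past segments for an ongoing conversation
#'
#' Embeds the last `context_size` messages of `newdata` with the
#' recommender's own pipeline and returns the `top_k` most cosine-similar
#' indexed windows.
#'
#' @param object A [chat_recommender()].
#' @param newdata A `chat` object: the ongoing conversation.
#' @param top_k Number of recommendations, default 10.
#' @param context_size Trailing messages used as query, default 5.
#' @param dedup_per_chat At most one window per source chat (default `FALSE`).
#' @param exclude_chat_ids Source chats to omit (e.g. the ongoing chat's own
#'   id when it is part of the corpus).
#' @param ... Unused.
#' @return Data frame with `rank`, `chat_id`, `start`, `score`.
#' @export
predict.chat_recommender <- function(object, newdata, top_k = 10L,
                                     context_size = 5L,
                                     dedup_per_chat = FALSE,
                                     exclude_chat_ids = character(0), ...) {
  stopifnot(inherits(newdata, "chat"))
  qv <- embed_query(newdata, object$store, object$freqs, object$emb_config,
                    context_size = context_size)
  query_index(object$index, qv,
              query_config(top_k = top_k, context_size = context_size,
                           dedup_per_chat = dedup_per_chat,
                           exclude_chat_ids = exclude_chat_ids))
}
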