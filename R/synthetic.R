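# Run code under a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic helpline corpus
#'
#' Describes a topic-structured stand-in for a real helpline corpus: each
#' chat carries one latent topic (the help-seeker's problem), tokens are
#' drawn from that topic's vocabulary mixed with a shared vocabulary, and
#' word vectors are clustered around per-topic centroids so that windows
#' about the same problem are geometrically closer than random windows.
#' Every generated artifact is a pure function of this configuration and a
#' seed.
#'
#' @param n_chats Number of chats, default 200.
#' @param n_topics Number of latent topics, default 5.
#' @param chat_length_range Inclusive (lo, hi) message-count range, default
#'   c(20, 40) so every generated chat passes the default length filter.
#' @param vocab_per_topic Topic-specific words per topic, default 40.
#' @param shared_vocab Words common to all topics (function words), default
#'   20.
#' @param tokens_per_message_range Inclusive token-count range per message,
#'   default c(5, 12).
#' @param vector_dimension Word-vector dimension, default 25.
#' @param topic_separation Centroid norm in units of `noise_sd`; 0 removes
#'   all topic structure from the vectors, larger values separate the topic
#'   clusters. Default 3.
#' @param noise_sd Per-coordinate s.d. of word-vector noise, default 0.3.
#' @param shared_rate Probability a token is drawn from the shared
#'   vocabulary, default 0.3.
#' @param seed Base RNG seed, default 1.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_chats = 200L, n_topics = 5L,
                             chat_length_range = c(20L, 40L),
                             vocab_per_topic = 40L, shared_vocab = 20L,
                             tokens_per_message_range = c(5L, 12L),
                             vector_dimension = 25L, topic_separation = 3,
                             noise_sd = 0.3, shared_rate = 0.3, seed = 1L) {
  stopifnot(n_chats >= 1L, n_topics >= 1L,
            length(chat_length_range) == 2L,
            chat_length_range[1] <= chat_length_range[2],
            vocab_per_topic >= 1L, shared_vocab >= 0L,
            length(tokens_per_message_range) == 2L,
            tokens_per_message_range[1] >= 1L,
            tokens_per_message_range[1] <= tokens_per_message_range[2],
            vector_dimension >= 1L, topic_separation >= 0, noise_sd > 0,
            shared_rate >= 0, shared_rate <= 1)
  structure(list(
    n_chats = as.integer(n_chats), n_topics = as.integer(n_topics),
    chat_length_range = as.integer(chat_length_range),
    vocab_per_topic = as.integer(vocab_per_topic),
    shared_vocab = as.integer(shared_vocab),
    tokens_per_message_range = as.integer(tokens_per_message_range),
    vector_dimension = as.integer(vector_dimension),
    topic_separation = as.numeric(topic_separation),
    noise_sd = as.numeric(noise_sd),
    shared_rate = as.numeric(shared_rate),
    seed = as.integer(seed)),
    class = "synthetic_config")
}

topic_vocabulary <- function(config, topic) {
  sprintf("t%dw%02d", topic, seq_len(config$vocab_per_topic))
}

shared_vocabulary <- function(config) {
  if (config$shared_vocab == 0L) character(0)
  else sprintf("sw%02d", seq_len(config$shared_vocab))
}

#' Generate topic-clustered word vectors
#'
#' Each topic receives a random unit centroid scaled to norm
#' `topic_separation * noise_sd`; each of its words gets the centroid plus
#' isotropic gaussian noise of s.d. `noise_sd`. Shared words sit around the
#' origin (the global mean of the centroids in expectation) with the same
#' noise. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `store` (a [word_vector_store()]) and `word_topic`
#'   (named character vector mapping each word to its topic label
#'   `"1"`..`"n_topics"` or `"shared"`).
#' @export
generate_vectors <- function(config) {
  d <- config$vector_dimension
  with_seed(config$seed, {
    centroids <- matrix(stats::rnorm(config$n_topics * d),
                        nrow = config$n_topics)
    centroids <- centroids / sqrt(rowSums(centroids^2)) *
      (config$topic_separation * config$noise_sd)
    words <- character(0)
    topics <- character(0)
    rows <- list()
    for (t in seq_len(config$n_topics)) {
      wt <- topic_vocabulary(config, t)
      noise <- matrix(stats::rnorm(length(wt) * d, sd = config$noise_sd),
                      nrow = length(wt))
      rows[[t]] <- sweep(noise, 2L, centroids[t, ], `+`)
      words <- c(words, wt)
      topics <- c(topics, rep(as.character(t), length(wt)))
    }
    sh <- shared_vocabulary(config)
    if (length(sh)) {
      rows[[config$n_topics + 1L]] <-
        matrix(stats::rnorm(length(sh) * d, sd = config$noise_sd),
               nrow = length(sh))
      words <- c(words, sh)
      topics <- c(topics, rep("shared", length(sh)))
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- words
    names(topics) <- words
    list(store = word_vector_store(mat), word_topic = topics)
  })
}

# Draw the texts of one chat/query: token counts per message, topic-vs-shared
# mixture per token, uniform word choice within the chosen vocabulary.
draw_messages <- function(config, topic, n_msg) {
  tv <- topic_vocabulary(config, topic)
  sv <- shared_vocabulary(config)
  rng <- config$tokens_per_message_range
  lens <- sample(rng[1]:rng[2], n_msg, replace = TRUE)
  vapply(lens, function(len) {
    toks <- sample(tv, len, replace = TRUE)
    if (length(sv) > 0 && config$shared_rate > 0) {
      use_shared <- stats::runif(len) < config$shared_rate
      if (any(use_shared)) {
        toks[use_shared] <- sample(sv, sum(use_shared), replace = TRUE)
      }
    }
    paste(toks, collapse = " ")
  }, character(1))
}

#' Generate a synthetic chat corpus
#'
#' Each chat draws one topic uniformly; senders alternate help-seeker /
#' counselor starting with the help-seeker; message counts fall in
#' `chat_length_range` and every token comes from the chat's topic
#' vocabulary or the shared vocabulary. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `chats` (list of `chat`) and `chat_topic` (named
#'   character vector chat_id -> topic label).
#' @export
generate_corpus <- function(config) {
  with_seed(config$seed + 1L, {
    lo <- config$chat_length_range[1]
    hi <- config$chat_length_range[2]
    chats <- vector("list", config$n_chats)
    chat_topic <- character(config$n_chats)
    ids <- sprintf("chat%04d", seq_len(config$n_chats))
    for (i in seq_len(config$n_chats)) {
      topic <- sample.int(config$n_topics, 1L)
      m <- sample(lo:hi, 1L)
      texts <- draw_messages(config, topic, m)
      senders <- rep_len(c("helpseeker", "counselor"), m)
      chats[[i]] <- chat(ids[i], senders, texts)
      chat_topic[i] <- as.character(topic)
    }
    names(chat_topic) <- ids
    list(chats = chats, chat_topic = chat_topic)
  })
}

#' Generate an ongoing-chat query fixture
#'
#' A short chat drawn from one topic's token distributions, standing in for
#' the live conversation whose tail is embedded as the query.
#'
#' @param config A [synthetic_config()].
#' @param topic Topic label (integer in 1..n_topics or its string form).
#' @param seed Seed for this query (independent of the corpus seed).
#' @param n_messages Number of messages, default 5.
#' @return A `chat` with id `"query-<topic>-<seed>"`.
#' @export
generate_query <- function(config, topic, seed, n_messages = 5L) {
  topic <- as.integer(topic)
  if (is.na(topic) || topic < 1L || topic > config$n_topics) {
    stop("unknown topic: must be in 1..", config$n_topics, call. = FALSE)
  }
  stopifnot(n_messages >= 1L)
  with_seed(seed, {
    texts <- draw_messages(config, topic, as.integer(n_messages))
    senders <- rep_len(c("helpseeker", "counselor"), n_messages)
    chat(sprintf("query-%d-%d", topic, as.integer(seed)), senders, texts)
  })
}

#' Generate a complete synthetic study set
#'
#' Convenience wrapper running [generate_vectors()] and [generate_corpus()]
#' on one configuration.
#'
#' @param config A [synthetic_config()].
#' @return List with `chats`, `store`, `chat_topic`, `word_topic`, `config`.
#' @export
simulate_helpline <- function(config = synthetic_config()) {
  vec <- generate_vectors(config)
  cor <- generate_corpus(config)
  list(chats = cor$chats, store = vec$store, chat_topic = cor$chat_topic,
       word_topic = vec$word_topic, config = config)
}

#' Write / read the ground-truth sidecar
#'
#' One JSON object per chat: `{"chat_id": "...", "topic": "..."}`.
#'
#' @param chat_topic Named character vector chat_id -> topic label.
#' @param path File path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the named character vector.
#' @export
write_ground_truth <- function(chat_topic, path) {
  lines <- vapply(seq_along(chat_topic), function(i) {
    jsonlite::toJSON(list(chat_id = names(chat_topic)[i],
                          topic = unname(chat_topic[i])),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    ids[i] <- rec$chat_id
    out[i] <- as.character(rec$topic)
  }
  names(out) <- ids
  out
}
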