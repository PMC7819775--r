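# Shared fixtures and independent oracles used across the suite.

# A deterministic little vector store over the given words.
tiny_store <- function(words, d = 4L, seed = 1L) {
  set.seed(seed)
  mat <- matrix(rnorm(length(words) * d), nrow = length(words),
                dimnames = list(words, NULL))
  word_vector_store(mat)
}

# A chat whose m messages are "msg<i> filler" with alternating senders.
dummy_chat <- function(id, m, word = "msg") {
  chat(id,
       rep_len(c("helpseeker", "counselor"), m),
       sprintf("%s%d filler", word, seq_len(m)))
}

# Frequency table built directly from explicit counts (bypasses the corpus
# path so embedding tests control p(w) exactly).
freq_from_counts <- function(counts) {
  structure(list(counts = counts, total = sum(counts),
                 p = counts / sum(counts)),
            class = "frequency_table")
}

# Naive one-line SIF re-computation: the oracle for sif_embed().
naive_sif <- function(tokens, store, freqs, a) {
  kept <- tokens[tokens %in% rownames(store$vectors) &
                   tokens %in% names(freqs$p)]
  if (length(kept) == 0L) return(numeric(store$dimension))
  acc <- numeric(store$dimension)
  for (w in kept) {
    acc <- acc + (a / (a + freqs$p[[w]])) * store$vectors[w, ]
  }
  acc / length(kept)
}

# Exhaustive brute-force cosine scan: the oracle for query_index(). Scores
# every rankable row one at a time with cosine_similarity(), sorts by
# (-score, chat_id, start) and truncates.
brute_force_query <- function(index, query_vec, top_k = 10L,
                              dedup_per_chat = FALSE,
                              exclude_chat_ids = character(0)) {
  rows <- which(index$rankable &
                  !(index$metadata$chat_id %in% exclude_chat_ids))
  scores <- vapply(rows, function(i) {
    cosine_similarity(index$matrix[i, ], query_vec)
  }, numeric(1))
  meta <- index$metadata[rows, , drop = FALSE]
  ord <- order(-scores, meta$chat_id, meta$start)
  meta <- meta[ord, , drop = FALSE]
  scores <- scores[ord]
  if (dedup_per_chat) {
    keep <- !duplicated(meta$chat_id)
    meta <- meta[keep, , drop = FALSE]
    scores <- scores[keep]
  }
  k <- min(top_k, length(scores))
  data.frame(rank = seq_len(k), chat_id = meta$chat_id[seq_len(k)],
             start = meta$start[seq_len(k)], score = scores[seq_len(k)],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Small fitted recommender over a synthetic corpus, reused where a full
# pipeline object is needed.
small_recommender <- function(n_chats = 30L, seed = 7L, ...) {
  cfg <- synthetic_config(n_chats = n_chats, seed = seed, ...)
  sim <- simulate_helpline(cfg)
  list(cfg = cfg, sim = sim,
       rec = chat_recommender(sim$chats, sim$store))
}
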