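test_that("word2vec text format round-trips through load/write", {
  store <- tiny_store(c("aap", "noot", "mies"), d = 4L, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(store, path)
  back <- load_word_vectors(path)
  expect_equal(back$dimension, 4L)
  expect_equal(rownames(back$vectors), c("aap", "noot", "mies"))
  expect_equal(back$vectors, store$vectors, tolerance = 1e-12)

  # dimension mismatch reported with the row
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 4", "aap 1 2 3 4", "noot 1 2 3"), bad)
  expect_error(load_word_vectors(bad), "row 3.*expected 4")

  # empty vocabulary is legal
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 4", empty)
  es <- load_word_vectors(empty)
  expect_equal(nrow(es$vectors), 0L)
  expect_equal(es$dimension, 4L)

  # duplicate word: last occurrence wins, with a warning
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 2", "aap 1 1", "aap 2 2"), dup)
  expect_warning(ds <- load_word_vectors(dup), "duplicate")
  expect_equal(unname(ds$vectors["aap", ]), c(2, 2))
})

test_that("tokenize splits on whitespace and strips edge punctuation", {
  expect_equal(tokenize("hoi!! hoe gaat het?"), c("hoi", "hoe", "gaat", "het"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("a-b"), "a-b")
  expect_equal(tokenize("'quoted' word."), c("quoted", "word"))
  expect_equal(tokenize(c("twee teksten", "drie woorden hier")),
               c("twee", "teksten", "drie", "woorden", "hier"))
})

test_that("word frequencies are relative counts over the whole corpus", {
  chats <- list(chat("c1", c("helpseeker", "counselor"), c("a a", "b c")))
  ft <- compute_word_frequencies(chats)
  expect_equal(ft$total, 4L)
  expect_equal(ft$p[["a"]], 0.5)
  expect_equal(ft$p[["b"]], 0.25)
  expect_equal(ft$p[["c"]], 0.25)
  expect_equal(sum(ft$p), 1)

  single <- list(chat("c1", "helpseeker", "woord"))
  expect_equal(compute_word_frequencies(single)$p[["woord"]], 1)

  none <- list(chat("c1", "helpseeker", "!!"))
  expect_error(compute_word_frequencies(none), "no tokens")
})

test_that("uniform synthetic corpus gives p(w) = 1/V for every word", {
  # brute-force oracle: count tokens of a corpus drawn from one vocabulary,
  # all words forced equally frequent by construction
  words <- sprintf("w%02d", 1:10)
  texts <- vapply(split(rep(words, 6), rep(1:20, each = 3)),
                  paste, character(1), collapse = " ")
  chats <- list(chat("c1", rep_len(c("helpseeker", "counselor"), 20), texts))
  ft <- compute_word_frequencies(chats)
  expect_equal(unname(ft$p[words]), rep(1 / 10, 10))
})

test_that("sif_embed matches the naive weighted-average oracle", {
  store <- tiny_store(sprintf("w%d", 1:12), d = 6L, seed = 3)
  set.seed(4)
  counts <- setNames(sample(1:50, 12, replace = TRUE), sprintf("w%d", 1:12))
  freqs <- freq_from_counts(counts)
  cfg <- embedding_config(sif_a = 1e-3)
  for (i in 1:25) {
    toks <- sample(c(sprintf("w%d", 1:12), "oov1", "oov2"),
                   sample(1:10, 1), replace = TRUE)
    got <- suppressWarnings(sif_embed(toks, store, freqs, cfg))
    want <- naive_sif(toks, store, freqs, 1e-3)
    expect_equal(unname(as.numeric(got)), unname(want), tolerance = 1e-12)
  }
})

test_that("single-token SIF weight equals a/(a+p) exactly", {
  store <- word_vector_store(matrix(c(2, -4, 6), nrow = 1,
                                    dimnames = list("zelf", NULL)))
  freqs <- freq_from_counts(c(zelf = 1L, ander = 99L))  # p(zelf) = 0.01
  v <- sif_embed("zelf", store, freqs, embedding_config(sif_a = 1e-3))
  expect_equal(as.numeric(v), (0.001 / 0.011) * c(2, -4, 6),
               tolerance = 1e-12)
  expect_equal(attr(v, "token_count"), 1L)
})

test_that("equal-frequency tokens reduce to a scaled plain mean", {
  store <- tiny_store(c("p", "q", "r"), d = 5L, seed = 5)
  freqs <- freq_from_counts(c(p = 7L, q = 7L, r = 7L))
  a <- 1e-3
  p <- 1 / 3
  v <- sif_embed(c("p", "q", "r"), store, freqs, embedding_config(sif_a = a))
  expect_equal(as.numeric(v),
               unname((a / (a + p)) * colMeans(store$vectors)),
               tolerance = 1e-12)
})

test_that("as a grows the SIF embedding approaches the unweighted mean", {
  store <- tiny_store(sprintf("w%d", 1:6), d = 4L, seed = 6)
  counts <- setNames(c(1L, 2L, 4L, 8L, 16L, 32L), sprintf("w%d", 1:6))
  freqs <- freq_from_counts(counts)
  toks <- sprintf("w%d", 1:6)
  v <- sif_embed(toks, store, freqs, embedding_config(sif_a = 1e6))
  mean_vec <- colMeans(store$vectors)
  expect_lt(sqrt(sum((as.numeric(v) - mean_vec)^2)) /
              sqrt(sum(mean_vec^2)), 1e-6)
})

test_that("SIF weight is strictly decreasing in word frequency", {
  for (a in c(1e-4, 1e-3, 1e-2, 1)) {
    p <- sort(runif(20))
    w <- a / (a + p)
    expect_true(all(diff(w) < 0))
  }
})

test_that("OOV tokens are skipped and all-OOV yields a flagged zero vector", {
  store <- tiny_store(c("in"), d = 3L, seed = 7)
  freqs <- freq_from_counts(c(in_corpus = 5L, `in` = 5L))
  expect_warning(v <- sif_embed(c("uit", "weg"), store, freqs),
                 "no embeddable")
  expect_equal(as.numeric(v), c(0, 0, 0))
  expect_equal(attr(v, "token_count"), 0L)
  # a token missing from either the store or the table is skipped
  v2 <- sif_embed(c("in", "uit"), store, freqs)
  expect_equal(attr(v2, "token_count"), 1L)
})

test_that("embed_windows preserves order, metadata and bag-of-words laws", {
  s <- small_recommender(n_chats = 3L, seed = 9L)
  chats <- normalize_corpus(s$sim$chats)
  freqs <- compute_word_frequencies(chats)
  windows <- segment_corpus(chats, segmentation_config())
  emb <- embed_windows(windows, s$sim$store, freqs)
  expect_equal(nrow(emb$matrix), length(windows))
  expect_equal(emb$metadata$chat_id,
               vapply(windows, `[[`, character(1), "chat_id"))
  expect_equal(emb$metadata$start,
               vapply(windows, `[[`, integer(1), "start"))

  # determinism: identical window -> identical vector
  w1 <- windows[[1]]
  dup <- embed_windows(list(w1, w1), s$sim$store, freqs)
  expect_identical(dup$matrix[1, ], dup$matrix[2, ])

  # order invariance: shuffling a window's tokens leaves the vector alone
  toks <- tokenize(paste(w1$texts, collapse = " "))
  set.seed(1)
  v1 <- sif_embed(toks, s$sim$store, freqs)
  v2 <- sif_embed(sample(toks), s$sim$store, freqs)
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-12)

  # scale law: scaling every stored vector scales every embedding
  scaled <- word_vector_store(s$sim$store$vectors * 3)
  emb3 <- embed_windows(windows[1:10], scaled, freqs)
  expect_equal(emb3$matrix, embed_windows(windows[1:10], s$sim$store,
                                          freqs)$matrix * 3,
               tolerance = 1e-12)
})

test_that("common-component removal leaves embeddings orthogonal to it", {
  s <- small_recommender(n_chats = 4L, seed = 10L)
  chats <- normalize_corpus(s$sim$chats)
  freqs <- compute_word_frequencies(chats)
  windows <- segment_corpus(chats, segmentation_config())
  emb <- embed_windows(windows, s$sim$store, freqs,
                       embedding_config(remove_common_component = TRUE))
  sv <- svd(embed_windows(windows, s$sim$store, freqs)$matrix, nu = 0, nv = 1)
  proj <- abs(emb$matrix %*% sv$v[, 1])
  expect_lt(max(proj), 1e-8)
})

test_that("embed_query uses only the conversation tail", {
  s <- small_recommender(n_chats = 3L, seed = 12L)
  chats <- normalize_corpus(s$sim$chats)
  freqs <- compute_word_frequencies(chats)
  ongoing <- chats[[1]]
  m <- n_messages(ongoing)
  qv <- embed_query(ongoing, s$sim$store, freqs, context_size = 5L)
  tail5 <- chat("tail", rep("helpseeker", 5), ongoing$messages$text[(m - 4):m])
  qv_tail <- embed_query(tail5, s$sim$store, freqs, context_size = 5L)
  expect_equal(as.numeric(qv), as.numeric(qv_tail), tolerance = 1e-12)

  # shorter than the context: embeds all messages
  short <- chat("s", rep("helpseeker", 3), ongoing$messages$text[1:3])
  expect_equal(as.numeric(embed_query(short, s$sim$store, freqs)),
               as.numeric(sif_embed(tokenize(ongoing$messages$text[1:3]),
                                    s$sim$store, freqs)),
               tolerance = 1e-12)

  no_content <- chat("z", "helpseeker", "!!")
  expect_error(embed_query(no_content, s$sim$store, freqs),
               "no embeddable content")
})
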