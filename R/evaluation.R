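#' Precision at k against ground-truth topics
#'
#' Fraction of the top-k retrieved windows whose source chat shares the
#' query's topic — the in-silico stand-in for a counselor judging that the
#' matched segment is about the same problem as the ongoing chat.
#'
#' @param results Retrieval results (data frame with `chat_id`, ranked), as
#'   returned by [query_index()] / [predict.chat_recommender()].
#' @param chat_topic Named character vector chat_id -> topic label (ground
#'   truth).
#' @param query_topic The query's topic label.
#' @param k Cutoff, default 10 (at most the number of results available).
#' @return Numeric in `[0, 1]`.
#' @export
precision_at_k <- function(results, chat_topic, query_topic, k = 10L) {
  stopifnot(k >= 1L)
  if (nrow(results) == 0L) stop("empty result set", call. = FALSE)
  top <- results$chat_id[seq_len(min(k, nrow(results)))]
  mean(chat_topic[top] == as.character(query_topic))
}

#' Run one matched-versus-random validity trial
#'
#' Mirrors the validity design of the original study: a trial presents 10
#' segments for one ongoing chat, half retrieved by the embedding algorithm
#' (the top `n_matched` recommendations) and half drawn uniformly at random
#' from the remaining rankable windows. Each segment receives an oracle
#' score from ground truth: 1 if its source chat shares the query's topic,
#' 0 otherwise (replacing the study's human 1-7 similarity ratings).
#'
#' @param rec A fitted [chat_recommender()].
#' @param chat_topic Named character vector chat_id -> topic label.
#' @param query A `chat`: the ongoing conversation.
#' @param query_topic The query's ground-truth topic label.
#' @param n_matched,n_random Segments per arm, default 5 each.
#' @param seed Seed for the random arm.
#' @return Object of class `"validity_trial"`: list with `query_chat_id`,
#'   `query_topic`, and `segments` (data frame with `chat_id`, `start`,
#'   `source` in {"matched", "random"}, `score`).
#' @export
run_validity_trial <- function(rec, chat_topic, query, query_topic,
                               n_matched = 5L, n_random = 5L, seed = 1L) {
  matched <- predict(rec, query, top_k = n_matched)
  meta <- rec$index$metadata
  key <- paste(meta$chat_id, meta$start)
  matched_key <- paste(matched$chat_id, matched$start)
  pool <- which(rec$index$rankable & !(key %in% matched_key))
  if (nrow(matched) + length(pool) < n_matched + n_random) {
    stop("corpus has fewer than ", n_matched + n_random,
         " distinct rankable windows", call. = FALSE)
  }
  random_rows <- with_seed(seed, sample(pool, n_random))
  segments <- data.frame(
    chat_id = c(matched$chat_id, meta$chat_id[random_rows]),
    start = c(matched$start, meta$start[random_rows]),
    source = rep(c("matched", "random"), c(nrow(matched), n_random)),
    stringsAsFactors = FALSE
  )
  segments$score <- as.numeric(
    chat_topic[segments$chat_id] == as.character(query_topic))
  structure(list(query_chat_id = query$chat_id,
                 query_topic = as.character(query_topic),
                 segments = segments),
            class = "validity_trial")
}

#' Run the in-silico validity experiment
#'
#' Aggregates one [run_validity_trial()] per query (the default design is 3
#' ongoing chats x 10 presented segments = 30 judged segments) and reports
#' the mean oracle score of the matched and random arms, their gap, and the
#' mean precision@k of the full top-k retrieval per query.
#'
#' @param rec A fitted [chat_recommender()].
#' @param chat_topic Named character vector chat_id -> topic label.
#' @param queries List of `chat` queries.
#' @param query_topics Topic label per query, same length.
#' @param n_matched,n_random Segments per arm per trial, default 5 each.
#' @param precision_k Cutoff for the precision summary, default 10.
#' @param seed Base seed; trial i uses `seed + i`.
#' @return Object of class `"validity_report"`: list with `n_trials`,
#'   `n_segments`, `mean_matched`, `mean_random`, `gap`
#'   (= mean_matched - mean_random), `precision_at_k`, and `trials`.
#' @export
run_validity_experiment <- function(rec, chat_topic, queries, query_topics,
                                    n_matched = 5L, n_random = 5L,
                                    precision_k = 10L, seed = 1L) {
  stopifnot(length(queries) >= 1L, length(queries) == length(query_topics))
  trials <- vector("list", length(queries))
  prec <- numeric(length(queries))
  for (i in seq_along(queries)) {
    trials[[i]] <- run_validity_trial(rec, chat_topic, queries[[i]],
                                      query_topics[[i]],
                                      n_matched = n_matched,
                                      n_random = n_random,
                                      seed = seed + i)
    full <- predict(rec, queries[[i]], top_k = precision_k)
    prec[i] <- precision_at_k(full, chat_topic, query_topics[[i]],
                              k = precision_k)
  }
  seg <- do.call(rbind, lapply(trials, `[[`, "segments"))
  mean_matched <- mean(seg$score[seg$source == "matched"])
  mean_random <- mean(seg$score[seg$source == "random"])
  structure(list(n_trials = length(trials),
                 n_segments = nrow(seg),
                 mean_matched = mean_matched,
                 mean_random = mean_random,
                 gap = mean_matched - mean_random,
                 precision_at_k = mean(prec),
                 precision_k = as.integer(precision_k),
                 trials = trials),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("Matched-vs-random validity experiment\n")
  cat(sprintf("  trials:        %d (%d segments judged)\n",
              x$n_trials, x$n_segments))
  cat(sprintf("  mean oracle score, matched arm: %.3f\n", x$mean_matched))
  cat(sprintf("  mean oracle score, random arm:  %.3f\n", x$mean_random))
  cat(sprintf("  gap (matched - random):         %.3f\n", x$gap))
  cat(sprintf("  precision@%d:                   %.3f\n",
              x$precision_k, x$precision_at_k))
  invisible(x)
}

#' Serialize a validity report to JSON
#'
#' Writes the summary fields plus per-trial segment records in a documented
#' schema, suitable for downstream statistics.
#'
#' @param report A `validity_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validity_report <- function(report, path) {
  obj <- list(
    n_trials = report$n_trials,
    n_segments = report$n_segments,
    mean_matched = report$mean_matched,
    mean_random = report$mean_random,
    gap = report$gap,
    precision_k = report$precision_k,
    precision_at_k = report$precision_at_k,
    trials = lapply(report$trials, function(tr) {
      list(query_chat_id = tr$query_chat_id,
           query_topic = tr$query_topic,
           segments = tr$segments)
    })
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             path, useBytes = TRUE)
  invisible(path)
}
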