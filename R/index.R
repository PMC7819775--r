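#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]` up to floating tolerance.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for the zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

INDEX_FORMAT_VERSION <- 1L

#' Build a window-embedding index
#'
#' Stores the embedding matrix row-aligned with its (chat_id, start,
#' token_count) metadata and a snapshot of the configurations used to build
#' it. Zero-vector rows (token_count 0) stay in the metadata but are flagged
#' non-rankable and never returned by [query_index()].
#'
#' @param embeddings Result of [embed_windows()] (`matrix` + `metadata`).
#' @param seg_config The [segmentation_config()] used for windowing.
#' @param emb_config The [embedding_config()] used for embedding.
#' @return Object of class `"embedding_index"`.
#' @export
build_index <- function(embeddings, seg_config = segmentation_config(),
                        emb_config = embedding_config()) {
  mat <- embeddings$matrix
  meta <- embeddings$metadata
  stopifnot(is.matrix(mat), nrow(mat) == nrow(meta))
  structure(
    list(matrix = mat,
         metadata = meta,
         rankable = meta$token_count > 0L & rowSums(mat != 0) > 0L,
         config_snapshot = list(segmentation = seg_config,
                                embedding = emb_config),
         format_version = INDEX_FORMAT_VERSION),
    class = "embedding_index"
  )
}

#' @export
print.embedding_index <- function(x, ...) {
  cat(sprintf("<embedding_index: %d windows (%d rankable), dimension %d>\n",
              nrow(x$matrix), sum(x$rankable), ncol(x$matrix)))
  invisible(x)
}

#' Retrieval configuration
#'
#' @param top_k Number of windows to recommend, default 10.
#' @param context_size Trailing messages of the ongoing chat used as the
#'   query, default 5.
#' @param dedup_per_chat If `TRUE`, keep only each source chat's single best
#'   window (off by default: overlapping windows of one chat may co-occur in
#'   the top k, as in the deployed pipeline).
#' @param exclude_chat_ids Chats never returned, e.g. the ongoing chat itself
#'   when it is part of the corpus.
#' @return A list of class `"query_config"`.
#' @export
query_config <- function(top_k = 10L, context_size = 5L,
                         dedup_per_chat = FALSE,
                         exclude_chat_ids = character(0)) {
  top_k <- as.integer(top_k)
  context_size <- as.integer(context_size)
  stopifnot(top_k >= 1L, context_size >= 1L)
  structure(list(top_k = top_k, context_size = context_size,
                 dedup_per_chat = isTRUE(dedup_per_chat),
                 exclude_chat_ids = as.character(exclude_chat_ids)),
            class = "query_config")
}

#' Top-k cosine retrieval over an index
#'
#' Ranks every rankable row of the index by cosine similarity to the query
#' vector (exact, exhaustive) and returns the best `top_k`. Ties are broken
#' deterministically by (chat_id, start) ascending, so results are invariant
#' to the row order of the index. Fewer than `top_k` candidates simply yield
#' fewer rows.
#'
#' @param index An [build_index()] result.
#' @param query_vec Numeric query vector (nonzero, matching dimension).
#' @param config A [query_config()].
#' @return Data frame with columns `rank` (1-based), `chat_id`, `start`,
#'   `score` (cosine, non-increasing).
#' @export
query_index <- function(index, query_vec, config = query_config()) {
  if (nrow(index$matrix) == 0L) stop("index is empty", call. = FALSE)
  if (length(query_vec) != ncol(index$matrix)) {
    stop("dimension mismatch: query has ", length(query_vec),
         ", index has ", ncol(index$matrix), call. = FALSE)
  }
  qn <- sqrt(sum(query_vec^2))
  if (qn == 0) stop("query vector is zero", call. = FALSE)
  cand <- which(index$rankable &
                  !(index$metadata$chat_id %in% config$exclude_chat_ids))
  if (length(cand) == 0L) {
    warning("no rankable candidate windows", call. = FALSE)
    return(data.frame(rank = integer(0), chat_id = character(0),
                      start = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  M <- index$matrix[cand, , drop = FALSE]
  scores <- as.numeric(M %*% query_vec) / (sqrt(rowSums(M^2)) * qn)
  meta <- index$metadata[cand, , drop = FALSE]
  ord <- order(-scores, meta$chat_id, meta$start)
  meta <- meta[ord, , drop = FALSE]
  scores <- scores[ord]
  if (config$dedup_per_chat) {
    keep <- !duplicated(meta$chat_id)
    meta <- meta[keep, , drop = FALSE]
    scores <- scores[keep]
  }
  k <- min(config$top_k, length(scores))
  data.frame(rank = seq_len(k),
             chat_id = meta$chat_id[seq_len(k)],
             start = meta$start[seq_len(k)],
             score = scores[seq_len(k)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Persist / restore an embedding index
#'
#' The index is written as a single versioned container (RDS serialization of
#' the index object, carrying an explicit `format_version` field). Loading
#' verifies the version and the structural invariants, so a truncated or
#' foreign file fails loudly rather than yielding a broken index.
#'
#' @param index An `embedding_index`.
#' @param path File path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   restored `embedding_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "embedding_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt index file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj, "embedding_index")) {
    stop("not an embedding_index container", call. = FALSE)
  }
  if (obj$format_version != INDEX_FORMAT_VERSION) {
    stop("index format version ", obj$format_version,
         " not supported (expected ", INDEX_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  if (nrow(obj$matrix) != nrow(obj$metadata)) {
    stop("corrupt index: matrix/metadata row mismatch", call. = FALSE)
  }
  obj
}
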