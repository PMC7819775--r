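#' Construct a chat transcript
#'
#' A chat is an ordered two-party transcript between a help-seeker and a
#' counselor. Messages are stored positionally; the message index is implicit
#' (0-based position within the chat).
#'
#' @param chat_id Unique string identifier for the chat.
#' @param sender Character vector of senders, each `"helpseeker"` or
#'   `"counselor"`.
#' @param text Character vector of message texts, same length as `sender`.
#' @return An object of class `"chat"`: a list with elements `chat_id` and
#'   `messages` (a data frame with columns `sender` and `text`).
#' @examples
#' chat("c1", c("helpseeker", "counselor"), c("hoi", "hallo, hoe gaat het?"))
#' @export
chat <- function(chat_id, sender, text) {
  stopifnot(is.character(chat_id), length(chat_id) == 1L, nzchar(chat_id))
  sender <- as.character(sender)
  text <- as.character(text)
  if (length(sender) != length(text)) {
    stop("'sender' and 'text' must have the same length", call. = FALSE)
  }
  bad <- !sender %in% c("helpseeker", "counselor")
  if (any(bad)) {
    stop("unknown sender role(s): ", paste(unique(sender[bad]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(chat_id = chat_id,
         messages = data.frame(sender = sender, text = text,
                               stringsAsFactors = FALSE)),
    class = "chat"
  )
}

#' @export
print.chat <- function(x, ...) {
  cat(sprintf("<chat '%s': %d messages>\n", x$chat_id, n_messages(x)))
  invisible(x)
}

#' Number of messages in a chat
#'
#' @param chat A `chat` object.
#' @return Integer message count.
#' @export
n_messages <- function(chat) nrow(chat$messages)

#' Read a chat corpus from JSON Lines
#'
#' One chat per line, in the schema
#' `{"chat_id": "...", "messages": [{"sender": "helpseeker"|"counselor",
#' "text": "..."}, ...]}`. Message index is positional. No normalization is
#' applied at read time.
#'
#' @param path Path to a JSONL transcript file.
#' @return A list of `chat` objects in file order.
#' @seealso [write_corpus()] for the inverse, [normalize_corpus()],
#'   [filter_chats()].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  chats <- vector("list", length(lines_keep))
  ids <- character(length(lines_keep))
  for (k in seq_along(lines_keep)) {
    i <- lines_keep[k]
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) stop(sprintf("line %d: malformed JSON record (%s)",
                                       i, conditionMessage(e)), call. = FALSE)
    )
    if (is.null(rec$chat_id) || !is.character(rec$chat_id)) {
      stop(sprintf("line %d: record missing 'chat_id' string field", i),
           call. = FALSE)
    }
    if (is.null(rec$messages) || !is.list(rec$messages)) {
      stop(sprintf("line %d: record missing 'messages' field", i),
           call. = FALSE)
    }
    sender <- vapply(rec$messages, function(m) {
      if (is.null(m$sender) || is.null(m$text)) {
        stop(sprintf("line %d: message missing 'sender' or 'text'", i),
             call. = FALSE)
      }
      as.character(m$sender)
    }, character(1))
    text <- vapply(rec$messages, function(m) as.character(m$text), character(1))
    chats[[k]] <- chat(rec$chat_id, sender, text)
    ids[k] <- rec$chat_id
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate chat_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  chats
}

#' Write a chat corpus to JSON Lines
#'
#' Emits the same schema [read_corpus()] consumes; `write_corpus` followed by
#' `read_corpus` reproduces the corpus, and output is byte-deterministic for
#' a given input.
#'
#' @param chats List of `chat` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(chats, path) {
  lines <- vapply(chats, function(ch) {
    msgs <- lapply(seq_len(n_messages(ch)), function(j) {
      list(sender = ch$messages$sender[j], text = ch$messages$text[j])
    })
    jsonlite::toJSON(list(chat_id = ch$chat_id, messages = msgs),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Clean a message text
#'
#' Lowercases, removes every character outside letters, digits, whitespace
#' and the retained punctuation set `. , ? ! ' -` (so emoji, control
#' characters and other symbols are dropped), collapses whitespace runs to
#' single spaces, and strips leading/trailing whitespace. Total and
#' idempotent.
#'
#' @param text Character vector (any unicode content).
#' @return Character vector of cleaned texts.
#' @examples
#' normalize_text("Hoi!!  Hoe GAAT het?")  # "hoi!! hoe gaat het?"
#' @export
normalize_text <- function(text) {
  out <- tolower(as.character(text))
  out <- gsub("[^\\p{L}\\p{N}\\s.,?!'-]+", "", out, perl = TRUE)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

#' Normalize every message in a corpus
#'
#' @param chats List of `chat` objects (or a single `chat`).
#' @return The same structure with all message texts passed through
#'   [normalize_text()].
#' @export
normalize_corpus <- function(chats) {
  norm1 <- function(ch) {
    ch$messages$text <- normalize_text(ch$messages$text)
    ch
  }
  if (inherits(chats, "chat")) return(norm1(chats))
  lapply(chats, norm1)
}

#' Filter short chats from a corpus
#'
#' Retains exactly the chats with at least `min_interactions` messages (a
#' chat of exactly the threshold length is kept), preserving order. One
#' interaction is one message from either party.
#'
#' @param chats List of `chat` objects.
#' @param min_interactions Minimum message count, default 20.
#' @return The retained chats, in the original order.
#' @export
filter_chats <- function(chats, min_interactions = 20L) {
  stopifnot(min_interactions >= 1L)
  chats[vapply(chats, n_messages, integer(1)) >= min_interactions]
}

#' Segmentation configuration
#'
#' @param window_size Messages per window, default 5.
#' @param stride Step between window starts, default 1 (every possible
#'   window).
#' @param min_interactions Corpus filter threshold, default 20.
#' @return A list of class `"segmentation_config"`.
#' @export
segmentation_config <- function(window_size = 5L, stride = 1L,
                                min_interactions = 20L) {
  window_size <- as.integer(window_size)
  stride <- as.integer(stride)
  min_interactions <- as.integer(min_interactions)
  stopifnot(window_size >= 1L, stride >= 1L,
            min_interactions >= window_size)
  structure(list(window_size = window_size, stride = stride,
                 min_interactions = min_interactions),
            class = "segmentation_config")
}

#' Enumerate sliding windows over one chat
#'
#' For a chat of m messages and window size w, produces the windows starting
#' at 0-based positions `0, stride, 2*stride, ...` up to `m - w`; with the
#' default stride 1 this is every run of w consecutive messages
#' (`max(0, m - w + 1)` windows), each consecutive pair sharing w - 1
#' messages. Chats shorter than w yield an empty list rather than an error,
#' since query-side chats may be short.
#'
#' @param chat A `chat` object.
#' @param config A [segmentation_config()].
#' @return List of windows; each window is a list with `chat_id`, `start`
#'   (0-based), `size`, and `texts` (the window's message texts in order).
#' @export
sliding_windows <- function(chat, config = segmentation_config()) {
  m <- n_messages(chat)
  w <- config$window_size
  if (m < w) return(list())
  starts <- seq.int(0L, m - w, by = config$stride)
  lapply(starts, function(s) {
    list(chat_id = chat$chat_id, start = s, size = w,
         texts = chat$messages$text[(s + 1L):(s + w)])
  })
}

#' Segment an entire corpus into windows
#'
#' Concatenates [sliding_windows()] over each chat, in corpus order. Expects
#' an already-filtered corpus; total window count with stride 1 is
#' the sum over chats of `m_i - w + 1`.
#'
#' @inheritParams filter_chats
#' @param config A [segmentation_config()].
#' @return Flat list of windows (see [sliding_windows()]).
#' @export
segment_corpus <- function(chats, config = segmentation_config()) {
  do.call(c, c(lapply(chats, sliding_windows, config = config), list(list())))
}

#' Retrieve a matched window and its full source transcript
#'
#' Given one row of a retrieval result, returns the window's texts together
#' with the complete source chat so a counselor-facing client can show the
#' match in context.
#'
#' @param chats The corpus the index was built over (list of `chat`).
#' @param result A one-row data frame (or list) with `chat_id` and `start`,
#'   as returned by [query_index()].
#' @return List with elements `window` (a window as in [sliding_windows()])
#'   and `chat` (the full source `chat`).
#' @export
fetch_context <- function(chats, result) {
  ids <- vapply(chats, function(ch) ch$chat_id, character(1))
  pos <- match(result$chat_id[1L], ids)
  if (is.na(pos)) {
    stop("chat_id '", result$chat_id[1L],
         "' not present in corpus (index/corpus mismatch)", call. = FALSE)
  }
  ch <- chats[[pos]]
  s <- as.integer(result$start[1L])
  w <- if (!is.null(result$size)) as.integer(result$size[1L]) else 5L
  if (s < 0L || s + w > n_messages(ch)) {
    stop("window [", s, ",", s + w, ") out of bounds for chat '",
         ch$chat_id, "'", call. = FALSE)
  }
  list(window = list(chat_id = ch$chat_id, start = s, size = w,
                     texts = ch$messages$text[(s + 1L):(s + w)]),
       chat = ch)
}
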