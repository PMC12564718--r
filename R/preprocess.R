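# Note cleaning and corpus chunking for masked-language-model pretraining.

#' Clean raw note text
#'
#' Normalises whitespace and strips characters outside a fixed whitelist of
#' letters, digits, space and basic punctuation (`. , ; : ? ! ' " ( ) / % - +`).
#' Runs of whitespace collapse to a single space and the result is trimmed.
#' The function is total and idempotent.
#'
#' @param raw Character vector of raw note text.
#' @return Character vector of cleaned text, same length as `raw`.
#' @export
clean_text <- function(raw) {
  stopifnot(is.character(raw))
  x <- gsub("[\\s]+", " ", raw, perl = TRUE)
  x <- gsub("[^A-Za-z0-9 .,;:?!'\"()/%+-]", "", x, perl = TRUE)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Build fixed-length token chunks from a corpus
#'
#' Tokenises every text, concatenates all token ids into one stream (chunks
#' deliberately cross note boundaries), and slices the stream into consecutive
#' rows of `chunk_len` tokens. A final partial chunk is either padded to
#' `chunk_len` (default) or dropped.
#'
#' @param texts Character vector, the corpus (one note per element).
#' @param tokenizer An [rac_tokenizer][train_tokenizer].
#' @param chunk_len Tokens per chunk (default 512).
#' @param drop_remainder Drop the final partial chunk instead of padding it.
#' @return A list of corpus chunks; each chunk is a list with integer `ids`
#'   (length `chunk_len`, padded with the padding id), `word_ids` (0 marks
#'   padding; tokens of one word share an index), `n_real` (unpadded token
#'   count) and `source_span` (start/end offsets into the token stream).
#' @export
chunk_corpus <- function(texts, tokenizer, chunk_len = 512L, drop_remainder = FALSE) {
  if (length(texts) == 0L) stop_validation("empty corpus: no texts to chunk")
  chunk_len <- check_count(chunk_len, "chunk_len")
  if (chunk_len < 2L) stop_config("chunk_len must be at least 2")
  enc <- lapply(texts, function(t) encode_text(tokenizer, t))
  ids <- unlist(lapply(enc, `[[`, "ids"), use.names = FALSE)
  # word ids made globally unique across notes so boundary maps stay coherent
  offs <- cumsum(c(0L, vapply(enc, function(e) {
    if (length(e$word_ids)) max(e$word_ids) else 0L
  }, integer(1))))
  word_ids <- unlist(lapply(seq_along(enc), function(i) {
    e <- enc[[i]]
    if (length(e$word_ids)) e$word_ids + offs[i] else integer(0)
  }), use.names = FALSE)
  n <- length(ids)
  if (n == 0L) stop_validation("corpus tokenised to zero tokens")
  n_full <- n %/% chunk_len
  rem <- n - n_full * chunk_len
  n_chunks <- n_full + if (rem > 0L && !drop_remainder) 1L else 0L
  if (n_chunks == 0L) stop_validation("corpus shorter than one chunk with drop_remainder = TRUE")
  lapply(seq_len(n_chunks), function(k) {
    from <- (k - 1L) * chunk_len + 1L
    to <- min(k * chunk_len, n)
    n_real <- to - from + 1L
    row_ids <- c(ids[from:to], rep.int(PAD_ID, chunk_len - n_real))
    row_words <- c(word_ids[from:to], rep.int(0L, chunk_len - n_real))
    list(ids = row_ids, word_ids = row_words, n_real = n_real,
         source_span = c(from, to))
  })
}

#' Randomly split chunks into training and validation sets
#'
#' @param chunks List of corpus chunks (from [chunk_corpus()]).
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with elements `train` and `val`, a disjoint exhaustive
#'   partition with `round(train_fraction * N)` training chunks.
#' @export
split_train_val <- function(chunks, train_fraction = 0.8, seed = 1L) {
  if (length(chunks) < 2L) stop_validation("need at least 2 chunks to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_fraction must lie strictly between 0 and 1")
  }
  n <- length(chunks)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n))
  list(train = chunks[sort(idx[seq_len(n_train)])],
       val = chunks[sort(idx[(n_train + 1L):n])])
}
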