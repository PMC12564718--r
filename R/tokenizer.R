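# Word-level tokeniser with character-piece fallback.
#
# The encoder needs a fixed integer vocabulary, whole-word masking needs a
# word-to-token map, and the chunked pooling mechanism needs explicit
# start/end/padding token ids. A compact trained vocabulary covers frequent
# in-domain words as single pieces; words outside the vocabulary fall back to
# character pieces ("w", "##o", "##w"), so rare or misspelled words tokenise
# to several subword tokens of one word, exactly the situation whole-word
# masking must treat atomically.

PAD_ID <- 1L
CLS_ID <- 2L
SEP_ID <- 3L
MASK_ID <- 4L
UNK_ID <- 5L
SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[MASK]", "[UNK]")

.tok_word_re <- "[a-z0-9']+|[.,;:?!\"()/%+-]"

#' Split cleaned text into basic word and punctuation tokens
#'
#' Lower-cases the text and returns maximal runs of letters, digits and
#' apostrophes, with each retained punctuation mark as its own token.
#'
#' @param text A character scalar (cleaned note text).
#' @return Character vector of basic tokens (possibly empty).
#' @export
basic_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr(.tok_word_re, tolower(text), perl = TRUE)
  out <- regmatches(tolower(text), m)[[1]]
  if (length(out) == 1L && is.na(out)) character(0) else out
}

#' Train a subword tokeniser on a corpus
#'
#' Builds a vocabulary of the most frequent basic tokens plus single-character
#' fallback pieces. Any word absent from the vocabulary is encoded as its
#' first character followed by `##`-prefixed continuation characters.
#'
#' @param texts Character vector of training texts.
#' @param vocab_size Maximum number of vocabulary entries including special
#'   tokens and fallback pieces (default 2000).
#' @return An object of class `rac_tokenizer`.
#' @export
train_tokenizer <- function(texts, vocab_size = 2000L) {
  if (length(texts) == 0L || all(!nzchar(texts))) {
    stop_validation("cannot train a tokeniser on an empty corpus")
  }
  vocab_size <- check_count(vocab_size, "vocab_size")
  toks <- unlist(lapply(texts, basic_tokenize), use.names = FALSE)
  freq <- sort(table(toks), decreasing = TRUE)
  chars <- c(letters, 0:9, "'", strsplit(".,;:?!\"()/%+-", "")[[1]])
  fallback <- c(chars, paste0("##", chars))
  base <- c(SPECIAL_TOKENS, fallback)
  room <- max(0L, vocab_size - length(base))
  words <- setdiff(names(freq), base)[seq_len(min(room, length(setdiff(names(freq), base))))]
  pieces <- c(base, words)
  tok <- list(pieces = pieces,
              ids = stats::setNames(seq_along(pieces), pieces),
              vocab_size = length(pieces))
  class(tok) <- "rac_tokenizer"
  tok
}

#' @export
print.rac_tokenizer <- function(x, ...) {
  cat("<rac_tokenizer> vocabulary size", x$vocab_size, "\n")
  invisible(x)
}

encode_word <- function(tokenizer, word) {
  id <- tokenizer$ids[word]
  if (!is.na(id)) return(unname(id))
  chars <- strsplit(word, "")[[1]]
  pieces <- c(chars[1L], if (length(chars) > 1L) paste0("##", chars[-1L]))
  ids <- tokenizer$ids[pieces]
  ids[is.na(ids)] <- UNK_ID
  unname(ids)
}

#' Encode text into token ids with a word-to-token map
#'
#' @param tokenizer An `rac_tokenizer`.
#' @param text A character scalar.
#' @return A list with `ids` (integer vector of token ids, no special tokens)
#'   and `word_ids` (parallel integer vector; tokens of the same
#'   whitespace-level word share a word index).
#' @export
encode_text <- function(tokenizer, text) {
  stopifnot(inherits(tokenizer, "rac_tokenizer"))
  words <- basic_tokenize(text)
  if (length(words) == 0L) {
    return(list(ids = integer(0), word_ids = integer(0)))
  }
  per <- lapply(words, encode_word, tokenizer = tokenizer)
  lens <- lengths(per)
  list(ids = as.integer(unlist(per, use.names = FALSE)),
       word_ids = rep.int(seq_along(words), lens))
}

#' Count tokens a text occupies under a tokeniser
#'
#' @inheritParams encode_text
#' @return Integer token count.
#' @export
count_tokens <- function(tokenizer, text) {
  length(encode_text(tokenizer, text)$ids)
}

#' Map token ids back to vocabulary pieces
#'
#' @param tokenizer An `rac_tokenizer`.
#' @param ids Integer token ids.
#' @return Character vector of pieces.
#' @export
id_to_token <- function(tokenizer, ids) {
  tokenizer$pieces[ids]
}

save_tokenizer <- function(tokenizer, path) {
  jsonlite::write_json(list(pieces = tokenizer$pieces), path, auto_unbox = FALSE)
  invisible(path)
}

load_tokenizer <- function(path) {
  pieces <- unlist(jsonlite::read_json(path)$pieces, use.names = FALSE)
  tok <- list(pieces = pieces,
              ids = stats::setNames(seq_along(pieces), pieces),
              vocab_size = length(pieces))
  class(tok) <- "rac_tokenizer"
  tok
}
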