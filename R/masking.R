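# Whole-word masking collator.
#
# Masking targets are selected at the word level: every subword token of a
# chosen word is corrupted together, and the corruption draw (mask token /
# random token / keep) is made once per word. Masking is re-drawn every time
# a chunk is served, so no fixed mask pattern can be memorised across epochs.

#' Configuration for the whole-word masking collator
#'
#' @param mask_prob Probability each word is selected for corruption
#'   (default 0.15).
#' @param whole_word Select at word level, corrupting all subword tokens of
#'   a selected word together (default `TRUE`); `FALSE` selects individual
#'   tokens.
#' @param replace_mask_fraction,replace_random_fraction,keep_fraction
#'   Corruption split for selected words (defaults 0.8 / 0.1 / 0.1, the
#'   original masked-LM recipe); must sum to 1.
#' @param seed Integer seed for seeded collation entry points.
#' @return A list of class `rac_mask_config`.
#' @export
masking_config <- function(mask_prob = 0.15, whole_word = TRUE,
                           replace_mask_fraction = 0.8,
                           replace_random_fraction = 0.1,
                           keep_fraction = 0.1, seed = 1L) {
  check_prob(mask_prob, "mask_prob")
  check_prob(replace_mask_fraction, "replace_mask_fraction")
  check_prob(replace_random_fraction, "replace_random_fraction")
  check_prob(keep_fraction, "keep_fraction")
  s <- replace_mask_fraction + replace_random_fraction + keep_fraction
  if (abs(s - 1) > 1e-9) stop_config("corruption fractions must sum to 1, got ", s)
  structure(list(mask_prob = mask_prob, whole_word = isTRUE(whole_word),
                 replace_mask_fraction = replace_mask_fraction,
                 replace_random_fraction = replace_random_fraction,
                 keep_fraction = keep_fraction, seed = as.integer(seed)),
            class = "rac_mask_config")
}

#' Apply whole-word masking to a batch of chunks
#'
#' Uses the current RNG stream (callers seed per epoch/step), so serving the
#' same chunk twice draws a fresh mask pattern each time.
#'
#' @param batch List of corpus chunks (see [chunk_corpus()]): each with
#'   `ids`, `word_ids` (0 on padding) and `n_real`.
#' @param config An [masking_config()].
#' @param vocab_size Vocabulary size, needed for random-token replacement.
#' @return A list of masked rows, each with `ids` (corrupted), `labels`
#'   (original ids at corrupted positions, `NA` elsewhere), `word_ids` and
#'   `n_real`. Padding positions are never masked.
#' @export
whole_word_mask <- function(batch, config, vocab_size) {
  stopifnot(inherits(config, "rac_mask_config"))
  n_special <- length(SPECIAL_TOKENS)
  regular <- (n_special + 1L):vocab_size
  lapply(batch, function(row) {
    ids <- row$ids
    n_real <- row$n_real
    wid <- row$word_ids
    if (length(wid) != length(ids)) {
      stop_validation("word-boundary map length does not match row length")
    }
    if (n_real > 0L && any(wid[seq_len(n_real)] == 0L)) {
      stop_validation("word-boundary map does not cover every content token")
    }
    labels <- rep(NA_integer_, length(ids))
    units <- if (config$whole_word) {
      split(seq_len(n_real), wid[seq_len(n_real)])
    } else {
      as.list(seq_len(n_real))
    }
    if (length(units) > 0L && config$mask_prob > 0) {
      sel <- stats::runif(length(units)) < config$mask_prob
      for (u in units[sel]) {
        labels[u] <- ids[u]
        r <- stats::runif(1L)
        if (r < config$replace_mask_fraction) {
          ids[u] <- MASK_ID
        } else if (r < config$replace_mask_fraction + config$replace_random_fraction) {
          ids[u] <- sample(regular, length(u), replace = TRUE)
        } # else keep original tokens
      }
    }
    list(ids = ids, labels = labels, word_ids = wid, n_real = n_real)
  })
}

#' Build one epoch of freshly masked batches
#'
#' Shuffles the chunk order and applies [whole_word_mask()] with the current
#' RNG stream, so every epoch sees a different permutation and different
#' mask patterns over the same chunks.
#'
#' @param chunks Training chunks.
#' @param config An [masking_config()].
#' @param batch_size Chunks per batch.
#' @param vocab_size Vocabulary size for random replacement.
#' @return List of batches; each batch is a list of masked rows.
#' @export
make_epoch_batches <- function(chunks, config, batch_size, vocab_size) {
  if (length(chunks) == 0L) stop_validation("empty training set")
  batch_size <- check_count(batch_size, "batch_size")
  ord <- sample.int(length(chunks))
  starts <- seq(1L, length(ord), by = batch_size)
  lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1L, length(ord))]
    whole_word_mask(chunks[idx], config, vocab_size)
  })
}
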