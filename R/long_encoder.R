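# Chunk-and-aggregate encoding for notes longer than the 512-position limit.
#
# An over-length token sequence is split into equal 512-position parts, each
# wrapped in start/end tokens and padded; each part is encoded independently
# and the last-hidden-state vectors of content tokens are summed across all
# parts and divided by the tracked content-token count n. For a note that
# fits in one part this reduces exactly to masked mean pooling, which is the
# invariant the design preserves: start/end tokens are attended to but
# excluded from the pool, since segmentation multiplies the number of
# specials and including them would break the short-note equivalence.

#' Split a content-token sequence into fixed-length parts
#'
#' Each part has exactly `part_len` positions: a start token, up to
#' `part_len - 2` content tokens, an end token, and trailing padding on the
#' final part. The attention mask is 0 exactly on padding; the pooling mask
#' is 1 exactly on content tokens.
#'
#' @param token_ids Integer vector of content token ids (no specials).
#' @param part_len Positions per part (default 512; minimum 3).
#' @return An object of class `rac_segmented`: lists `parts`,
#'   `attention_masks`, `pooling_masks` (parallel, each entry of length
#'   `part_len`) and `content_token_count`.
#' @export
segment <- function(token_ids, part_len = 512L) {
  part_len <- check_count(part_len, "part_len")
  if (part_len < 3L) stop_config("part_len must be at least 3 (start + content + end)")
  C <- length(token_ids)
  if (C < 1L) stop_validation("cannot segment an empty token sequence")
  capacity <- part_len - 2L
  n_parts <- as.integer(ceiling(C / capacity))
  parts <- vector("list", n_parts)
  att <- vector("list", n_parts)
  pool <- vector("list", n_parts)
  for (k in seq_len(n_parts)) {
    from <- (k - 1L) * capacity + 1L
    to <- min(k * capacity, C)
    content <- token_ids[from:to]
    filled <- length(content) + 2L
    pad_n <- part_len - filled
    parts[[k]] <- c(CLS_ID, content, SEP_ID, rep.int(PAD_ID, pad_n))
    att[[k]] <- c(rep.int(1L, filled), rep.int(0L, pad_n))
    pool[[k]] <- c(0L, rep.int(1L, length(content)), 0L, rep.int(0L, pad_n))
  }
  structure(list(parts = parts, attention_masks = att, pooling_masks = pool,
                 content_token_count = C, part_len = part_len),
            class = "rac_segmented")
}

#' @export
print.rac_segmented <- function(x, ...) {
  cat("<rac_segmented>", length(x$parts), "part(s) of", x$part_len,
      "positions,", x$content_token_count, "content tokens\n")
  invisible(x)
}

# Encode one part with either a real encoder or a stub function
# (function(ids, attention_mask) -> L x d matrix over the unpadded prefix).
encode_part <- function(encoder, ids, attention_mask) {
  n_real <- sum(attention_mask)
  if (inherits(encoder, "rac_encoder")) {
    encoder_forward(encoder, ids[seq_len(n_real)])
  } else if (is.function(encoder)) {
    encoder(ids[seq_len(n_real)], attention_mask[seq_len(n_real)])
  } else {
    stop_validation("encoder must be an rac_encoder or a function")
  }
}

#' Pool a segmented sequence into one embedding vector
#'
#' Each part is encoded independently with its attention mask; the
#' last-hidden-state vectors at pooling-mask-1 positions are summed across
#' all parts and divided by the tracked content-token count.
#'
#' @param encoder An `rac_encoder`, or a function
#'   `(ids, attention_mask) -> matrix` returning per-position hidden states
#'   (handy for stubbing in tests).
#' @param seg An `rac_segmented` from [segment()].
#' @return Numeric vector of encoder hidden width, with attribute
#'   `"content_token_count"`.
#' @export
pooled_embedding <- function(encoder, seg) {
  stopifnot(inherits(seg, "rac_segmented"))
  total <- NULL
  for (k in seq_along(seg$parts)) {
    H <- encode_part(encoder, seg$parts[[k]], seg$attention_masks[[k]])
    keep <- which(seg$pooling_masks[[k]][seq_len(nrow(H))] == 1L)
    part_sum <- if (length(keep)) colSums(H[keep, , drop = FALSE]) else numeric(ncol(H))
    if (is.null(total)) total <- numeric(ncol(H))
    if (ncol(H) != length(total)) stop_validation("encoder hidden width mismatch across parts")
    total <- total + part_sum
  }
  v <- total / seg$content_token_count
  if (any(!is.finite(v))) stop_validation("pooled embedding contains non-finite entries")
  attr(v, "content_token_count") <- seg$content_token_count
  v
}

#' Encode one cleaned note into a pooled embedding
#'
#' Composition of cleaning, tokenisation, segmentation and masked-sum
#' pooling. Deterministic for fixed encoder weights.
#'
#' @param encoder An `rac_encoder` (or stub function, see
#'   [pooled_embedding()]).
#' @param tokenizer An [rac_tokenizer][train_tokenizer].
#' @param text Note text.
#' @param part_len Positions per part (default 512).
#' @return Numeric embedding vector.
#' @export
encode_note <- function(encoder, tokenizer, text, part_len = 512L) {
  cleaned <- clean_text(text)
  if (!nzchar(cleaned)) stop_validation("note text is empty after cleaning")
  ids <- encode_text(tokenizer, cleaned)$ids
  if (length(ids) == 0L) stop_validation("note tokenised to zero tokens")
  pooled_embedding(encoder, segment(ids, part_len = part_len))
}
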