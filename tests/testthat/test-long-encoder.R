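# The chunk-and-aggregate mechanism: part counting, token conservation,
# masks, and exact equivalence with single-pass masked mean pooling.

test_that("segmentation obeys the part-count law and the Figure-2 example", {
  # worked example: 1530 content tokens -> 3 parts of 512 positions
  seg <- segment(rep(6L, 1530L), part_len = 512L)
  expect_length(seg$parts, 3L)
  expect_true(all(lengths(seg$parts) == 512L))
  expect_equal(seg$content_token_count, 1530L)

  for (C in c(1L, 2L, 509L, 510L, 511L, 1020L, 1021L, 1530L, 2000L)) {
    seg <- segment(seq_len(C) %% 90L + 6L, part_len = 512L)
    expect_length(seg$parts, ceiling(C / 510))
  }
})

test_that("segmentation conserves content tokens and builds exact masks", {
  set.seed(8)
  ids <- sample(6:500, 1234L, replace = TRUE)
  seg <- segment(ids, part_len = 512L)
  back <- unlist(lapply(seq_along(seg$parts), function(k) {
    seg$parts[[k]][seg$pooling_masks[[k]] == 1L]
  }))
  expect_identical(back, ids)
  for (k in seq_along(seg$parts)) {
    att <- seg$attention_masks[[k]]
    part <- seg$parts[[k]]
    n_real <- sum(att)
    expect_identical(part[1L], racnlp:::CLS_ID)
    expect_identical(part[n_real], racnlp:::SEP_ID)
    expect_true(all(part[att == 0L] == racnlp:::PAD_ID))
    expect_true(all(seg$pooling_masks[[k]][c(1L, n_real)] == 0L))
  }
  expect_equal(sum(unlist(seg$pooling_masks)), seg$content_token_count)
  expect_error(segment(integer(0)), class = "racnlp_validation_error")
  expect_error(segment(1:5, part_len = 2L), class = "racnlp_config_error")
})

test_that("a constant-embedding stub pools to the constant for any length", {
  const <- function(ids, mask) matrix(rep(c(1, -2, 3), each = length(ids)),
                                      length(ids), 3L)
  for (C in c(1L, 10L, 510L, 511L, 1600L)) {
    v <- pooled_embedding(const, segment(rep(6L, C)))
    expect_equal(as.numeric(v), c(1, -2, 3), tolerance = 1e-12)
  }
})

test_that("segmented pooling equals single-pass masked mean for short inputs", {
  stub <- stub_encoder(d = 8L)
  set.seed(11)
  for (C in c(1L, 2L, 63L, 255L, 509L, 510L)) {
    ids <- sample(6:2500, C, replace = TRUE)
    seg <- segment(ids)
    v <- pooled_embedding(stub, seg)
    # oracle: direct mean of the stub vectors at the content positions
    full <- stub(c(racnlp:::CLS_ID, ids, racnlp:::SEP_ID), NULL)
    oracle <- colMeans(full[1L + seq_len(C), , drop = FALSE])
    expect_equal(as.numeric(v), oracle, tolerance = 1e-12)
  }

  ck <- get_checkpoint()
  for (C in c(1L, 5L, 64L, 126L)) {
    ids <- sample(6:ck$model$cfg$vocab_size, C, replace = TRUE)
    v <- pooled_embedding(ck$model, segment(ids))
    H <- encoder_forward(ck$model, c(racnlp:::CLS_ID, ids, racnlp:::SEP_ID))
    oracle <- colMeans(H[1L + seq_len(C), , drop = FALSE])
    expect_equal(as.numeric(v), oracle, tolerance = 1e-5)
  }
})

test_that("padding and part-order are pooling-invariant", {
  stub <- stub_encoder(d = 6L)
  set.seed(12)
  ids <- sample(6:2000, 700L, replace = TRUE)
  seg <- segment(ids)
  v <- pooled_embedding(stub, seg)
  # append 100 extra padding positions to the last part
  seg2 <- seg
  k <- length(seg2$parts)
  seg2$parts[[k]] <- c(seg2$parts[[k]], rep(racnlp:::PAD_ID, 100L))
  seg2$attention_masks[[k]] <- c(seg2$attention_masks[[k]], rep(0L, 100L))
  seg2$pooling_masks[[k]] <- c(seg2$pooling_masks[[k]], rep(0L, 100L))
  expect_equal(pooled_embedding(stub, seg2), v, tolerance = 1e-6)
  # summing parts in reverse order
  seg3 <- seg
  seg3$parts <- rev(seg3$parts)
  seg3$attention_masks <- rev(seg3$attention_masks)
  seg3$pooling_masks <- rev(seg3$pooling_masks)
  expect_equal(as.numeric(pooled_embedding(stub, seg3)), as.numeric(v),
               tolerance = 1e-6)
})

test_that("encode_note routes short notes and long windows correctly", {
  ck <- get_checkpoint()
  tok <- ck$tokenizer
  note <- get_corpus()[2]
  v <- encode_note(ck$model, tok, note)
  expect_length(v, ck$model$cfg$d_model)
  expect_identical(v, encode_note(ck$model, tok, note))  # deterministic
  # a ~644-token window takes the 2-part pathway (capacity 510)
  win <- get_windows()[[1]]
  n_tok <- count_tokens(tok, clean_text(win$aggregated_text))
  v2 <- encode_note(ck$model, tok, win$aggregated_text)
  expect_length(v2, ck$model$cfg$d_model)
  expect_equal(length(segment(seq_len(n_tok) + 5L)$parts), ceiling(n_tok / 510))
  expect_error(encode_note(ck$model, tok, "↓↓↓"), class = "racnlp_validation_error")
})
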