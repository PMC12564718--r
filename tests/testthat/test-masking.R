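# Whole-word masking collator: atomicity, rate, conservation and freshness.

test_that("mask_prob = 0 leaves the batch untouched with all-ignore labels", {
  batch <- get_chunks()[1:5]
  out <- whole_word_mask(batch, masking_config(mask_prob = 0),
                         get_tokenizer()$vocab_size)
  for (i in seq_along(out)) {
    expect_identical(out[[i]]$ids, batch[[i]]$ids)
    expect_true(all(is.na(out[[i]]$labels)))
  }
})

test_that("a multi-subword word is always corrupted atomically", {
  tok <- get_tokenizer()
  # "zzyqx" falls back to character pieces: one word, >= 3 subword tokens
  enc <- encode_text(tok, "resident zzyqx lunch resident zzyqx tea")
  row <- list(ids = enc$ids, word_ids = enc$word_ids,
              n_real = length(enc$ids))
  cfg <- masking_config(mask_prob = 0.9, seed = 1L)
  set.seed(2)
  hit <- FALSE
  for (r in 1:20) {
    out <- whole_word_mask(list(row), cfg, tok$vocab_size)[[1L]]
    for (w in unique(row$word_ids)) {
      pos <- which(row$word_ids == w)
      lab <- !is.na(out$labels[pos])
      expect_true(all(lab) || all(!lab))       # never partially selected
      if (all(lab) && length(pos) >= 3L) hit <- TRUE
    }
  }
  expect_true(hit)  # the 3+-subword word did get selected whole at least once
})

test_that("labels preserve original ids and unselected positions are untouched", {
  batch <- get_chunks()[1:20]
  set.seed(3)
  out <- whole_word_mask(batch, masking_config(), get_tokenizer()$vocab_size)
  for (i in seq_along(out)) {
    orig <- batch[[i]]$ids
    m <- out[[i]]
    sel <- !is.na(m$labels)
    expect_identical(m$ids[!sel], orig[!sel])      # conservation off-mask
    expect_identical(m$labels[sel], orig[sel])     # labels hold originals
    expect_true(all(which(sel) <= m$n_real))       # padding never masked
  }
})

test_that("empirical word-level mask rate converges to mask_prob", {
  chunks <- get_chunks()
  batch <- chunks[rep_len(seq_along(chunks), 300L)]
  set.seed(4)
  out <- whole_word_mask(batch, masking_config(mask_prob = 0.15),
                         get_tokenizer()$vocab_size)
  sel_words <- 0L
  tot_words <- 0L
  for (i in seq_along(out)) {
    wid <- out[[i]]$word_ids[seq_len(out[[i]]$n_real)]
    lab <- !is.na(out[[i]]$labels[seq_len(out[[i]]$n_real)])
    tot_words <- tot_words + length(unique(wid))
    sel_words <- sel_words + length(unique(wid[lab]))
  }
  expect_gt(sel_words / tot_words, 0.14)
  expect_lt(sel_words / tot_words, 0.16)
})

test_that("masking is re-drawn each time a chunk is served", {
  chunks <- get_chunks()[1:64]
  cfg <- masking_config()
  V <- get_tokenizer()$vocab_size
  set.seed(5)
  e1 <- make_epoch_batches(chunks, cfg, 32L, V)
  e2 <- make_epoch_batches(chunks, cfg, 32L, V)
  expect_length(e1, 2L)                    # 64 chunks, batch 32
  key <- function(epoch) {
    rows <- unlist(epoch, recursive = FALSE)
    spans <- vapply(rows, function(r) paste(which(!is.na(r$labels)), collapse = ","),
                    character(1))
  }
  expect_false(identical(sort(key(e1)), sort(key(e2))))
})

test_that("inconsistent boundary maps and bad configs are rejected", {
  row <- list(ids = c(6L, 7L, 8L), word_ids = c(1L, 2L), n_real = 3L)
  expect_error(whole_word_mask(list(row), masking_config(), 100L),
               class = "racnlp_validation_error")
  row2 <- list(ids = c(6L, 7L, 8L), word_ids = c(1L, 0L, 2L), n_real = 3L)
  expect_error(whole_word_mask(list(row2), masking_config(), 100L),
               class = "racnlp_validation_error")
  expect_error(masking_config(replace_mask_fraction = 0.9, keep_fraction = 0.2),
               class = "racnlp_config_error")
})
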