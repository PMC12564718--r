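# Shared fixtures, built once per test run and memoised. The smoke chain
# mirrors the package's desk-scale protocol: 200 synthetic clients (seed 0,
# full keyword signal), a 1500-note pretraining corpus chunked at 128
# tokens, and 50 masked-LM steps on the tiny encoder profile.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

smoke_config <- function() {
  synthetic_config(n_clients = 200L, seed = 0L, signal_strength = 1)
}

get_clients <- function() {
  memo("clients", function() generate_clients(smoke_config()))
}

get_corpus <- function() {
  memo("corpus", function() clean_text(generate_pretrain_corpus(smoke_config(), 1500L)))
}

get_tokenizer <- function() {
  memo("tokenizer", function() train_tokenizer(get_corpus(), vocab_size = 2000L))
}

get_chunks <- function() {
  memo("chunks", function() chunk_corpus(get_corpus(), get_tokenizer(), chunk_len = 128L))
}

# Domain-pretrained tiny checkpoint (the smoke chain's path-1 artifact).
get_checkpoint <- function() {
  memo("checkpoint", function() {
    sp <- split_train_val(get_chunks(), 0.8, seed = 0L)
    pretrain(sp$train, sp$val,
             pretrain_config(max_steps = 50L, seed = 0L),
             masking_config(seed = 0L),
             get_tokenizer())
  })
}

# Balanced labelled note set for the note-identification task.
get_labelled_notes <- function(n_per_class = 200L, seed = 0L) {
  nf <- notes_frame(get_clients())
  pos <- which(nf$label == 1L)
  neg <- which(nf$label == 0L)
  with_seed <- racnlp:::with_seed
  with_seed(seed, {
    idx <- sample(c(sample(pos, n_per_class), sample(neg, n_per_class)))
    nf[idx, ]
  })
}

get_windows <- function() {
  memo("windows", function() suppressMessages(build_windows(get_clients())))
}

# Pooled embeddings of the smoke windows under the frozen pretrained
# encoder (deterministic; reused across head-only training runs).
get_window_embeddings <- function() {
  memo("window_embeddings", function() {
    ck <- get_checkpoint()
    t(vapply(get_windows(), function(w) {
      as.numeric(encode_note(ck$model, ck$tokenizer, w$aggregated_text))
    }, numeric(ck$model$cfg$d_model)))
  })
}

# Desk-scale fine-tuning protocol for the tiny encoder (see the methods
# vignette): lr 3e-3, batch 8, the prescribed 4 epochs.
desk_classifier_config <- function(seed = 0L, ...) {
  args <- list(learning_rate = 3e-3, batch_size = 8L, epochs = 4L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(classifier_config, args)
}

# A deterministic stub encoder: every token id maps to a fixed random
# vector, independent of context. Useful as a pooling oracle.
stub_encoder <- function(d = 8L, vocab = 3000L, seed = 7L) {
  tab <- racnlp:::with_seed(seed, matrix(stats::rnorm(vocab * d), vocab, d))
  function(ids, attention_mask) tab[ids, , drop = FALSE]
}
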