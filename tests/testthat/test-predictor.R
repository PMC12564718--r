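# Window assembly, negation-aware risk-factor extraction, fusion and the
# malnutrition predictor.

test_that("window filter is half-open, sorted and shuffle-invariant", {
  notes <- data.frame(
    client_id = "A",
    timestamp = c("2020-02-26", "2020-03-12", "2020-03-27", "2020-04-01"),
    text = c("day minus 35", "day minus 20", "day minus 5", "index day"),
    label = 0L, stringsAsFactors = FALSE)
  w <- assemble_window(notes, "2020-04-01", label = 1L)
  expect_equal(nrow(w$notes), 2L)
  expect_equal(w$notes$text, c("day minus 20", "day minus 5"))
  expect_equal(w$aggregated_text, "day minus 20 day minus 5")

  # boundary: exactly index - 30 is in, index day is out
  wb <- assemble_window(data.frame(client_id = "A",
                                   timestamp = c("2020-03-02", "2020-04-01"),
                                   text = c("boundary", "index"), label = 0L),
                        "2020-04-01")
  expect_equal(wb$notes$text, "boundary")

  set.seed(20)
  shuffled <- notes[sample(nrow(notes)), ]
  w2 <- assemble_window(shuffled, "2020-04-01", label = 1L)
  expect_equal(w2$notes$text, w$notes$text)
  expect_equal(w2$aggregated_text, w$aggregated_text)

  expect_error(assemble_window(notes[4, ], "2020-04-01"),
               class = "racnlp_empty_window")
})

test_that("negation detection distinguishes confirmed from negated factors", {
  cat <- load_catalogue()
  expect_equal(nrow(cat$factors), 46L)
  cancer <- which(cat$factors$name == "cancer")
  appetite <- which(cat$factors$name == "poor appetite")
  wl <- which(cat$factors$name == "weight loss")

  bits <- extract_risk_factors("no sign of cancer", cat)
  expect_equal(unname(bits[cancer]), 0L)
  bits <- extract_risk_factors("resident has poor appetite today", cat)
  expect_equal(unname(bits[appetite]), 1L)
  bits <- extract_risk_factors("no weight loss. poor appetite noted", cat)
  expect_equal(unname(bits[wl]), 0L)
  expect_equal(unname(bits[appetite]), 1L)
  # sentence boundary breaks negation scope
  bits <- extract_risk_factors("appetite is not good. weight loss observed", cat)
  expect_equal(unname(bits[wl]), 1L)
  # a confirmed mention elsewhere overrides a negated one
  bits <- extract_risk_factors("denies nausea. nausea observed overnight", cat)
  expect_equal(unname(bits[which(cat$factors$name == "nausea")]), 1L)
  # cue further than 5 tokens upstream does not negate
  bits <- extract_risk_factors(
    "no concerns this morning at all whatsoever regarding mobility but dysphagia observed", cat)
  expect_equal(unname(bits[which(cat$factors$name == "dysphagia")]), 1L)
  expect_length(bits, 46L)
})

test_that("fusion head arithmetic follows sigmoid(linear(concat))", {
  d <- 8L
  head <- list(W = numeric(d + 46L), b = 0)
  expect_equal(fuse_and_classify(numeric(d), integer(46L), head), 0.5)
  set.seed(21)
  head$W <- stats::rnorm(d + 46L)
  v <- stats::rnorm(d)
  risk <- as.integer(stats::runif(46) < 0.2)
  p <- fuse_and_classify(v, risk, head)
  expect_equal(p, racnlp:::sigmoid(sum(head$W * c(v, risk)) + head$b))
  # flipping a 0-bit with positive weight strictly raises the probability
  j <- which(risk == 0L & head$W[(d + 1L):(d + 46L)] > 0)[1L]
  risk2 <- risk
  risk2[j] <- 1L
  expect_gt(fuse_and_classify(v, risk2, head), p)
  expect_error(fuse_and_classify(numeric(d + 1L), risk, head),
               class = "racnlp_validation_error")
})

test_that("with no text signal, structured signal flows only through fusion", {
  ck <- get_checkpoint()
  wins <- get_windows()[1:120]
  # strip every factor synonym and malnutrition statement from the text,
  # keeping the risk vectors extracted from the original text
  cat <- load_catalogue()
  pat <- paste(c(unlist(cat$factors$synonyms),
                 "malnutrition", "malnourished", "nutritional", "nutrition"),
               collapse = "|")
  stripped <- lapply(wins, function(w) {
    w$aggregated_text <- gsub(pat, "care", w$aggregated_text)
    w
  })
  cfg <- desk_classifier_config(seed = 3L, freeze_encoder = TRUE, epochs = 2L)
  text_only <- train_predictor(stripped, ck, cfg, use_risk_factors = FALSE)
  fused <- train_predictor(stripped, ck, cfg, use_risk_factors = TRUE)
  expect_lt(abs(text_only$holdout$auroc - 0.5), 0.35)
  expect_gt(fused$holdout$auroc, text_only$holdout$auroc)
  expect_gt(fused$holdout$auroc, 0.75)
})

test_that("null-signal data yields chance-level prediction (5 seeds)", {
  cfg0 <- synthetic_config(n_clients = 300L, seed = 11L, signal_strength = 0)
  cl0 <- generate_clients(cfg0)
  wins0 <- suppressMessages(build_windows(cl0))
  ck <- get_checkpoint()
  emb0 <- t(vapply(wins0, function(w) {
    as.numeric(encode_note(ck$model, ck$tokenizer, w$aggregated_text))
  }, numeric(ck$model$cfg$d_model)))
  aucs <- vapply(1:5, function(seed) {
    cfg <- desk_classifier_config(seed = seed, freeze_encoder = TRUE, epochs = 2L)
    train_predictor(wins0, ck, cfg, use_risk_factors = TRUE,
                    embeddings = emb0)$holdout$auroc
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("serialisation preserves factor ordering and predictions", {
  ck <- get_checkpoint()
  wins <- get_windows()[1:80]
  fit <- train_predictor(wins, ck,
                         desk_classifier_config(seed = 9L, epochs = 1L,
                                                freeze_encoder = TRUE))
  dir <- tempfile("pred")
  save_predictor(fit, dir)
  back <- load_predictor(dir)
  expect_identical(back$factor_ids, fit$factor_ids)
  expect_identical(back$head, fit$head)
  w <- wins[[1]]
  expect_identical(predict_window(back, w), predict_window(fit, w))
  meta <- jsonlite::read_json(file.path(dir, "model_meta.json"))
  expect_equal(unlist(meta$factor_ids), fit$factor_ids)
})

test_that("reproducibility: identical metrics for identical seeds", {
  ck <- get_checkpoint()
  wins <- get_windows()[1:100]
  cfg <- desk_classifier_config(seed = 13L, epochs = 1L, freeze_encoder = TRUE)
  a <- train_predictor(wins, ck, cfg)
  b <- train_predictor(wins, ck, cfg)
  expect_identical(a$holdout, b$holdout)
})
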