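# The generator must reproduce the study conditions: sex-stratified
# prevalence, calibrated note lengths, keyword-borne signal and label
# independence when the signal is switched off.

test_that("generation is deterministic and fixtures are byte-identical", {
  cfg <- synthetic_config(n_clients = 20L, seed = 42L)
  f1 <- tempfile(fileext = ".jsonl")
  f2 <- tempfile(fileext = ".jsonl")
  write_fixture(generate_clients(cfg), f1)
  write_fixture(generate_clients(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(file.size(f1), 0)
})

test_that("sex-conditional prevalence calibrates to Table-1 rates at large n", {
  cfg <- synthetic_config(n_clients = 50000L, seed = 123L)
  cl <- generate_clients(cfg, notes = FALSE)
  sex <- vapply(cl, `[[`, character(1), "sex")
  lab <- vapply(cl, `[[`, integer(1), "label")
  expect_equal(mean(lab[sex == "female"]), 0.26, tolerance = 0.01 / 0.26)
  expect_equal(mean(lab[sex == "male"]), 0.30, tolerance = 0.01 / 0.30)
  expect_equal(mean(sex == "female"), 2797 / 4405, tolerance = 0.02)
})

test_that("short-note token lengths track the configured mean", {
  tok <- get_tokenizer()
  lines <- generate_pretrain_corpus(smoke_config(), 1000L)
  lens <- vapply(clean_text(lines), function(t) count_tokens(tok, t), numeric(1))
  expect_equal(mean(lens), 64, tolerance = 0.10)
  # overdispersed relative to Poisson
  expect_gt(stats::var(lens), mean(lens))

  cfg10 <- synthetic_config(n_clients = 10L, mean_short_note_tokens = 10L, seed = 5L)
  lens10 <- vapply(clean_text(generate_pretrain_corpus(cfg10, 2000L)),
                   function(t) length(basic_tokenize(t)), numeric(1))
  expect_equal(mean(lens10), 10, tolerance = 0.10)

  expect_length(generate_pretrain_corpus(cfg10, 1L), 1L)
})

test_that("malnourished clients' notes carry factor phrases at elevated rate", {
  cl <- get_clients()
  nf <- notes_frame(cl)
  client_label <- vapply(cl, `[[`, integer(1), "label")
  names(client_label) <- vapply(cl, `[[`, character(1), "client_id")
  factor_pat <- paste(load_catalogue()$factors$name, collapse = "|")
  has_factor <- grepl(factor_pat, nf$text)
  negated <- grepl("no sign of|no evidence of|denies|without|^no |\\bno\\b", nf$text)
  rate_case <- mean(has_factor[client_label[nf$client_id] == 1L])
  rate_ctrl <- mean(has_factor[client_label[nf$client_id] == 0L])
  expect_gt(rate_case, rate_ctrl + 0.2)
  expect_gt(mean(negated), 0.05)  # negation templates do appear
})

test_that("signal_strength = 0 makes note text independent of labels", {
  cfg <- synthetic_config(n_clients = 150L, seed = 9L, signal_strength = 0)
  nf <- notes_frame(generate_clients(cfg))
  marker <- grepl("malnutrition|malnourished|nutrition", nf$text)
  # exchangeability: marker rate must not differ by note label
  tab <- table(marker, nf$label)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("JSONL fixtures round-trip and count one line per note", {
  # 100 handmade clients x 4 notes -> 400 lines
  mk <- function(i) {
    list(client_id = sprintf("X%03d", i), sex = "female", age = 80L,
         label = 0L, index_date = as.Date("2020-01-31"),
         notes = data.frame(client_id = sprintf("X%03d", i),
                            timestamp = sprintf("2020-01-%02d", 1:4),
                            text = paste("resident ate lunch", 1:4),
                            label = 0L, stringsAsFactors = FALSE))
  }
  records <- structure(lapply(1:100, mk), class = "rac_clients")
  f <- tempfile(fileext = ".jsonl")
  write_fixture(records, f)
  expect_length(readLines(f), 400L)
  back <- read_notes_jsonl(f)
  expect_equal(back, notes_frame(records))

  empty <- tempfile(fileext = ".jsonl")
  write_fixture(data.frame(), empty)
  expect_equal(nrow(read_notes_jsonl(empty)), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_clients = 0L), class = "racnlp_config_error")
  expect_error(synthetic_config(prevalence_female = 1.2), class = "racnlp_config_error")
  expect_error(synthetic_config(signal_strength = -0.1), class = "racnlp_config_error")
})

test_that("note timestamps are non-decreasing within each client", {
  cl <- generate_clients(synthetic_config(n_clients = 30L, seed = 2L))
  for (c in cl) {
    expect_true(!is.unsorted(as.Date(c$notes$timestamp)))
  }
})
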