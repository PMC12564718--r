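# Synthetic nursing-note generator.
#
# The study corpus (free-text progress notes from residential aged care) is
# protected health information and cannot be shipped. This module generates
# corpora, labelled notes and longitudinal client records with the
# statistical structure the pipeline assumes: short notes averaging 64
# tokens, overdispersed lengths, sex-stratified malnutrition prevalence
# (26% of females, 30% of males), 30-day pre-onset windows averaging ~644
# tokens, keyword-borne malnutrition signal, and negated factor mentions.

default_filler_words <- function() {
  c("resident", "client", "staff", "nurse", "carer", "assisted", "attended",
    "ate", "drank", "finished", "enjoyed", "lunch", "dinner", "breakfast",
    "supper", "tea", "juice", "water", "meal", "snack", "dessert", "plate",
    "tray", "dining", "room", "bed", "chair", "walker", "frame", "wheelchair",
    "mobilised", "walked", "transferred", "settled", "slept", "rested",
    "woke", "continent", "hygiene", "shower", "dressed", "groomed",
    "medication", "given", "administered", "charted", "reviewed", "observed",
    "noted", "stable", "comfortable", "pleasant", "cheerful", "calm",
    "cooperative", "independent", "supervision", "assistance", "family",
    "visit", "visited", "activity", "activities", "bingo", "music", "garden",
    "afternoon", "morning", "evening", "overnight", "shift", "routine",
    "care", "plan", "usual", "well", "good", "fair", "intact", "warm",
    "obs", "bp", "hr", "temp", "sats", "prn", "bd", "tds", "mane", "nocte",
    "adls", "gp", "physio", "dietitian", "podiatry", "review", "due",
    "today", "tomorrow", "yesterday", "week", "day", "night", "ml", "mls",
    "grams", "percent", "full", "half", "most", "some", "offered",
    "encouraged", "tolerated", "requires", "requested", "repositioned",
    "ambulant", "rails", "buzzer", "within", "reach", "checked", "hourly")
}

#' Load the bundled synthetic risk-factor catalogue
#'
#' A 46-entry catalogue of common malnutrition risk factors with synonym
#' phrases and negation cues. The factor list is an illustrative synthetic
#' fixture (the catalogue is fully configurable via CSV), not an assertion
#' about any particular clinical vocabulary.
#'
#' @param path Optional path to a catalogue CSV with columns
#'   `factor_id,name,synonyms` (synonyms pipe-separated). Defaults to the
#'   bundled synthetic catalogue.
#' @return An object of class `rac_catalogue`: a list with `factors`
#'   (data.frame with `factor_id`, `name`, and a list-column `synonyms`) and
#'   `negation_cues` (character vector of cue phrases).
#' @export
load_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_risk_factors.csv", package = "racnlp")
  }
  if (!file.exists(path)) stop_validation("catalogue file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("factor_id", "name", "synonyms") %in% names(df))) {
    stop_validation("catalogue CSV must have columns factor_id,name,synonyms")
  }
  if (anyDuplicated(df$factor_id)) stop_validation("catalogue factor ids must be unique")
  out <- list(
    factors = data.frame(factor_id = df$factor_id, name = df$name,
                         stringsAsFactors = FALSE),
    negation_cues = c("no sign of", "no evidence of", "free of", "absence of",
                      "no", "not", "without", "denies", "denied", "nil")
  )
  out$factors$synonyms <- strsplit(df$synonyms, "|", fixed = TRUE)
  class(out) <- "rac_catalogue"
  out
}

#' @export
print.rac_catalogue <- function(x, ...) {
  cat("<rac_catalogue>", nrow(x$factors), "factors,",
      length(x$negation_cues), "negation cues\n")
  invisible(x)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions: female fraction 2797/4405, label
#' prevalence 26% (female) and 30% (male), mean short-note length 64 tokens
#' with negative-binomial overdispersion, and a note cadence calibrated so a
#' 30-day aggregated window averages ~644 tokens.
#'
#' @param n_clients Number of clients to generate.
#' @param female_fraction Probability a client is female (default 0.635).
#' @param prevalence_female,prevalence_male Sex-conditional malnutrition
#'   prevalence (defaults 0.26 and 0.30).
#' @param mean_short_note_tokens Target mean tokens per note (default 64).
#' @param mean_window_tokens Target mean tokens per 30-day window (default
#'   644); together with `mean_short_note_tokens` this fixes the default
#'   note cadence.
#' @param notes_per_client_per_week Note-writing rate; `NULL` (default)
#'   derives it as `7 * mean_window_tokens / (30 * mean_short_note_tokens)`.
#' @param signal_strength In `[0, 1]`: gates how strongly note text reflects
#'   the labels. Notes labelled as reporting malnutrition carry a
#'   malnutrition-statement phrase at rate
#'   `base_statement_rate + signal_strength * (1 - base_statement_rate)`;
#'   malnourished clients' notes carry affirmative risk-factor phrases at
#'   rate `base_phrase_rate + signal_strength * (factor_rate_case -
#'   base_phrase_rate)`. 0 makes note text independent of all labels.
#' @param negation_rate Probability a note carries a negated factor mention
#'   ("no sign of X"), independent of labels.
#' @param base_phrase_rate Baseline probability any note carries an
#'   affirmative factor phrase (default 0.08).
#' @param base_statement_rate Baseline probability any note carries a
#'   malnutrition-statement phrase (default 0.02).
#' @param factor_rate_case Affirmative factor-phrase rate in malnourished
#'   clients' notes at full signal strength (default 0.5).
#' @param note_positive_rate_case,note_positive_rate_control Probability a
#'   note is labelled as reporting malnutrition for malnourished and
#'   well-nourished clients respectively (defaults 0.5 and 0.02).
#' @param length_dispersion Negative-binomial size parameter for note
#'   lengths (default 8; smaller is more overdispersed).
#' @param vocab List with `filler` (character vector of filler words),
#'   `factors` (character vector of injectable factor phrases) and
#'   `statements` (malnutrition-statement phrases marking notes that report
#'   malnutrition); defaults to the built-in filler list, the bundled
#'   catalogue names and the built-in statement set.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   config.
#' @return An object of class `rac_synth_config`.
#' @export
synthetic_config <- function(n_clients = 100L,
                             female_fraction = 2797 / 4405,
                             prevalence_female = 0.26,
                             prevalence_male = 0.30,
                             mean_short_note_tokens = 64L,
                             mean_window_tokens = 644L,
                             notes_per_client_per_week = NULL,
                             signal_strength = 0.8,
                             negation_rate = 0.10,
                             base_phrase_rate = 0.08,
                             base_statement_rate = 0.02,
                             factor_rate_case = 0.5,
                             note_positive_rate_case = 0.5,
                             note_positive_rate_control = 0.02,
                             length_dispersion = 8,
                             vocab = NULL,
                             seed = 1L) {
  n_clients <- check_count(n_clients, "n_clients")
  check_prob(female_fraction, "female_fraction")
  check_prob(prevalence_female, "prevalence_female")
  check_prob(prevalence_male, "prevalence_male")
  check_prob(signal_strength, "signal_strength")
  check_prob(negation_rate, "negation_rate")
  check_prob(base_phrase_rate, "base_phrase_rate")
  check_prob(base_statement_rate, "base_statement_rate")
  check_prob(factor_rate_case, "factor_rate_case")
  check_prob(note_positive_rate_case, "note_positive_rate_case")
  check_prob(note_positive_rate_control, "note_positive_rate_control")
  check_count(mean_short_note_tokens, "mean_short_note_tokens")
  check_count(mean_window_tokens, "mean_window_tokens")
  if (is.null(notes_per_client_per_week)) {
    notes_per_client_per_week <-
      7 * mean_window_tokens / (30 * mean_short_note_tokens)
  }
  if (notes_per_client_per_week <= 0) stop_config("notes_per_client_per_week must be positive")
  if (length_dispersion <= 0) stop_config("length_dispersion must be positive")
  if (is.null(vocab)) {
    vocab <- list(filler = default_filler_words(),
                  factors = load_catalogue()$factors$name,
                  statements = default_statement_phrases())
  }
  structure(list(
    n_clients = n_clients, female_fraction = female_fraction,
    prevalence_female = prevalence_female, prevalence_male = prevalence_male,
    mean_short_note_tokens = as.integer(mean_short_note_tokens),
    mean_window_tokens = as.integer(mean_window_tokens),
    notes_per_client_per_week = notes_per_client_per_week,
    signal_strength = signal_strength, negation_rate = negation_rate,
    base_phrase_rate = base_phrase_rate,
    base_statement_rate = base_statement_rate,
    factor_rate_case = factor_rate_case,
    note_positive_rate_case = note_positive_rate_case,
    note_positive_rate_control = note_positive_rate_control,
    length_dispersion = length_dispersion,
    vocab = vocab, seed = as.integer(seed)
  ), class = "rac_synth_config")
}

default_statement_phrases <- function() {
  c("malnutrition risk", "nutritional decline", "malnourished state",
    "nutrition deteriorating", "severe malnutrition", "poor nutritional status")
}

aff_templates <- list(
  function(f) c(f, "noted"),
  function(f) c("has", f),
  function(f) c(f, "observed"),
  function(f) c("ongoing", f)
)

neg_templates <- list(
  function(f) c("no", "sign", "of", f),
  function(f) c("no", f, "observed"),
  function(f) c("denies", f),
  function(f) c("without", f)
)

# Build one note of ~k basic tokens (words + sentence periods). Phrase token
# budgets are deducted from the filler budget so the total stays at k. The
# negated mention always sits in a different sentence from the affirmative
# phrases, so a negation cue can never fall inside their 5-token scope.
build_note_text <- function(k, stmt_phrase, aff_factor, neg_factor, filler) {
  pick <- function(templates, phrase) {
    templates[[sample.int(length(templates), 1L)]](strsplit(phrase, " ")[[1]])
  }
  stmt <- if (!is.na(stmt_phrase)) pick(aff_templates, stmt_phrase)
  aff <- if (!is.na(aff_factor)) pick(aff_templates, aff_factor)
  neg <- if (!is.na(neg_factor)) pick(neg_templates, neg_factor)
  n_sent <- max(1L, as.integer(round(k / 20)))
  if (!is.null(neg) && (!is.null(aff) || !is.null(stmt))) n_sent <- max(2L, n_sent)
  k_fill <- max(0L, k - n_sent - length(stmt) - length(aff) - length(neg))
  words <- if (k_fill > 0L) sample(filler, k_fill, replace = TRUE) else character(0)
  sent_of <- if (k_fill > 0L) sort(sample.int(n_sent, k_fill, replace = TRUE)) else integer(0)
  sents <- lapply(seq_len(n_sent), function(s) words[sent_of == s])
  neg_slot <- sample.int(n_sent, 1L)
  other_slots <- if (n_sent >= 2L) setdiff(seq_len(n_sent), neg_slot) else neg_slot
  insert_phrase <- function(sent, phrase) {
    pos <- sample.int(length(sent) + 1L, 1L) - 1L
    append(sent, phrase, after = pos)
  }
  if (!is.null(neg)) sents[[neg_slot]] <- insert_phrase(sents[[neg_slot]], neg)
  for (ph in list(stmt, aff)) {
    if (is.null(ph)) next
    slot <- other_slots[sample.int(length(other_slots), 1L)]
    sents[[slot]] <- insert_phrase(sents[[slot]], ph)
  }
  sents <- sents[lengths(sents) > 0L]
  if (length(sents) == 0L) sents <- list(sample(filler, 1L))
  paste0(paste(vapply(sents, paste, character(1), collapse = " "),
               collapse = ". "), ".")
}

# Note sampler with three injection channels, all gated by signal_strength
# except the label-independent negation channel:
#   statements  ~ note label (Task 1 signal: notes reporting malnutrition)
#   factors     ~ client label (Task 2 signal: elevated risk-factor mentions)
#   negations   ~ label-independent
sample_notes <- function(cfg, note_labels, client_labels) {
  n <- length(note_labels)
  if (length(client_labels) == 1L) client_labels <- rep(client_labels, n)
  mu <- cfg$mean_short_note_tokens
  k <- 3L + stats::rnbinom(n, mu = mu - 3L, size = cfg$length_dispersion)
  s <- cfg$signal_strength
  p_stmt <- ifelse(note_labels == 1L,
                   cfg$base_statement_rate + s * (1 - cfg$base_statement_rate),
                   cfg$base_statement_rate)
  p_aff <- ifelse(client_labels == 1L,
                  cfg$base_phrase_rate +
                    s * (cfg$factor_rate_case - cfg$base_phrase_rate),
                  cfg$base_phrase_rate)
  has_stmt <- stats::runif(n) < p_stmt
  has_aff <- stats::runif(n) < p_aff
  has_neg <- stats::runif(n) < cfg$negation_rate
  factors <- cfg$vocab$factors
  statements <- cfg$vocab$statements
  stmt_p <- ifelse(has_stmt, sample(statements, n, replace = TRUE), NA_character_)
  aff_f <- ifelse(has_aff, sample(factors, n, replace = TRUE), NA_character_)
  neg_f <- ifelse(has_neg, sample(factors, n, replace = TRUE), NA_character_)
  texts <- character(n)
  for (i in seq_len(n)) {
    texts[i] <- build_note_text(k[i], stmt_p[i], aff_f[i], neg_f[i],
                                cfg$vocab$filler)
  }
  texts
}

#' Generate synthetic client records
#'
#' Each client receives a sex, an age, a sex-conditional malnutrition label,
#' an index date (the onset date for malnourished clients, the latest note
#' date otherwise) and a stream of timestamped notes. Note timestamps follow
#' a renewal process whose mean interval is set by the note cadence; the
#' interval is bounded above so every 30-day window holds several notes.
#' Malnourished clients' notes carry affirmative risk-factor phrases at a
#' rate elevated by `signal_strength`; negated mentions appear at
#' `negation_rate` regardless of label.
#'
#' @param config An [synthetic_config()] object.
#' @param notes Build note text (default `TRUE`). `notes = FALSE` skips the
#'   per-client note streams and returns cohort-level fields only (sex,
#'   age, label, index date), which is much faster for large-n calibration
#'   checks; the cohort draw is identical either way.
#' @return A list of client records (class `rac_clients`); each record has
#'   `client_id`, `sex`, `age`, `label`, `index_date` and `notes` (a
#'   data.frame with `client_id`, `timestamp`, `text`, `label`).
#' @export
generate_clients <- function(config, notes = TRUE) {
  stopifnot(inherits(config, "rac_synth_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_clients
    sex <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
    prev <- ifelse(sex == "female", cfg$prevalence_female, cfg$prevalence_male)
    label <- as.integer(stats::runif(n) < prev)
    age <- pmin(104L, pmax(65L, as.integer(round(stats::rnorm(n, 85.2, 8.9)))))
    if (!notes) {
      empty <- data.frame(client_id = character(0), timestamp = character(0),
                          text = character(0), label = integer(0),
                          stringsAsFactors = FALSE)
      clients <- lapply(seq_len(n), function(i) {
        list(client_id = sprintf("C%05d", i), sex = sex[i], age = age[i],
             label = label[i], index_date = as.Date(NA), notes = empty)
      })
      class(clients) <- "rac_clients"
      return(clients)
    }
    base_date <- as.Date("2019-03-01")
    mean_gap <- 7 / cfg$notes_per_client_per_week
    horizon <- 52
    max_notes <- as.integer(ceiling(horizon / (0.3 * mean_gap))) + 2L
    clients <- vector("list", n)
    for (i in seq_len(n)) {
      start <- base_date + (sample.int(240L, 1L) - 1L)
      gaps <- stats::runif(max_notes, 0.3 * mean_gap, 1.7 * mean_gap)
      times <- cumsum(gaps)
      times <- times[times <= horizon]
      m <- length(times)
      note_dates <- start + floor(times)
      p_pos <- if (label[i] == 1L) cfg$note_positive_rate_case else cfg$note_positive_rate_control
      note_labels <- as.integer(stats::runif(m) < p_pos)
      texts <- sample_notes(cfg, note_labels, label[i])
      onset <- 40 + stats::runif(1L, 0, 10)
      index_date <- if (label[i] == 1L) start + floor(onset) else max(note_dates)
      cid <- sprintf("C%05d", i)
      clients[[i]] <- list(
        client_id = cid, sex = sex[i], age = age[i], label = label[i],
        index_date = index_date,
        notes = data.frame(client_id = cid,
                           timestamp = format(note_dates, "%Y-%m-%d"),
                           text = texts, label = note_labels,
                           stringsAsFactors = FALSE))
    }
    class(clients) <- "rac_clients"
    clients
  })
}

#' @export
print.rac_clients <- function(x, ...) {
  n_notes <- sum(vapply(x, function(c) nrow(c$notes), integer(1)))
  cat("<rac_clients>", length(x), "clients,", n_notes, "notes,",
      sum(vapply(x, `[[`, integer(1), "label")), "malnourished\n")
  invisible(x)
}

#' Stack all clients' notes into one data.frame
#'
#' @param clients An `rac_clients` list from [generate_clients()].
#' @return A data.frame with columns `client_id`, `timestamp`, `text`, `label`.
#' @export
notes_frame <- function(clients) {
  do.call(rbind, c(lapply(clients, `[[`, "notes"), list(make.row.names = FALSE)))
}

#' Generate a raw-text pretraining corpus
#'
#' Emits free-standing note lines whose tokenised length distribution matches
#' the short-note model (mean `mean_short_note_tokens`). Texts include the
#' domain shorthand of the filler vocabulary (obs, prn, adls, ...), so domain
#' adaptation has something to learn that general English lacks.
#'
#' @param config An [synthetic_config()] object.
#' @param n_notes Number of note lines to generate.
#' @return Character vector of `n_notes` raw text lines.
#' @export
generate_pretrain_corpus <- function(config, n_notes) {
  stopifnot(inherits(config, "rac_synth_config"))
  n_notes <- check_count(n_notes, "n_notes")
  with_seed(child_seed(config$seed, "pretrain_corpus"), {
    prev <- mean(c(config$prevalence_female, config$prevalence_male))
    client_labels <- as.integer(stats::runif(n_notes) < prev)
    p_pos <- ifelse(client_labels == 1L, config$note_positive_rate_case,
                    config$note_positive_rate_control)
    labels <- as.integer(stats::runif(n_notes) < p_pos)
    sample_notes(config, labels, client_labels)
  })
}

#' Write notes to a JSONL fixture
#'
#' One JSON object per line with fields `client_id`, `timestamp`, `text`,
#' `label`. Round-trips losslessly through [read_notes_jsonl()].
#'
#' @param records An `rac_clients` list or a notes data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fixture <- function(records, path) {
  notes <- if (inherits(records, "rac_clients")) notes_frame(records) else records
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_validation("cannot open path for writing: ", path)
  })
  on.exit(close(con))
  if (is.null(notes) || nrow(notes) == 0L) return(invisible(path))
  jsonlite::stream_out(notes, con, verbose = FALSE)
  invisible(path)
}

#' Read a JSONL note fixture
#'
#' @param path Path to a JSONL file written by [write_fixture()].
#' @return A data.frame with columns `client_id`, `timestamp`, `text`,
#'   `label` (zero rows for an empty file).
#' @export
read_notes_jsonl <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(client_id = character(0), timestamp = character(0),
                      text = character(0), label = integer(0),
                      stringsAsFactors = FALSE))
  }
  con <- file(path, open = "rb")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  df$label <- as.integer(df$label)
  df
}

#' Write client-level metadata to JSONL
#'
#' Persists `client_id`, `sex`, `age`, `label` and `index_date` (one client
#' per line), complementing the per-note fixture from [write_fixture()].
#'
#' @param clients An `rac_clients` list.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_clients_jsonl <- function(clients, path) {
  df <- do.call(rbind, lapply(clients, function(c) {
    data.frame(client_id = c$client_id, sex = c$sex, age = c$age,
               label = c$label, index_date = format(c$index_date, "%Y-%m-%d"),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' Read client-level metadata written by [write_clients_jsonl()]
#'
#' @param path Path to the clients JSONL file.
#' @return A data.frame with one row per client.
#' @export
read_clients_jsonl <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  df <- jsonlite::stream_in(con, verbose = FALSE)
  df$label <- as.integer(df$label)
  df
}
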