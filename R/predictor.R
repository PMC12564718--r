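# Malnutrition prediction from 30-day pre-onset note windows fused with
# structured risk factors.

#' Assemble a client's 30-day pre-index note window
#'
#' Notes are filtered to the half-open interval
#' `[index_date - window_days, index_date)` — a note on the index date
#' itself is excluded, one exactly `window_days` before it is included —
#' sorted ascending by timestamp (ties broken by input order) and
#' concatenated earliest-first with single spaces.
#'
#' @param notes A data.frame of one client's notes (`timestamp`, `text`,
#'   optionally `client_id`, `label`).
#' @param index_date The onset date for malnourished clients; any anchor
#'   date for others (a `Date` or `"YYYY-MM-DD"` string).
#' @param window_days Window length in days (default 30).
#' @param label Optional binary outcome label to attach.
#' @param client_id Optional client identifier.
#' @return An object of class `rac_window`: `client_id`, `index_date`,
#'   `notes` (filtered, sorted), `aggregated_text`, `label`.
#' @export
assemble_window <- function(notes, index_date, window_days = 30L,
                            label = NA_integer_, client_id = NULL) {
  window_days <- check_count(window_days, "window_days")
  index_date <- as.Date(index_date)
  ts <- as.Date(notes$timestamp)
  keep <- ts >= index_date - window_days & ts < index_date
  if (!any(keep)) {
    stop(structure(class = c("racnlp_empty_window", "error", "condition"),
                   list(message = paste0("no notes in the ", window_days,
                                         "-day window before ", index_date),
                        call = sys.call(-1))))
  }
  sub <- notes[keep, , drop = FALSE]
  ord <- order(as.Date(sub$timestamp))     # stable: ties keep input order
  sub <- sub[ord, , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(
    client_id = client_id %||% (if ("client_id" %in% names(sub)) sub$client_id[1L] else NA_character_),
    index_date = index_date,
    notes = sub,
    aggregated_text = paste(sub$text, collapse = " "),
    label = as.integer(label)
  ), class = "rac_window")
}

#' @export
print.rac_window <- function(x, ...) {
  cat("<rac_window>", x$client_id, "|", nrow(x$notes), "notes before",
      format(x$index_date), "| label", x$label, "\n")
  invisible(x)
}

#' Extract a one-hot risk-factor vector with negation detection
#'
#' A factor's bit is 1 iff any of its synonym phrases occurs at least once
#' in the text NOT governed by a negation cue. Negation scope: a cue ending
#' within the 5 tokens immediately preceding the matched phrase, inside the
#' same sentence (sentences split on `. ! ? ;`). Repeated confirmed
#' mentions still yield 1 — the vector encodes presence, not counts.
#'
#' @param text Cleaned note or window text.
#' @param catalogue An `rac_catalogue` from [load_catalogue()].
#' @return Integer 0/1 vector of length `nrow(catalogue$factors)`, named by
#'   factor id.
#' @export
extract_risk_factors <- function(text, catalogue) {
  stopifnot(inherits(catalogue, "rac_catalogue"))
  n_f <- nrow(catalogue$factors)
  bits <- stats::setNames(integer(n_f), catalogue$factors$factor_id)
  sentences <- strsplit(clean_text(text), "[.!?;]+")[[1]]
  cues <- lapply(catalogue$negation_cues, function(c) strsplit(tolower(c), " ")[[1]])
  for (sent in sentences) {
    toks <- basic_tokenize(sent)
    toks <- toks[grepl("^[a-z0-9']", toks)]  # negation scope counts words
    if (length(toks) == 0L) next
    for (fi in seq_len(n_f)) {
      if (bits[fi] == 1L) next
      for (syn in catalogue$factors$synonyms[[fi]]) {
        ph <- strsplit(tolower(syn), " ")[[1]]
        m <- length(ph)
        if (m > length(toks)) next
        for (start in seq_len(length(toks) - m + 1L)) {
          if (!all(toks[start:(start + m - 1L)] == ph)) next
          scope <- toks[max(1L, start - 5L):max(1L, start - 1L)]
          if (start == 1L) scope <- character(0)
          negated <- any(vapply(cues, function(cu) {
            lc <- length(cu)
            if (lc > length(scope)) return(FALSE)
            any(vapply(seq_len(length(scope) - lc + 1L), function(s) {
              all(scope[s:(s + lc - 1L)] == cu)
            }, logical(1)))
          }, logical(1)))
          if (!negated) {
            bits[fi] <- 1L
            break
          }
        }
        if (bits[fi] == 1L) break
      }
    }
  }
  bits
}

#' Build labelled windows with risk vectors for a cohort
#'
#' Applies [assemble_window()] at each client's index date (onset for
#' malnourished clients, latest note date otherwise) and
#' [extract_risk_factors()] to the aggregated window text. Clients with no
#' notes in the window are excluded with a message.
#'
#' @param clients An `rac_clients` list from [generate_clients()] (or any
#'   list of records with `client_id`, `label`, `index_date`, `notes`).
#' @param catalogue An `rac_catalogue` (default: the bundled one).
#' @param window_days Window length in days (default 30).
#' @return A list of `rac_window` objects, each with a `risk_vector` field.
#' @export
build_windows <- function(clients, catalogue = load_catalogue(),
                          window_days = 30L) {
  out <- list()
  dropped <- 0L
  for (cl in clients) {
    w <- tryCatch(
      assemble_window(cl$notes, cl$index_date, window_days,
                      label = cl$label, client_id = cl$client_id),
      racnlp_empty_window = function(e) NULL)
    if (is.null(w)) {
      dropped <- dropped + 1L
      next
    }
    w$risk_vector <- extract_risk_factors(w$aggregated_text, catalogue)
    out[[length(out) + 1L]] <- w
  }
  if (dropped > 0L) message(dropped, " client(s) excluded: no notes in window")
  out
}

#' Fuse a pooled embedding with a risk vector through the sigmoid head
#'
#' @param pooled Numeric pooled text embedding (width d).
#' @param risk Binary risk-factor vector.
#' @param head A list with weights `W` (length `d + length(risk)`) and bias
#'   `b`.
#' @return Probability `sigmoid(W . [pooled; risk] + b)` in (0, 1).
#' @export
fuse_and_classify <- function(pooled, risk, head) {
  x <- c(as.numeric(pooled), as.numeric(risk))
  if (length(head$W) != length(x)) {
    stop_validation("fusion head expects input width ", length(head$W),
                    ", got ", length(x))
  }
  sigmoid(sum(head$W * x) + head$b)
}

#' Fine-tune the malnutrition predictor on client windows
#'
#' The aggregated window text is encoded through the chunked pooling
#' pathway (windows average ~644 tokens and routinely exceed one 512-token
#' part). With `use_risk_factors = TRUE` the pooled embedding is
#' concatenated with the one-hot risk vector before the fully connected
#' sigmoid head; with `FALSE` the head sees the text embedding only (the
#' text-only ablation). Training mirrors [train_note_classifier()]:
#' stratified 85/15 holdout, weighted binary cross-entropy, best
#' validation-loss epoch.
#'
#' @param windows A list of `rac_window` objects with `risk_vector` fields
#'   (see [build_windows()]).
#' @param checkpoint An `rac_checkpoint`.
#' @param cfg An [classifier_config()].
#' @param use_risk_factors Fuse the structured risk vector (default `TRUE`).
#' @param embeddings Optional precomputed pooled window embeddings (one row
#'   per window) for the frozen-encoder path; see [encode_note()].
#' @return An object of class `rac_predictor` (a fitted classifier; the
#'   catalogue factor ordering used is stored in `factor_ids`).
#' @export
train_predictor <- function(windows, checkpoint, cfg = classifier_config(),
                            use_risk_factors = TRUE, embeddings = NULL) {
  labels <- vapply(windows, function(w) w$label, integer(1))
  texts <- vapply(windows, function(w) w$aggregated_text, character(1))
  risk <- NULL
  factor_ids <- NULL
  if (use_risk_factors) {
    risk <- do.call(rbind, lapply(windows, function(w) w$risk_vector))
    factor_ids <- colnames(risk) %||% names(windows[[1L]]$risk_vector)
  }
  fit <- fit_pooled_classifier(texts, labels, checkpoint, cfg, risk = risk,
                               embeddings = embeddings)
  fit$use_risk_factors <- use_risk_factors
  fit$factor_ids <- factor_ids
  class(fit) <- c("rac_predictor", class(fit))
  fit
}

#' Predict malnutrition risk for a client window
#'
#' @param model A fitted `rac_predictor`.
#' @param window An `rac_window` with a `risk_vector` (when the model was
#'   trained with risk-factor fusion).
#' @return A list with `probability` and `label`.
#' @export
predict_window <- function(model, window) {
  stopifnot(inherits(model, "rac_predictor"), inherits(window, "rac_window"))
  risk <- if (model$risk_dim > 0L) {
    matrix(window$risk_vector, nrow = 1L)
  }
  p <- classifier_scores(model, window$aggregated_text, risk = risk)
  list(probability = p, label = as.integer(p >= model$cfg$threshold))
}

#' Save a fitted predictor, preserving factor ordering
#'
#' @param model An `rac_predictor` (or `rac_note_classifier`).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
save_predictor <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(classes = class(model), risk_dim = model$risk_dim,
               factor_ids = model$factor_ids,
               threshold = model$cfg$threshold,
               pos_weight = model$pos_weight)
  jsonlite::write_json(meta, file.path(dir, "model_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a predictor saved by [save_predictor()]
#'
#' @param dir Model directory.
#' @return The fitted model.
#' @export
load_predictor <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}
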