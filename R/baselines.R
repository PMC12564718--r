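# Bag-of-words and static-embedding baselines with a logistic linear head.
#
# The baselines deliberately use the weakest reasonable classification head
# (ridge-regularised logistic regression) so that comparisons against the
# contextual encoder reflect the text representation, not the head.

#' Bag-of-words count features
#'
#' @param texts Character vector of (cleaned) texts.
#' @param vocabulary Optional character vector: a previously fitted
#'   vocabulary (e.g. fitted on the training split only, so test-only tokens
#'   are ignored rather than leaking columns).
#' @return A list with `matrix` (documents x vocabulary counts) and
#'   `vocabulary`.
#' @export
bow_features <- function(texts, vocabulary = NULL) {
  if (length(texts) == 0L) stop_validation("empty corpus")
  tok <- lapply(texts, basic_tokenize)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(tok, use.names = FALSE)))
    if (length(vocabulary) == 0L) stop_validation("corpus tokenised to nothing")
  }
  m <- matrix(0L, length(texts), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(tok)) {
    tb <- table(tok[[i]][tok[[i]] %in% vocabulary])
    if (length(tb)) m[i, names(tb)] <- as.integer(tb)
  }
  list(matrix = m, vocabulary = vocabulary)
}

#' Averaged static word-vector features
#'
#' Maps each text to the mean of its in-vocabulary word vectors;
#' out-of-vocabulary words are skipped and an all-OOV text maps to the zero
#' vector with a warning.
#'
#' @param texts Character vector of texts.
#' @param vector_table Numeric matrix with one row per word (rownames are
#'   the words).
#' @return Numeric matrix, one row per text.
#' @export
static_embedding_features <- function(texts, vector_table) {
  if (!is.matrix(vector_table) || nrow(vector_table) == 0L ||
      is.null(rownames(vector_table))) {
    stop_validation("vector_table must be a non-empty matrix with word rownames")
  }
  out <- matrix(0, length(texts), ncol(vector_table))
  any_oov <- FALSE
  for (i in seq_along(texts)) {
    words <- basic_tokenize(texts[i])
    hit <- words[words %in% rownames(vector_table)]
    if (length(hit) == 0L) {
      any_oov <- TRUE
    } else {
      out[i, ] <- colMeans(vector_table[hit, , drop = FALSE])
    }
  }
  if (any_oov) warning("text(s) with no in-vocabulary words mapped to the zero vector",
                       call. = FALSE)
  out
}

#' Random static word-vector table
#'
#' A seeded random vector table standing in for any external static
#' embedding file; any table with word rownames can be supplied instead.
#'
#' @param words Character vector of words to cover.
#' @param dim Vector width (default 50).
#' @param seed Integer seed.
#' @return Numeric matrix with `words` as rownames.
#' @export
random_vector_table <- function(words, dim = 50L, seed = 1L) {
  words <- unique(words)
  with_seed(seed, {
    matrix(stats::rnorm(length(words) * dim), length(words), dim,
           dimnames = list(words, NULL))
  })
}

# Ridge logistic head shared by the baselines; lambda kept small and fixed
# so the fit is deterministic and the representation dominates.
fit_logistic_head <- function(x, y, lambda = 1e-2) {
  if (ncol(x) < 2L) x <- cbind(x, 0)
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = FALSE)
}

predict_logistic_head <- function(fit, x) {
  if (ncol(x) < 2L) x <- cbind(x, 0)
  as.numeric(stats::predict(fit, newx = x, type = "response"))
}

#' Build a baseline trainer for [kfold_cv()]
#'
#' Returns a `(train, test, fold_seed) -> scores` closure over a
#' bag-of-words or static-embedding representation with a ridge logistic
#' head. The BOW vocabulary (or the embedding table lookup) is fitted on
#' the training split only.
#'
#' @param type `"bow"` or `"static"`.
#' @param vector_table Static vector table (required for `type = "static"`).
#' @return A trainer function usable with [kfold_cv()]; datasets must be
#'   data.frames with `text` and `label` columns.
#' @export
baseline_trainer <- function(type = c("bow", "static"), vector_table = NULL) {
  type <- match.arg(type)
  if (type == "static" && is.null(vector_table)) {
    stop_config("static baseline needs a vector_table")
  }
  function(train, test, fold_seed) {
    if (type == "bow") {
      tr <- bow_features(train$text)
      te <- bow_features(test$text, vocabulary = tr$vocabulary)
      fit <- fit_logistic_head(tr$matrix, train$label)
      predict_logistic_head(fit, te$matrix)
    } else {
      tr <- suppressWarnings(static_embedding_features(train$text, vector_table))
      te <- suppressWarnings(static_embedding_features(test$text, vector_table))
      fit <- fit_logistic_head(tr, train$label)
      predict_logistic_head(fit, te)
    }
  }
}
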