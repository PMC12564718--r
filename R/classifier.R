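# Binary classification heads over pooled note embeddings.
#
# Both downstream tasks share one training core: a dropout + linear + sigmoid
# head on the masked-mean pooled last hidden state (optionally concatenated
# with a structured risk-factor vector), trained with class-weighted binary
# cross-entropy. The encoder is fine-tuned jointly by default; with
# freeze_encoder the pooled embeddings are computed once and only the head is
# trained.

#' Configuration for fine-tuning a pooled-embedding classifier
#'
#' Defaults follow the fine-tuning recipe: learning rate 3e-5, batch size
#' 16, weight decay 0.01, 50% dropout, 4 epochs, 15% holdout, automatic
#' positive-class weighting, threshold 0.5. Note the default learning rate
#' is calibrated to a large pretrained encoder; the compact test-profile
#' encoder learns from random-ish initialisation and typically wants a much
#' larger rate (see the methods vignette).
#'
#' @param learning_rate AdamW learning rate (default 3e-5).
#' @param batch_size Samples per optimisation step (default 16).
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param dropout Dropout probability on the head input (default 0.5).
#' @param epochs Training epochs (default 4).
#' @param pos_weight Positive-class loss weight; `"auto"` (default) uses
#'   `N_neg / N_pos` of the training split.
#' @param threshold Hard-label threshold (default 0.5; label 1 iff
#'   probability >= threshold).
#' @param test_fraction Stratified holdout fraction (default 0.15). The
#'   remainder is split 80/20 into training and internal validation.
#' @param val_fraction Internal validation share of the non-holdout data
#'   (default 0.2).
#' @param freeze_encoder Train the head only, on embeddings computed once
#'   (default `FALSE`: encoder weights are fine-tuned jointly).
#' @param part_len Positions per encoder part for long inputs (default 512).
#' @param seed Integer seed for splits, shuffling, dropout and head init.
#' @return A list of class `rac_classifier_config`.
#' @export
classifier_config <- function(learning_rate = 3e-5, batch_size = 16L,
                              weight_decay = 0.01, dropout = 0.5,
                              epochs = 4L, pos_weight = "auto",
                              threshold = 0.5, test_fraction = 0.15,
                              val_fraction = 0.2, freeze_encoder = FALSE,
                              part_len = 512L, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) stop_config("learning_rate must be positive")
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs", positive = FALSE)
  check_prob(dropout, "dropout")
  if (!identical(pos_weight, "auto")) {
    if (!is.numeric(pos_weight) || pos_weight <= 0) stop_config("pos_weight must be positive or \"auto\"")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_config("threshold must lie strictly between 0 and 1")
  }
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop_config("test_fraction must lie strictly between 0 and 1")
  }
  check_prob(val_fraction, "val_fraction")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 weight_decay = weight_decay, dropout = dropout,
                 epochs = epochs, pos_weight = pos_weight,
                 threshold = threshold, test_fraction = test_fraction,
                 val_fraction = val_fraction,
                 freeze_encoder = isTRUE(freeze_encoder),
                 part_len = check_count(part_len, "part_len"),
                 seed = as.integer(seed)),
            class = "rac_classifier_config")
}

#' Positive-class weight from label imbalance
#'
#' @param labels Binary label vector with both classes present.
#' @return `N_negative / N_positive`.
#' @export
compute_pos_weight <- function(labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_validation("pos_weight needs both classes present")
  }
  n_neg / n_pos
}

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `-(w * y * log(p) + (1 - y) * log(1 - p))` with
#' `w = pos_weight`; reduces to standard binary cross-entropy at
#' `pos_weight = 1`. Probabilities exactly 0 or 1 are clamped at 1e-7 (a
#' message is emitted).
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary labels.
#' @param pos_weight Positive-class weight.
#' @return Scalar loss.
#' @export
weighted_bce <- function(probabilities, labels, pos_weight = 1) {
  if (length(probabilities) != length(labels)) {
    stop_validation("probabilities and labels must have equal length")
  }
  eps <- 1e-7
  if (any(probabilities <= 0 | probabilities >= 1)) {
    message("probabilities clamped to [1e-7, 1 - 1e-7]")
    probabilities <- pmin(pmax(probabilities, eps), 1 - eps)
  }
  y <- as.numeric(labels)
  -mean(pos_weight * y * log(probabilities) + (1 - y) * log(1 - probabilities))
}

# Per-class stratified index split: `fraction` of each class goes to the
# second component (rounded per class, so counts are preserved within 1).
stratified_split <- function(labels, fraction, seed) {
  labels <- as.integer(labels)
  idx_b <- integer(0)
  with_seed(seed, {
    for (cl in unique(labels)) {
      cl_idx <- sample(which(labels == cl))
      n_b <- round(fraction * length(cl_idx))
      idx_b <- c(idx_b, cl_idx[seq_len(n_b)])
    }
  })
  list(a = sort(setdiff(seq_along(labels), idx_b)), b = sort(idx_b))
}

segment_texts <- function(tokenizer, texts, part_len) {
  lapply(texts, function(t) {
    cleaned <- clean_text(t)
    ids <- encode_text(tokenizer, cleaned)$ids
    if (length(ids) == 0L) stop_validation("a text tokenised to zero tokens")
    segment(ids, part_len = part_len)
  })
}

# Forward pass for one sample; returns pooled vector (and caches when
# training the encoder jointly).
pooled_forward <- function(model, seg, cache = FALSE) {
  d <- model$cfg$d_model
  total <- numeric(d)
  caches <- if (cache) vector("list", length(seg$parts))
  pools <- vector("list", length(seg$parts))
  for (k in seq_along(seg$parts)) {
    n_real <- sum(seg$attention_masks[[k]])
    ids <- seg$parts[[k]][seq_len(n_real)]
    if (cache) {
      fwd <- encoder_forward(model, ids, cache = TRUE)
      H <- fwd$H
      caches[[k]] <- fwd
    } else {
      H <- encoder_forward(model, ids)
    }
    keep <- which(seg$pooling_masks[[k]][seq_len(n_real)] == 1L)
    pools[[k]] <- keep
    total <- total + colSums(H[keep, , drop = FALSE])
  }
  list(v = total / seg$content_token_count, caches = caches, pools = pools)
}

# The shared training core. `risk` is NULL or an n x R binary matrix.
# `embeddings` optionally supplies precomputed pooled vectors (one row per
# sample) for the frozen-encoder path; they are deterministic given the
# encoder weights, so this is purely a compute cache.
fit_pooled_classifier <- function(texts, labels, checkpoint, cfg, risk = NULL,
                                  embeddings = NULL) {
  stopifnot(inherits(checkpoint, "rac_checkpoint"),
            inherits(cfg, "rac_classifier_config"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop_validation("need both classes present")
  model <- checkpoint$model
  tokenizer <- checkpoint$tokenizer
  d <- model$cfg$d_model
  R <- if (is.null(risk)) 0L else ncol(risk)
  n <- length(labels)
  if (!is.null(risk) && nrow(risk) != n) stop_validation("risk matrix rows must match labels")

  sp <- stratified_split(labels, cfg$test_fraction, child_seed(cfg$seed, "holdout"))
  test_idx <- sp$b
  rest <- sp$a
  if (length(unique(labels[rest])) < 2L) stop_validation("single-class training split")
  sp2 <- stratified_split(labels[rest], cfg$val_fraction, child_seed(cfg$seed, "val"))
  train_idx <- rest[sp2$a]
  val_idx <- rest[sp2$b]
  if (length(unique(labels[train_idx])) < 2L) stop_validation("single-class training split")

  pos_weight <- if (identical(cfg$pos_weight, "auto")) {
    compute_pos_weight(labels[train_idx])
  } else {
    cfg$pos_weight
  }

  segs <- segment_texts(tokenizer, texts, cfg$part_len)
  emb <- NULL
  if (cfg$freeze_encoder) {
    if (!is.null(embeddings)) {
      if (nrow(embeddings) != n || ncol(embeddings) != d) {
        stop_validation("embeddings must be an n x d_model matrix")
      }
      emb <- embeddings
    } else {
      emb <- t(vapply(segs, function(s) pooled_forward(model, s)$v, numeric(d)))
    }
  }

  head <- with_seed(child_seed(cfg$seed, "head"), {
    list(W = stats::rnorm(d + R, sd = 0.02), b = 0)
  })

  eval_scores <- function(idx, enc) {
    vapply(idx, function(i) {
      v <- if (cfg$freeze_encoder) emb[i, ] else pooled_forward(enc, segs[[i]])$v
      x <- c(v, if (R > 0L) risk[i, ] else numeric(0))
      sigmoid(sum(head$W * x) + head$b)
    }, numeric(1))
  }

  opt <- adamw_init(model$params)
  opt_head <- list(m = list(W = numeric(d + R), b = 0),
                   v = list(W = numeric(d + R), b = 0), t = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, head = head, params = model$params, epoch = 0L)

  with_seed(child_seed(cfg$seed, "trainloop"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_idx)
      starts <- seq(1L, length(ord), by = cfg$batch_size)
      ep_loss <- 0
      ep_n <- 0L
      for (s in starts) {
        bidx <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        bs <- length(bidx)
        g <- if (!cfg$freeze_encoder) new_grad_env(model$params)
        dW <- numeric(d + R)
        db <- 0
        for (i in bidx) {
          y <- labels[i]
          if (cfg$freeze_encoder) {
            v <- emb[i, ]
            pf <- NULL
          } else {
            pf <- pooled_forward(model, segs[[i]], cache = TRUE)
            v <- pf$v
          }
          x <- c(v, if (R > 0L) risk[i, ] else numeric(0))
          keep_mask <- if (cfg$dropout > 0) {
            (stats::runif(d + R) >= cfg$dropout) / (1 - cfg$dropout)
          } else {
            rep(1, d + R)
          }
          xd <- x * keep_mask
          z <- sum(head$W * xd) + head$b
          p_hat <- sigmoid(z)
          w <- pos_weight
          pc <- min(max(p_hat, 1e-7), 1 - 1e-7)
          ep_loss <- ep_loss - (w * y * log(pc) + (1 - y) * log(1 - pc))
          ep_n <- ep_n + 1L
          dz <- p_hat * (w * y + 1 - y) - w * y
          dW <- dW + dz * xd
          db <- db + dz
          if (!cfg$freeze_encoder) {
            dv <- (dz * head$W * keep_mask)[seq_len(d)]
            seg <- segs[[i]]
            for (k in seq_along(seg$parts)) {
              keep <- pf$pools[[k]]
              if (length(keep) == 0L) next
              fwd <- pf$caches[[k]]
              dH <- matrix(0, nrow(fwd$H), d)
              dH[keep, ] <- matrix(dv / seg$content_token_count,
                                   length(keep), d, byrow = TRUE)
              encoder_backward(model, fwd, dH, g)
            }
          }
        }
        # mean-reduced gradients, with global-norm clipping on the head
        gh <- list(W = dW / bs, b = db / bs)
        hn <- sqrt(sum(gh$W^2) + gh$b^2)
        if (is.finite(hn) && hn > 1) gh <- lapply(gh, function(x) x / hn)
        opt_head$t <- opt_head$t + 1L
        for (nm in c("W", "b")) {
          opt_head$m[[nm]] <- 0.9 * opt_head$m[[nm]] + 0.1 * gh[[nm]]
          opt_head$v[[nm]] <- 0.999 * opt_head$v[[nm]] + 0.001 * gh[[nm]]^2
          upd <- (opt_head$m[[nm]] / (1 - 0.9^opt_head$t)) /
            (sqrt(opt_head$v[[nm]] / (1 - 0.999^opt_head$t)) + 1e-8)
          if (nm == "W") upd <- upd + cfg$weight_decay * head$W
          head[[nm]] <- head[[nm]] - cfg$learning_rate * upd
        }
        if (!cfg$freeze_encoder) {
          scale_grads(g, 1 / bs)
          clip_grads(g, 1)
          upd <- adamw_step(model$params, g$grads, opt,
                            lr = cfg$learning_rate,
                            weight_decay = cfg$weight_decay)
          model$params <- upd$params
          opt <- upd$state
        }
      }
      val_scores <- eval_scores(val_idx, model)
      vl <- suppressMessages(weighted_bce(
        pmin(pmax(val_scores, 1e-7), 1 - 1e-7), labels[val_idx], pos_weight))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / max(ep_n, 1L), val_loss = vl))
      if (vl < best$val) {
        best <- list(val = vl, head = head, params = model$params, epoch = ep)
      }
    }
  })

  # model selection: the epoch state with lowest validation loss
  if (cfg$epochs > 0L) {
    head <- best$head
    model$params <- best$params
  }
  test_scores <- eval_scores(test_idx, model)
  holdout <- if (length(test_idx) && length(unique(labels[test_idx])) == 2L) {
    fold_report(labels[test_idx], test_scores, cfg$threshold)
  }

  structure(list(model = model, head = head, tokenizer = tokenizer,
                 cfg = cfg, pos_weight = pos_weight, risk_dim = R,
                 history = history, best_epoch = best$epoch,
                 holdout = holdout,
                 holdout_scores = test_scores,
                 holdout_labels = labels[test_idx],
                 splits = list(train = train_idx, val = val_idx,
                               test = test_idx)),
            class = "rac_fitted_classifier")
}

classifier_scores <- function(fit, texts, risk = NULL) {
  segs <- segment_texts(fit$tokenizer, texts, fit$cfg$part_len)
  d <- fit$model$cfg$d_model
  vapply(seq_along(segs), function(i) {
    v <- pooled_forward(fit$model, segs[[i]])$v
    x <- c(v, if (fit$risk_dim > 0L) risk[i, ] else numeric(0))
    sigmoid(sum(fit$head$W * x) + fit$head$b)
  }, numeric(1))
}

#' Fine-tune the malnutrition-note classifier
#'
#' Splits off a stratified holdout (`test_fraction`), splits the remainder
#' into training and internal validation, trains a dropout + linear +
#' sigmoid head on the masked-mean pooled last hidden state with
#' class-weighted binary cross-entropy, and returns the epoch state with
#' the lowest validation loss, scored on the holdout.
#'
#' @param notes A data.frame with `text` and binary `label` columns.
#' @param checkpoint An `rac_checkpoint` (encoder + tokeniser), e.g. from
#'   [pretrain()].
#' @param cfg An [classifier_config()].
#' @return An object of class `rac_note_classifier` (a fitted classifier
#'   with `holdout` metrics, `history`, and the selected `best_epoch`).
#' @export
train_note_classifier <- function(notes, checkpoint, cfg = classifier_config()) {
  stopifnot(is.data.frame(notes), all(c("text", "label") %in% names(notes)))
  fit <- fit_pooled_classifier(notes$text, notes$label, checkpoint, cfg)
  class(fit) <- c("rac_note_classifier", class(fit))
  fit
}

#' Predict malnutrition status of a note
#'
#' @param model A fitted `rac_note_classifier`.
#' @param text Note text (character scalar or vector).
#' @return For a scalar, a list with `probability` and `label` (1 iff
#'   probability >= threshold); for a vector, a data.frame.
#' @export
predict_note <- function(model, text) {
  stopifnot(inherits(model, "rac_note_classifier"))
  cleaned <- clean_text(text)
  if (any(!nzchar(cleaned))) stop_validation("note text is empty after cleaning")
  p <- classifier_scores(model, text)
  lab <- as.integer(p >= model$cfg$threshold)
  if (length(text) == 1L) list(probability = p, label = lab)
  else data.frame(probability = p, label = lab)
}

#' @export
print.rac_fitted_classifier <- function(x, ...) {
  cat("<rac fitted classifier> best epoch", x$best_epoch)
  if (!is.null(x$holdout)) {
    cat(sprintf(" | holdout F1 %.3f AUROC %.3f", x$holdout$f1, x$holdout$auroc))
  }
  cat("\n")
  invisible(x)
}
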