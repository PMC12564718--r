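# Domain-adaptive masked-language-model pretraining.

#' Configuration for masked-LM pretraining
#'
#' Defaults follow the domain-adaptation recipe: learning rate 1e-4, batch
#' size 32, weight decay 0.01. `max_steps` bounds the run; training also
#' stops early once validation loss stops improving (relative improvement
#' below 0.5% across a 5-evaluation patience window).
#'
#' @param learning_rate AdamW learning rate (default 1e-4).
#' @param batch_size Chunks per optimisation step (default 32).
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param max_steps Maximum optimisation steps.
#' @param eval_every Steps between validation evaluations (default 10).
#' @param patience Evaluations in the early-stop window (default 5).
#' @param min_rel_improvement Early-stop threshold on relative validation
#'   improvement across the patience window (default 0.005).
#' @param max_val_chunks Validation chunks used per evaluation (default 32).
#' @param seed Integer seed governing initialisation, batching and masking.
#' @return A list of class `rac_pretrain_config`.
#' @export
pretrain_config <- function(learning_rate = 1e-4, batch_size = 32L,
                            weight_decay = 0.01, max_steps = 100L,
                            eval_every = 10L, patience = 5L,
                            min_rel_improvement = 0.005,
                            max_val_chunks = 32L, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) stop_config("learning_rate must be positive")
  batch_size <- check_count(batch_size, "batch_size")
  max_steps <- check_count(max_steps, "max_steps")
  eval_every <- check_count(eval_every, "eval_every")
  patience <- check_count(patience, "patience")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 weight_decay = weight_decay, max_steps = max_steps,
                 eval_every = eval_every, patience = patience,
                 min_rel_improvement = min_rel_improvement,
                 max_val_chunks = max_val_chunks, seed = as.integer(seed)),
            class = "rac_pretrain_config")
}

# Cross-entropy over masked positions for one batch; optionally accumulate
# parameter gradients (normalised by the number of labelled tokens).
mlm_batch_loss <- function(model, batch, g = NULL) {
  p <- model$params
  loss_sum <- 0
  n_lab <- 0L
  for (row in batch) {
    n_real <- row$n_real
    lab <- row$labels[seq_len(n_real)]
    pos <- which(!is.na(lab))
    if (length(pos) == 0L) next
    if (is.null(g)) {
      H <- encoder_forward(model, row$ids[seq_len(n_real)])
    } else {
      fwd <- encoder_forward(model, row$ids[seq_len(n_real)], cache = TRUE)
      H <- fwd$H
    }
    logits <- sweep(H[pos, , drop = FALSE] %*% p$mlm.W, 2L, p$mlm.b, `+`)
    mx <- apply(logits, 1L, max)
    E <- exp(logits - mx)
    Z <- rowSums(E)
    tgt <- lab[pos]
    loss_sum <- loss_sum + sum(log(Z) - (logits[cbind(seq_along(pos), tgt)] - mx))
    n_lab <- n_lab + length(pos)
    if (!is.null(g)) {
      P <- E / Z
      P[cbind(seq_along(pos), tgt)] <- P[cbind(seq_along(pos), tgt)] - 1
      g$grads$mlm.W <- g$grads$mlm.W + crossprod(H[pos, , drop = FALSE], P)
      g$grads$mlm.b <- g$grads$mlm.b + colSums(P)
      dH <- matrix(0, n_real, ncol(H))
      dH[pos, ] <- P %*% t(p$mlm.W)
      encoder_backward(model, fwd, dH, g)
    }
  }
  if (n_lab == 0L) return(list(loss = NA_real_, n = 0L))
  if (!is.null(g)) scale_grads(g, 1 / n_lab)
  list(loss = loss_sum / n_lab, n = n_lab)
}

validation_loss <- function(model, val_chunks, mask_cfg, seed) {
  if (length(val_chunks) == 0L) return(NA_real_)
  batch <- with_seed(seed, whole_word_mask(val_chunks, mask_cfg, model$cfg$vocab_size))
  mlm_batch_loss(model, batch)$loss
}

#' Pretrain the encoder with whole-word masked-language modelling
#'
#' Runs AdamW over freshly masked batches (mask patterns re-drawn every
#' epoch), evaluating masked cross-entropy on a fixed-mask validation subset
#' and early-stopping when improvement stalls. Fully deterministic for a
#' fixed config.
#'
#' @param corpus_train,corpus_val Lists of chunks from [chunk_corpus()]
#'   (typically via [split_train_val()]); `corpus_val` may be empty.
#' @param pretrain_cfg An [pretrain_config()].
#' @param mask_cfg An [masking_config()].
#' @param tokenizer The [rac_tokenizer][train_tokenizer] paired with the
#'   corpus.
#' @param encoder Optional pre-initialised `rac_encoder` to continue from;
#'   by default a tiny randomly initialised encoder profile is created.
#' @param encoder_cfg Optional [encoder_config()] used when `encoder` is
#'   `NULL`.
#' @return An object of class `rac_checkpoint`: `model`, `tokenizer`,
#'   `trace` (data.frame of step, train and validation loss) and `manifest`
#'   (all resolved hyperparameters, seed, steps run).
#' @export
pretrain <- function(corpus_train, corpus_val, pretrain_cfg, mask_cfg,
                     tokenizer, encoder = NULL, encoder_cfg = NULL) {
  stopifnot(inherits(pretrain_cfg, "rac_pretrain_config"),
            inherits(mask_cfg, "rac_mask_config"),
            inherits(tokenizer, "rac_tokenizer"))
  if (length(corpus_train) == 0L) stop_validation("empty pretraining corpus")
  if (is.null(encoder)) {
    if (is.null(encoder_cfg)) encoder_cfg <- encoder_config(tokenizer$vocab_size)
    encoder <- encoder_init(encoder_cfg, seed = child_seed(pretrain_cfg$seed, "init"))
  }
  model <- encoder
  V <- model$cfg$vocab_size
  opt <- adamw_init(model$params)
  trace <- list()
  val_seed <- child_seed(pretrain_cfg$seed, "valmask")
  val_sub <- corpus_val[seq_len(min(length(corpus_val), pretrain_cfg$max_val_chunks))]
  evals <- numeric(0)
  step <- 0L
  stopped_early <- FALSE
  init_val <- validation_loss(model, val_sub, mask_cfg, val_seed)
  with_seed(child_seed(pretrain_cfg$seed, "train"), {
    repeat {
      batches <- make_epoch_batches(corpus_train, mask_cfg,
                                    pretrain_cfg$batch_size, V)
      for (b in batches) {
        step <- step + 1L
        g <- new_grad_env(model$params)
        res <- mlm_batch_loss(model, b, g)
        if (!is.finite(res$loss)) {
          stop("masked-LM loss became non-finite at step ", step)
        }
        clip_grads(g, 1)
        upd <- adamw_step(model$params, g$grads, opt,
                          lr = pretrain_cfg$learning_rate,
                          weight_decay = pretrain_cfg$weight_decay)
        model$params <- upd$params
        opt <- upd$state
        vl <- NA_real_
        if (step %% pretrain_cfg$eval_every == 0L || step == pretrain_cfg$max_steps) {
          vl <- validation_loss(model, val_sub, mask_cfg, val_seed)
          if (!is.na(vl)) evals <- c(evals, vl)
        }
        trace[[step]] <- c(step = step, train_loss = res$loss, val_loss = vl)
        if (length(evals) > pretrain_cfg$patience) {
          window <- utils::tail(evals, pretrain_cfg$patience + 1L)
          rel <- (window[1L] - min(window[-1L])) / abs(window[1L])
          if (is.finite(rel) && rel < pretrain_cfg$min_rel_improvement) {
            stopped_early <- TRUE
            break
          }
        }
        if (step >= pretrain_cfg$max_steps) break
      }
      if (stopped_early || step >= pretrain_cfg$max_steps) break
    }
  })
  trace_df <- as.data.frame(do.call(rbind, trace))
  manifest <- list(
    task = "mlm_pretrain",
    learning_rate = pretrain_cfg$learning_rate,
    batch_size = pretrain_cfg$batch_size,
    weight_decay = pretrain_cfg$weight_decay,
    mask_prob = mask_cfg$mask_prob,
    whole_word = mask_cfg$whole_word,
    corruption_split = c(mask = mask_cfg$replace_mask_fraction,
                         random = mask_cfg$replace_random_fraction,
                         keep = mask_cfg$keep_fraction),
    steps_run = step, stopped_early = stopped_early,
    initial_val_loss = init_val,
    final_val_loss = if (length(evals)) utils::tail(evals, 1L) else NA_real_,
    n_train_chunks = length(corpus_train),
    n_val_chunks = length(corpus_val),
    encoder = unclass(model$cfg),
    seed = pretrain_cfg$seed
  )
  structure(list(model = model, tokenizer = tokenizer, trace = trace_df,
                 manifest = manifest),
            class = "rac_checkpoint")
}

#' @export
print.rac_checkpoint <- function(x, ...) {
  cat("<rac_checkpoint>", x$manifest$task %||% "encoder", "-",
      x$manifest$steps_run %||% NA, "steps, val loss",
      format(x$manifest$final_val_loss %||% NA, digits = 4), "\n")
  invisible(x)
}

#' Save a checkpoint directory
#'
#' Writes encoder weights, tokeniser vocabulary and a JSON run manifest.
#'
#' @param checkpoint An `rac_checkpoint`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_checkpoint <- function(checkpoint, dir) {
  stopifnot(inherits(checkpoint, "rac_checkpoint"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(checkpoint$model, file.path(dir, "encoder.rds"))
  save_tokenizer(checkpoint$tokenizer, file.path(dir, "tokenizer.json"))
  jsonlite::write_json(checkpoint$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(checkpoint$trace)) {
    utils::write.csv(checkpoint$trace, file.path(dir, "loss_trace.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a checkpoint directory written by [save_checkpoint()]
#'
#' @param dir Checkpoint directory.
#' @return An `rac_checkpoint`.
#' @export
load_checkpoint <- function(dir) {
  model <- readRDS(file.path(dir, "encoder.rds"))
  tokenizer <- load_tokenizer(file.path(dir, "tokenizer.json"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  trace_path <- file.path(dir, "loss_trace.csv")
  trace <- if (file.exists(trace_path)) utils::read.csv(trace_path) else NULL
  structure(list(model = model, tokenizer = tokenizer, trace = trace,
                 manifest = manifest),
            class = "rac_checkpoint")
}
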