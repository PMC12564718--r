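# Compact transformer encoder in base R.
#
# A post-LayerNorm encoder (multi-head self-attention + GELU feed-forward,
# learned token and position embeddings) with hand-derived backpropagation
# and an AdamW optimiser. Matrices are small enough (width 64, two layers by
# default) that BLAS-backed base R matmuls are adequate; the analytic
# gradients are verified against central finite differences in the test
# suite. Padding is always trailing, so a sequence is processed on its
# unpadded prefix; this is numerically identical to masked attention over
# the padded sequence and is what makes padding-invariance exact.

#' Configuration for the compact transformer encoder
#'
#' The default profile (2 layers, 4 heads, width 64) is deliberately small:
#' it runs the full pretraining and fine-tuning machinery on a single CPU
#' with no external checkpoint.
#'
#' @param vocab_size Vocabulary size of the paired tokeniser.
#' @param d_model Hidden width (default 64; must be divisible by `n_heads`).
#' @param n_layers Number of encoder blocks (default 2).
#' @param n_heads Attention heads per block (default 4).
#' @param d_ff Feed-forward inner width (default 128).
#' @param max_len Maximum sequence length in positions (default 512).
#' @return A list of class `rac_encoder_config`.
#' @export
encoder_config <- function(vocab_size, d_model = 64L, n_layers = 2L,
                           n_heads = 4L, d_ff = 128L, max_len = 512L) {
  vocab_size <- check_count(vocab_size, "vocab_size")
  d_model <- check_count(d_model, "d_model")
  n_layers <- check_count(n_layers, "n_layers")
  n_heads <- check_count(n_heads, "n_heads")
  d_ff <- check_count(d_ff, "d_ff")
  max_len <- check_count(max_len, "max_len")
  if (d_model %% n_heads != 0L) stop_config("d_model must be divisible by n_heads")
  structure(list(vocab_size = vocab_size, d_model = d_model,
                 n_layers = n_layers, n_heads = n_heads, d_ff = d_ff,
                 max_len = max_len, ln_eps = 1e-5),
            class = "rac_encoder_config")
}

#' Initialise a randomly weighted encoder
#'
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `rac_encoder`: `cfg` plus a flat named list of
#'   parameter matrices and vectors (including a masked-LM output head).
#' @export
encoder_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "rac_encoder_config"))
  d <- cfg$d_model
  f <- cfg$d_ff
  V <- cfg$vocab_size
  with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    p <- list(tok_emb = rn(V, d), pos_emb = rn(cfg$max_len, d))
    for (l in seq_len(cfg$n_layers)) {
      nm <- function(s) paste0("L", l, ".", s)
      p[[nm("Wq")]] <- rn(d, d); p[[nm("bq")]] <- numeric(d)
      p[[nm("Wk")]] <- rn(d, d); p[[nm("bk")]] <- numeric(d)
      p[[nm("Wv")]] <- rn(d, d); p[[nm("bv")]] <- numeric(d)
      p[[nm("Wo")]] <- rn(d, d); p[[nm("bo")]] <- numeric(d)
      p[[nm("ln1.g")]] <- rep(1, d); p[[nm("ln1.b")]] <- numeric(d)
      p[[nm("W1")]] <- rn(d, f); p[[nm("b1")]] <- numeric(f)
      p[[nm("W2")]] <- rn(f, d); p[[nm("b2")]] <- numeric(d)
      p[[nm("ln2.g")]] <- rep(1, d); p[[nm("ln2.b")]] <- numeric(d)
    }
    p[["mlm.W"]] <- rn(d, V)
    p[["mlm.b"]] <- numeric(V)
    structure(list(cfg = cfg, params = p), class = "rac_encoder")
  })
}

#' @export
print.rac_encoder <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("<rac_encoder>", x$cfg$n_layers, "layers, width", x$cfg$d_model,
    ",", x$cfg$n_heads, "heads, vocab", x$cfg$vocab_size,
    sprintf("(%.2fM parameters)\n", n_par / 1e6))
  invisible(x)
}

gelu <- function(x) x * stats::pnorm(x)
dgelu <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ln_fwd <- function(X, g, b, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, `*`)
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Run the encoder forward over one token sequence
#'
#' `attention_mask`, when supplied, must be a 0/1 vector whose ones form a
#' prefix (padding is trailing by construction everywhere in the package);
#' the sequence is cropped to that prefix, which is numerically identical to
#' masked attention over the padded row.
#'
#' @param model An `rac_encoder`.
#' @param ids Integer token ids.
#' @param attention_mask Optional 0/1 vector parallel to `ids`.
#' @param cache Keep intermediate activations for backpropagation.
#' @return If `cache = FALSE`, the last-hidden-state matrix (`L_real` rows,
#'   `d_model` columns). Otherwise a list with `H` and `caches`.
#' @export
encoder_forward <- function(model, ids, attention_mask = NULL, cache = FALSE) {
  stopifnot(inherits(model, "rac_encoder"))
  cfg <- model$cfg
  p <- model$params
  if (!is.null(attention_mask)) {
    n_real <- sum(attention_mask)
    if (any(attention_mask[seq_len(n_real)] != 1L)) {
      stop_validation("attention mask must be a prefix of ones (trailing padding)")
    }
    ids <- ids[seq_len(n_real)]
  }
  L <- length(ids)
  if (L < 1L) stop_validation("cannot encode an empty sequence")
  if (L > cfg$max_len) stop_validation("sequence length ", L, " exceeds max_len ", cfg$max_len)
  if (any(ids < 1L | ids > cfg$vocab_size)) stop_validation("token id out of vocabulary range")
  d <- cfg$d_model
  nh <- cfg$n_heads
  dh <- d %/% nh
  X <- p$tok_emb[ids, , drop = FALSE] + p$pos_emb[seq_len(L), , drop = FALSE]
  caches <- if (cache) vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(s) paste0("L", l, ".", s)
    Q <- sweep(X %*% p[[nm("Wq")]], 2L, p[[nm("bq")]], `+`)
    K <- sweep(X %*% p[[nm("Wk")]], 2L, p[[nm("bk")]], `+`)
    V <- sweep(X %*% p[[nm("Wv")]], 2L, p[[nm("bv")]], `+`)
    Oc <- matrix(0, L, d)
    A_list <- if (cache) vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      Oc[, cols] <- A %*% V[, cols, drop = FALSE]
      if (cache) A_list[[h]] <- A
    }
    AO <- sweep(Oc %*% p[[nm("Wo")]], 2L, p[[nm("bo")]], `+`)
    l1 <- ln_fwd(X + AO, p[[nm("ln1.g")]], p[[nm("ln1.b")]], cfg$ln_eps)
    X1 <- l1$Y
    Hpre <- sweep(X1 %*% p[[nm("W1")]], 2L, p[[nm("b1")]], `+`)
    Hact <- gelu(Hpre)
    FF <- sweep(Hact %*% p[[nm("W2")]], 2L, p[[nm("b2")]], `+`)
    l2 <- ln_fwd(X1 + FF, p[[nm("ln2.g")]], p[[nm("ln2.b")]], cfg$ln_eps)
    if (cache) {
      caches[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A_list, Oc = Oc,
                          l1 = l1, X1 = X1, Hpre = Hpre, Hact = Hact, l2 = l2)
    }
    X <- l2$Y
  }
  if (cache) list(H = X, caches = caches, ids = ids) else X
}

zero_grads <- function(params) {
  lapply(params, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
}

# Backpropagate dH through the encoder, accumulating into the grads
# environment `g` (a list in an environment, flat parameter names).
encoder_backward <- function(model, fwd, dH, g) {
  cfg <- model$cfg
  p <- model$params
  nh <- cfg$n_heads
  d <- cfg$d_model
  dh <- d %/% nh
  L <- nrow(dH)
  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    nm <- function(s) paste0("L", l, ".", s)
    cc <- fwd$caches[[l]]
    b2 <- ln_bwd(dX, cc$l2, p[[nm("ln2.g")]])
    g$grads[[nm("ln2.g")]] <- g$grads[[nm("ln2.g")]] + b2$dg
    g$grads[[nm("ln2.b")]] <- g$grads[[nm("ln2.b")]] + b2$db
    dsum2 <- b2$dX                       # grad of X1 + FF
    dFF <- dsum2
    g$grads[[nm("W2")]] <- g$grads[[nm("W2")]] + crossprod(cc$Hact, dFF)
    g$grads[[nm("b2")]] <- g$grads[[nm("b2")]] + colSums(dFF)
    dHact <- dFF %*% t(p[[nm("W2")]])
    dHpre <- dHact * dgelu(cc$Hpre)
    g$grads[[nm("W1")]] <- g$grads[[nm("W1")]] + crossprod(cc$X1, dHpre)
    g$grads[[nm("b1")]] <- g$grads[[nm("b1")]] + colSums(dHpre)
    dX1 <- dsum2 + dHpre %*% t(p[[nm("W1")]])
    b1 <- ln_bwd(dX1, cc$l1, p[[nm("ln1.g")]])
    g$grads[[nm("ln1.g")]] <- g$grads[[nm("ln1.g")]] + b1$dg
    g$grads[[nm("ln1.b")]] <- g$grads[[nm("ln1.b")]] + b1$db
    dsum1 <- b1$dX                       # grad of X + AO
    dAO <- dsum1
    g$grads[[nm("Wo")]] <- g$grads[[nm("Wo")]] + crossprod(cc$Oc, dAO)
    g$grads[[nm("bo")]] <- g$grads[[nm("bo")]] + colSums(dAO)
    dOc <- dAO %*% t(p[[nm("Wo")]])
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dOh <- dOc[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dh)
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    g$grads[[nm("Wq")]] <- g$grads[[nm("Wq")]] + crossprod(cc$X, dQ)
    g$grads[[nm("bq")]] <- g$grads[[nm("bq")]] + colSums(dQ)
    g$grads[[nm("Wk")]] <- g$grads[[nm("Wk")]] + crossprod(cc$X, dK)
    g$grads[[nm("bk")]] <- g$grads[[nm("bk")]] + colSums(dK)
    g$grads[[nm("Wv")]] <- g$grads[[nm("Wv")]] + crossprod(cc$X, dV)
    g$grads[[nm("bv")]] <- g$grads[[nm("bv")]] + colSums(dV)
    dX <- dsum1 + dQ %*% t(p[[nm("Wq")]]) + dK %*% t(p[[nm("Wk")]]) +
      dV %*% t(p[[nm("Wv")]])
  }
  ids <- fwd$ids
  rs <- rowsum(dX, group = ids)
  rows <- as.integer(rownames(rs))
  g$grads$tok_emb[rows, ] <- g$grads$tok_emb[rows, , drop = FALSE] + rs
  g$grads$pos_emb[seq_len(L), ] <- g$grads$pos_emb[seq_len(L), , drop = FALSE] + dX
  invisible(NULL)
}

new_grad_env <- function(params) {
  g <- new.env(parent = emptyenv())
  g$grads <- zero_grads(params)
  g
}

scale_grads <- function(g, s) {
  g$grads <- lapply(g$grads, function(x) x * s)
  invisible(NULL)
}

# Global L2-norm gradient clipping (the usual transformer stabiliser).
clip_grads <- function(g, max_norm = 1) {
  total <- sqrt(sum(vapply(g$grads, function(x) sum(x * x), numeric(1))))
  if (is.finite(total) && total > max_norm) scale_grads(g, max_norm / total)
  invisible(total)
}

# AdamW with decoupled weight decay on matrix-valued parameters only
# (embeddings and projection/FFN/head weights); LayerNorm parameters and
# biases are not decayed.
adamw_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (all(gmat == 0)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (is.matrix(params[[nm]]) && weight_decay > 0) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
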