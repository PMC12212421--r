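# Attention-based MIL transformer, written directly in R matrix algebra with
# hand-derived backpropagation (verified against finite differences in the
# test suite). One bag = one sample: instance embeddings are encoded by a
# small pre-norm transformer, pooled by a learned attention head, and mapped
# to a bag-level probability through a sigmoid.

#' MIL model configuration
#'
#' @param embed_dim_in Input embedding dimension D (must match the bags).
#' @param model_dim Transformer width (default 512); must be divisible by
#'   `n_heads`.
#' @param n_layers Number of transformer layers (default 2).
#' @param n_heads Number of attention heads (default 8).
#' @param dropout Dropout probability on the FFN hidden layer (default 0).
#' @param epochs Maximum training epochs (default 64).
#' @param patience Early-stopping patience in epochs (default 15).
#' @param lr_max Peak learning rate for cosine annealing (default 1e-4).
#' @param lr_initial Optimizer-default initial learning rate recorded in the
#'   configuration (1e-3); the schedule anneals from `lr_max`.
#' @param momentum ADAM first-moment decay (default 0.95).
#' @param aug_prob Per-epoch, per-bag probability of feeding the augmented
#'   twin (default 0.5).
#' @param n_folds Cross-validation folds (default 5).
#' @param batch_size Bags per optimizer step (default 32).
#' @param attn_dim Hidden width of the attention-pooling head.
#' @param seed Seed for weights, folds and augmentation coins (default 1337).
#' @return A `mil_config` list.
#' @export
mil_config <- function(embed_dim_in, model_dim = 512L, n_layers = 2L,
                       n_heads = 8L, dropout = 0, epochs = 64L,
                       patience = 15L, lr_max = 1e-4, lr_initial = 1e-3,
                       momentum = 0.95, aug_prob = 0.5, n_folds = 5L,
                       batch_size = 32L, attn_dim = max(16L, model_dim %/% 8L),
                       seed = 1337L) {
  stopifnot(embed_dim_in >= 1, model_dim %% n_heads == 0, n_folds >= 2,
            patience <= epochs)
  assert_prob(dropout, "dropout"); assert_prob(aug_prob, "aug_prob")
  structure(list(embed_dim_in = as.integer(embed_dim_in),
                 model_dim = as.integer(model_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), dropout = dropout,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 lr_max = lr_max, lr_initial = lr_initial,
                 momentum = momentum, aug_prob = aug_prob,
                 n_folds = as.integer(n_folds),
                 batch_size = as.integer(batch_size),
                 attn_dim = as.integer(attn_dim), seed = as.integer(seed)),
            class = "mil_config")
}

# broadcast a length-d vector across the rows of an N x d matrix
.bcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

mil_init <- function(cfg) {
  D <- cfg$embed_dim_in; d <- cfg$model_dim; f <- 2L * d; da <- cfg$attn_dim
  xav <- function(n_in, n_out)
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
  p <- list(W_in = xav(D, d), b_in = numeric(d))
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d_", l)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- numeric(d)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- xav(d, d)
    for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- xav(d, f); p[[paste0(pre, "b1")]] <- numeric(f)
    p[[paste0(pre, "W2")]] <- xav(f, d); p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p$pool_Wa <- xav(d, da); p$pool_ba <- numeric(da)
  p$pool_va <- stats::rnorm(da, sd = 1 / sqrt(da))
  p$head_w <- stats::rnorm(d, sd = 1 / sqrt(d)); p$head_b <- 0
  p
}

ln_fwd <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = xhat * .bcast(g, n) + .bcast(b, n), xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * .bcast(g, n)
  xhat <- cache$xhat
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(s) {
  e <- exp(s - s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))])
  e / rowSums(e)
}

# full forward pass; returns score, attention and (optionally) the cache
# needed for backpropagation
mil_fwd <- function(X, p, cfg, keep_cache = FALSE, drop_masks = NULL) {
  n <- nrow(X); d <- cfg$model_dim; nh <- cfg$n_heads; dk <- d %/% nh
  H <- X %*% p$W_in + .bcast(p$b_in, n)
  cache <- list(X = X, H_in = list(), ln1 = list(), ln2 = list(),
                attn = list(), ffn = list())
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d_", l)
    if (keep_cache) cache$H_in[[l]] <- H
    l1 <- ln_fwd(H, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    Z <- l1$y
    Q <- Z %*% p[[paste0(pre, "Wq")]] + .bcast(p[[paste0(pre, "bq")]], n)
    K <- Z %*% p[[paste0(pre, "Wk")]] + .bcast(p[[paste0(pre, "bk")]], n)
    V <- Z %*% p[[paste0(pre, "Wv")]] + .bcast(p[[paste0(pre, "bv")]], n)
    Ocat <- matrix(0, n, d)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
      A <- softmax_rows(S)
      A_heads[[h]] <- A
      Ocat[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    O <- Ocat %*% p[[paste0(pre, "Wo")]] + .bcast(p[[paste0(pre, "bo")]], n)
    H <- H + O
    if (keep_cache) {
      cache$ln1[[l]] <- l1
      cache$attn[[l]] <- list(Z = Z, Q = Q, K = K, V = V, A = A_heads,
                              Ocat = Ocat, H_mid = H)
    }
    l2 <- ln_fwd(H, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    U <- l2$y %*% p[[paste0(pre, "W1")]] + .bcast(p[[paste0(pre, "b1")]], n)
    Ur <- U * (U > 0)
    if (!is.null(drop_masks)) Ur <- Ur * drop_masks[[l]]
    Fo <- Ur %*% p[[paste0(pre, "W2")]] + .bcast(p[[paste0(pre, "b2")]], n)
    H <- H + Fo
    if (keep_cache) {
      cache$ln2[[l]] <- l2
      cache$ffn[[l]] <- list(U = U, Ur = Ur)
    }
  }
  Tm <- tanh(H %*% p$pool_Wa + .bcast(p$pool_ba, n))
  s <- as.numeric(Tm %*% p$pool_va)
  a <- as.numeric(softmax_rows(matrix(s, 1)))
  bag <- as.numeric(crossprod(matrix(a, ncol = 1), H))
  logit <- sum(bag * p$head_w) + p$head_b
  out <- list(score = stats::plogis(logit), logit = logit, attention = a)
  if (keep_cache) {
    cache$H_final <- H; cache$Tm <- Tm; cache$a <- a; cache$bag <- bag
    out$cache <- cache
  }
  out
}

# backpropagate d(loss)/d(logit) through the cached forward pass
mil_bwd <- function(dlogit, p, cfg, cache, drop_masks = NULL) {
  n <- nrow(cache$X); d <- cfg$model_dim; nh <- cfg$n_heads; dk <- d %/% nh
  g <- list()
  H <- cache$H_final; a <- cache$a; Tm <- cache$Tm
  g$head_w <- dlogit * cache$bag
  g$head_b <- dlogit
  d_bag <- dlogit * p$head_w
  dH <- a %o% d_bag
  da <- as.numeric(H %*% d_bag)
  ds <- a * (da - sum(a * da))
  dT <- ds %o% p$pool_va
  g$pool_va <- as.numeric(crossprod(Tm, ds))
  dpre <- dT * (1 - Tm * Tm)
  g$pool_Wa <- crossprod(H, dpre)
  g$pool_ba <- colSums(dpre)
  dH <- dH + tcrossprod(dpre, p$pool_Wa)

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d_", l)
    # FFN sublayer
    ffn <- cache$ffn[[l]]; l2 <- cache$ln2[[l]]
    dF <- dH
    g[[paste0(pre, "W2")]] <- crossprod(ffn$Ur, dF)
    g[[paste0(pre, "b2")]] <- colSums(dF)
    dUr <- tcrossprod(dF, p[[paste0(pre, "W2")]])
    if (!is.null(drop_masks)) dUr <- dUr * drop_masks[[l]]
    dU <- dUr * (ffn$U > 0)
    g[[paste0(pre, "W1")]] <- crossprod(l2$y, dU)
    g[[paste0(pre, "b1")]] <- colSums(dU)
    dZ2 <- tcrossprod(dU, p[[paste0(pre, "W1")]])
    lb2 <- ln_bwd(dZ2, l2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dH <- dH + lb2$dx

    # attention sublayer
    at <- cache$attn[[l]]; l1 <- cache$ln1[[l]]
    dO <- dH
    g[[paste0(pre, "Wo")]] <- crossprod(at$Ocat, dO)
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dOcat <- tcrossprod(dO, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (h in seq_len(nh)) {
      idx <- ((h - 1) * dk + 1):(h * dk)
      A <- at$A[[h]]
      dOh <- dOcat[, idx, drop = FALSE]
      Vh <- at$V[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(A * dA))
      dQ[, idx] <- dS %*% at$K[, idx, drop = FALSE] / sqrt(dk)
      dK[, idx] <- crossprod(dS, at$Q[, idx, drop = FALSE]) / sqrt(dk)
    }
    Z <- at$Z
    g[[paste0(pre, "Wq")]] <- crossprod(Z, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(Z, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(Z, dV)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    dZ <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, p[[paste0(pre, "Wv")]])
    lb1 <- ln_bwd(dZ, l1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dH <- dH + lb1$dx
  }
  g$W_in <- crossprod(cache$X, dH)
  g$b_in <- colSums(dH)
  g
}

#' Weighted binary cross-entropy with inverse class-proportion weights
#'
#' Each sample's cross-entropy is multiplied by the inverse proportion of
#' its class and the result averaged.
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param labels Binary labels (0/1).
#' @param class_proportions Named vector with elements `pos` and `neg`
#'   giving the class proportions; both must be > 0.
#' @return The scalar loss.
#' @export
weighted_bce <- function(probabilities, labels, class_proportions) {
  if (any(class_proportions <= 0))
    stop("class with zero proportion: weighted BCE undefined", call. = FALSE)
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  w <- ifelse(labels == 1, 1 / class_proportions[["pos"]],
              1 / class_proportions[["neg"]])
  mean(w * -(labels * log(p) + (1 - labels) * log(1 - p)))
}

#' Score a single bag with a trained MIL model
#'
#' @param bag An `instance_bag` (plain embeddings are used) or a bare N x D
#'   matrix.
#' @param model A trained MIL model (as returned per fold by
#'   [train_mil_cv()]).
#' @return A `mil_prediction`: `patient_id`, `score` in `[0, 1]`, and
#'   per-instance `attention` weights summing to 1.
#' @export
mil_forward <- function(bag, model) {
  X <- if (inherits(bag, "instance_bag")) bag$embeddings else bag
  if (is.null(X) || nrow(X) == 0L) stop("empty bag", call. = FALSE)
  if (ncol(X) != model$config$embed_dim_in)
    stop(sprintf("bag dimension %d does not match model embed_dim_in %d",
                 ncol(X), model$config$embed_dim_in), call. = FALSE)
  X <- apply_norm(X, model$norm)
  out <- mil_fwd(X, model$params, model$config)
  structure(list(patient_id = if (inherits(bag, "instance_bag")) bag$patient_id else "",
                 score = out$score, attention = out$attention),
            class = "mil_prediction")
}

adam_step <- function(p, g, state, lr, beta1, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(g)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g[[nm]] * 0
      state$v[[nm]] <- g[[nm]] * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}
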