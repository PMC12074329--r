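# Forward pass of the patch transformer.
#
# Each channel is instance-normalised over its observed samples, cut into
# patches, linearly projected and position-encoded, run through a stack of
# transformer encoder layers whose attention masks out invalid patches, and
# average-pooled over valid tokens. The two channel summaries are
# concatenated and mapped to an adverse-outcome probability by a dense layer
# with a sigmoid. Every function returns enough intermediate state for the
# matching backward pass in model-backward.R.

NORM_EPS <- 1e-8
PROB_EPS <- 1e-7

#' Instance normalisation of one channel
#'
#' Standardises a series to zero mean and unit variance, computing the
#' statistics over observed positions only (population SD, epsilon-guarded).
#' Masked positions are set to 0 in the output so they cannot leak into
#' downstream computation.
#'
#' @param x Numeric series.
#' @param valid Logical mask, `TRUE` = observed; `NULL` means all observed.
#' @return List: `values` (normalised series), `mu`, `sigma`.
#' @export
#' @examples
#' instance_normalize(c(1, 2, 3, 4))$values
instance_normalize <- function(x, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  if (!any(valid)) {
    abort("Channel has no observed samples.", class = "ctg_degenerate_channel")
  }
  obs <- x[valid]
  mu <- mean(obs)
  sigma <- sqrt(mean((obs - mu)^2))
  out <- (x - mu) / (sigma + NORM_EPS)
  out[!valid] <- 0
  list(values = out, mu = mu, sigma = sigma)
}

# Optional same-padded moving-average input smoother (width kernel_size),
# renormalised over observed neighbours; masked positions stay 0. Fixed
# (non-trained) by design.
smooth_series <- function(x, valid, kernel_size) {
  n <- length(x)
  half <- kernel_size %/% 2
  w <- as.numeric(valid)
  num <- rep(0, n); den <- rep(0, n)
  for (off in -half:half) {
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    num[ok] <- num[ok] + (x * w)[src[ok]]
    den[ok] <- den[ok] + w[src[ok]]
  }
  out <- ifelse(den > 0, num / den, 0)
  out[!valid] <- 0
  out
}

#' Cut a series into patches
#'
#' Patch `j` (0-based) covers input indices `[j*stride, j*stride + patch_len)`
#' (0-based, half-open); the number of patches follows [patch_count()]. A
#' patch is valid iff at least half of its positions are observed.
#'
#' @param x Numeric series of length L.
#' @param valid Logical mask; `NULL` = all observed.
#' @param patch_len,stride Patch length P and stride S.
#' @return List: `patches` (N x P matrix), `patch_valid` (N logicals),
#'   `n_patches`.
#' @export
#' @examples
#' make_patches(1:10, patch_len = 4, stride = 2)$patches
make_patches <- function(x, valid = NULL, patch_len, stride) {
  L <- length(x)
  if (patch_len > L) {
    abort("`patch_len` exceeds the series length.", class = "ctg_config_error")
  }
  if (is.null(valid)) valid <- rep(TRUE, L)
  N <- patch_count(L, patch_len, stride)
  idx <- outer((seq_len(N) - 1L) * stride, seq_len(patch_len), `+`)
  patches <- matrix(x[idx], N, patch_len)
  obs_frac <- rowMeans(matrix(valid[idx], N, patch_len))
  list(patches = patches, patch_valid = obs_frac >= 0.5, n_patches = N)
}

#' Project patches into the latent space and add positional encodings
#'
#' Token `j` is `W_P' p_j + W_pos[j, ]`.
#'
#' @param patches N x P patch matrix.
#' @param W_P P x d projection matrix.
#' @param W_pos N x d learned positional table.
#' @return N x d token matrix.
#' @export
embed_patches <- function(patches, W_P, W_pos) {
  if (ncol(patches) != nrow(W_P) || nrow(patches) != nrow(W_pos) ||
      ncol(W_P) != ncol(W_pos)) {
    abort("Shape mismatch between patches, W_P and W_pos.",
          class = "ctg_config_error")
  }
  patches %*% W_P + W_pos
}

#' Masked scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with invalid keys receiving -Inf scores
#' (exactly zero weight) and invalid queries returning zero context rows.
#'
#' @param Q,K,V N x d_k (and N x d_v) matrices.
#' @param key_valid Logical mask over rows of K/V; `NULL` = all valid.
#' @param query_valid Logical mask over rows of Q; `NULL` = all valid.
#' @return List: `context` (N x d_v), `weights` (N x N attention matrix).
#' @export
#' @examples
#' scaled_dot_attention(matrix(c(1, 0)), matrix(c(1, 0)), matrix(c(1, 0)))
scaled_dot_attention <- function(Q, K, V, key_valid = NULL,
                                 query_valid = NULL) {
  dk <- ncol(K)
  if (is.null(key_valid)) key_valid <- rep(TRUE, nrow(K))
  if (is.null(query_valid)) query_valid <- rep(TRUE, nrow(Q))
  if (!any(key_valid) && any(query_valid)) {
    abort("All keys are invalid for a valid query.",
          class = "ctg_masked_attention")
  }
  scores <- Q %*% t(K) / sqrt(dk)
  scores[, !key_valid] <- -Inf
  W <- row_softmax(scores)
  ctx <- W %*% V
  ctx[!query_valid, ] <- 0
  list(context = ctx, weights = W)
}

act_fun <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         gelu = x * stats::pnorm(x),
         elu = ifelse(x > 0, x, exp(x) - 1))
}

act_grad <- function(x, activation) {
  switch(activation,
         relu = (x > 0) * 1,
         gelu = stats::pnorm(x) + x * stats::dnorm(x),
         elu = ifelse(x > 0, 1, exp(x)))
}

# Row-wise layer normalisation with scale g and shift b; returns cache for
# the backward pass.
layer_norm_fwd <- function(Z, g, b) {
  m <- rowMeans(Z)
  C <- Z - m
  v <- rowMeans(C * C)
  inv <- 1 / sqrt(v + NORM_EPS)
  Xhat <- C * inv
  out <- sweep(Xhat, 2L, g, `*`)
  out <- sweep(out, 2L, b, `+`)
  list(out = out, Xhat = Xhat, inv = inv)
}

# Inverted-dropout mask (already scaled); NULL when rate is 0 or eval mode.
drop_mask <- function(dim, rate, training) {
  if (!training || rate <= 0) return(NULL)
  matrix((runif(prod(dim)) >= rate) / (1 - rate), dim[1], dim[2])
}

apply_drop <- function(X, mask) if (is.null(mask)) X else X * mask

# Multi-head self-attention with masking; returns output and cache.
mhsa_fwd <- function(X, tok_valid, lp, config, training) {
  d <- config$d_model; h <- config$n_heads; dk <- d %/% h
  N <- nrow(X)
  Q <- X %*% lp$Wq; Q <- sweep(Q, 2L, lp$bq, `+`)
  K <- X %*% lp$Wk; K <- sweep(K, 2L, lp$bk, `+`)
  V <- X %*% lp$Wv; V <- sweep(V, 2L, lp$bv, `+`)
  C <- matrix(0, N, d)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    S[, !tok_valid] <- -Inf
    W <- row_softmax(S)
    mask <- drop_mask(dim(W), config$attn_dropout, training)
    Wd <- apply_drop(W, mask)
    C[, cols] <- Wd %*% V[, cols, drop = FALSE]
    heads[[i]] <- list(W = W, mask = mask)
  }
  C[!tok_valid, ] <- 0
  O <- C %*% lp$Wo; O <- sweep(O, 2L, lp$bo, `+`)
  list(out = O, cache = list(X = X, Q = Q, K = K, V = V, C = C, heads = heads))
}

# One encoder layer: post-norm residual MHSA + FFN blocks.
encoder_layer_fwd <- function(X, tok_valid, lp, config, training) {
  at <- mhsa_fwd(X, tok_valid, lp, config, training)
  ln1 <- layer_norm_fwd(X + at$out, lp$g1, lp$c1)
  X1 <- ln1$out
  Hpre <- X1 %*% lp$W1; Hpre <- sweep(Hpre, 2L, lp$f1, `+`)
  H <- act_fun(Hpre, config$activation)
  ff_mask <- drop_mask(dim(H), config$dropout, training)
  Hd <- apply_drop(H, ff_mask)
  F_ <- Hd %*% lp$W2; F_ <- sweep(F_, 2L, lp$f2, `+`)
  ln2 <- layer_norm_fwd(X1 + F_, lp$g2, lp$c2)
  list(out = ln2$out,
       cache = list(attn = at$cache, ln1 = ln1, X1 = X1, Hpre = Hpre,
                    Hd = Hd, ff_mask = ff_mask, ln2 = ln2))
}

#' Run one transformer encoder layer
#'
#' Post-norm residual composition
#' `LN(x + MHSA(x))` then `LN(. + FFN(.))`, with invalid tokens masked out of
#' attention. Evaluation mode (no dropout).
#'
#' @param tokens N x d token matrix.
#' @param token_valid Logical validity per token; `NULL` = all valid.
#' @param layer_params One element of `model$params$channels[[i]]$layers`.
#' @param config The [model_config()].
#' @return The transformed N x d token matrix.
#' @export
encoder_layer <- function(tokens, token_valid = NULL, layer_params, config) {
  if (is.null(token_valid)) token_valid <- rep(TRUE, nrow(tokens))
  encoder_layer_fwd(tokens, token_valid, layer_params, config,
                    training = FALSE)$out
}

#' Masked global average pooling over tokens
#'
#' Mean of the valid token rows.
#'
#' @param tokens N x d matrix.
#' @param token_valid Logical mask; `NULL` = all valid.
#' @return Length-d numeric vector.
#' @export
pool_tokens <- function(tokens, token_valid = NULL) {
  if (is.null(token_valid)) token_valid <- rep(TRUE, nrow(tokens))
  if (!any(token_valid)) {
    abort("No valid tokens to pool.", class = "ctg_degenerate_window")
  }
  colMeans(tokens[token_valid, , drop = FALSE])
}

#' Concatenate channel summaries (FHR first)
#'
#' @param g_fhr,g_toco Pooled channel vectors of equal length.
#' @return Concatenated vector of length `2 d`.
#' @export
aggregate_channels <- function(g_fhr, g_toco) {
  if (is.null(g_fhr) || is.null(g_toco) || length(g_fhr) != length(g_toco)) {
    abort("Both channel summaries are required.", class = "ctg_config_error")
  }
  c(g_fhr, g_toco)
}

#' Sigmoid classification head
#'
#' @param g Aggregated feature vector.
#' @param W_c Weight vector of the same length.
#' @param b_c Scalar bias.
#' @return List: `probability`, `logit`.
#' @export
classify <- function(g, W_c, b_c) {
  logit <- sum(W_c * g) + b_c
  list(probability = sigmoid(logit), logit = logit)
}

#' Binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))` with the probability clamped away from
#' 0 and 1; vectorised, mean over the batch via `mean()`.
#'
#' @param y Binary labels (0/1).
#' @param y_hat Predicted probabilities.
#' @return Per-element loss vector.
#' @export
#' @examples
#' bce_loss(1, 0.5)           # log(2)
bce_loss <- function(y, y_hat) {
  if (!all(y %in% c(0, 1))) {
    abort("Labels must be 0 or 1.", class = "ctg_label_error")
  }
  p <- pmin(pmax(y_hat, PROB_EPS), 1 - PROB_EPS)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# Full forward pass over one window; returns prediction and (optionally) the
# cache needed for the backward pass.
forward_window <- function(values, valid, params, config, training = FALSE,
                           keep_cache = FALSE) {
  ch_caches <- vector("list", config$n_channels)
  pooled <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    x <- values[ch, ]; v <- valid[ch, ]
    inorm <- instance_normalize(x, v)
    xs <- if (isTRUE(config$smooth_input)) {
      smooth_series(inorm$values, v, config$kernel_size)
    } else inorm$values
    ps <- make_patches(xs, v, config$patch_len, config$stride)
    cp <- params$channels[[ch]]
    tokens <- embed_patches(ps$patches, cp$W_P, cp$W_pos)
    emb_mask <- drop_mask(dim(tokens), config$dropout, training)
    X <- apply_drop(tokens, emb_mask)
    layer_caches <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      fl <- encoder_layer_fwd(X, ps$patch_valid, cp$layers[[l]], config,
                              training)
      X <- fl$out
      layer_caches[[l]] <- fl$cache
    }
    pooled[[ch]] <- pool_tokens(X, ps$patch_valid)
    if (keep_cache) {
      ch_caches[[ch]] <- list(patches = ps$patches,
                              patch_valid = ps$patch_valid,
                              emb_mask = emb_mask, layers = layer_caches)
    }
  }
  g <- do.call(aggregate_channels, pooled)
  fc_mask <- if (training && config$fc_dropout > 0) {
    (runif(length(g)) >= config$fc_dropout) / (1 - config$fc_dropout)
  } else NULL
  gd <- if (is.null(fc_mask)) g else g * fc_mask
  cl <- classify(gd, params$Wc, params$bc)
  out <- list(probability = cl$probability, logit = cl$logit)
  if (keep_cache) {
    out$cache <- list(channels = ch_caches, g = gd, fc_mask = fc_mask,
                      pooled = pooled)
  }
  out
}

#' Forward pass for one CTG window
#'
#' Composes instance normalisation, patching, embedding, the encoder stack,
#' masked pooling, channel aggregation and the sigmoid head. Deterministic
#' (no dropout) in evaluation mode.
#'
#' @param window One row of a windows tibble (a list with `values` 2 x L and
#'   `valid` 2 x L), or the two matrices given separately.
#' @param model A `ctg_model` from [init_model()] or [train_model()].
#' @return List: `probability`, `logit`.
#' @export
forward <- function(window, model) {
  forward_window(window$values, window$valid, model$params, model$config,
                 training = FALSE)
}

#' Predict adverse-outcome probabilities for a set of windows
#'
#' @param object A `ctg_model`.
#' @param windows A windows tibble (see [prepare_windows()]).
#' @param ... Unused.
#' @return The windows tibble with a `score` column appended (and the
#'   list-columns dropped), a *prediction set* usable by [roc_curve()],
#'   [operating_points()] and [temporal_sweep()].
#' @export
predict.ctg_model <- function(object, windows, ...) {
  scores <- vapply(seq_len(nrow(windows)), function(i) {
    forward_window(windows$values[[i]], windows$valid[[i]],
                   object$params, object$config)$probability
  }, 0)
  out <- windows[, setdiff(names(windows), c("values", "valid")), drop = FALSE]
  out$score <- scores
  out
}
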