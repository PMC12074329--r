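# Reverse-mode gradients for the patch transformer.
#
# Mirrors model-forward.R exactly: classification head -> channel pooling ->
# encoder layers (post-norm residual MHSA + FFN) -> patch embedding. The
# input series is data, so gradients stop at W_P / W_pos. Gradient containers
# share the nesting of `model$params`, which lets the optimiser treat the
# whole model as one tree of numeric leaves.

# Apply f elementwise to the numeric leaves of parallel trees.
tree_map <- function(f, a, b = NULL, c = NULL, d = NULL) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) {
      out[[k]] <- tree_map(f,
                           a[[k]],
                           if (!is.null(b)) b[[k]],
                           if (!is.null(c)) c[[k]],
                           if (!is.null(d)) d[[k]])
    }
    out
  } else {
    if (is.null(b)) f(a) else if (is.null(c)) f(a, b)
    else if (is.null(d)) f(a, b, c) else f(a, b, c, d)
  }
}

zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# Layer-norm backward. dOut: upstream gradient; cache from layer_norm_fwd.
layer_norm_bwd <- function(dOut, cache, g) {
  dXhat <- sweep(dOut, 2L, g, `*`)
  dg <- colSums(dOut * cache$Xhat)
  db <- colSums(dOut)
  dZ <- cache$inv * (dXhat - rowMeans(dXhat) -
                       cache$Xhat * rowMeans(dXhat * cache$Xhat))
  list(dZ = dZ, dg = dg, db = db)
}

# Multi-head attention backward; returns dX and a gradient list matching the
# attention entries of the layer parameter list.
mhsa_bwd <- function(dO, cache, tok_valid, lp, config) {
  d <- config$d_model; h <- config$n_heads; dk <- d %/% h
  X <- cache$X
  dWo <- t(cache$C) %*% dO
  dbo <- colSums(dO)
  dC <- dO %*% t(lp$Wo)
  dC[!tok_valid, ] <- 0                      # context of invalid queries was forced 0
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    hd <- cache$heads[[i]]
    dCh <- dC[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    Wd <- apply_drop(hd$W, hd$mask)
    dV[, cols] <- t(Wd) %*% dCh
    dWd <- dCh %*% t(Vh)
    dW <- apply_drop(dWd, hd$mask)           # dropout backward = same scaling
    # Softmax backward, row-wise; masked keys have weight 0 -> gradient 0.
    dS <- hd$W * (dW - rowSums(dW * hd$W))
    dS <- dS / sqrt(dk)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE]
  }
  dX <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  grads <- list(Wq = t(X) %*% dQ, bq = colSums(dQ),
                Wk = t(X) %*% dK, bk = colSums(dK),
                Wv = t(X) %*% dV, bv = colSums(dV),
                Wo = dWo, bo = dbo)
  list(dX = dX, grads = grads)
}

# One encoder layer backward.
encoder_layer_bwd <- function(dOut, cache, tok_valid, lp, config) {
  ln2 <- layer_norm_bwd(dOut, cache$ln2, lp$g2)
  dZ2 <- ln2$dZ                               # gradient of X1 + F
  dF <- dZ2
  dHd <- dF %*% t(lp$W2)
  dW2 <- t(cache$Hd) %*% dF
  df2 <- colSums(dF)
  dH <- apply_drop(dHd, cache$ff_mask)
  dHpre <- dH * act_grad(cache$Hpre, config$activation)
  dW1 <- t(cache$X1) %*% dHpre
  df1 <- colSums(dHpre)
  dX1 <- dZ2 + dHpre %*% t(lp$W1)
  ln1 <- layer_norm_bwd(dX1, cache$ln1, lp$g1)
  dZ1 <- ln1$dZ                               # gradient of X + A
  at <- mhsa_bwd(dZ1, cache$attn, tok_valid, lp, config)
  dX <- dZ1 + at$dX
  grads <- c(at$grads,
             list(g1 = ln1$dg, c1 = ln1$db,
                  W1 = dW1, f1 = df1, W2 = dW2, f2 = df2,
                  g2 = ln2$dg, c2 = ln2$db))
  list(dX = dX, grads = grads[names(lp)])
}

# Full backward for one window given d(loss)/d(logit); returns a gradient
# tree shaped like params.
backward_window <- function(dlogit, fw, params, config) {
  cache <- fw$cache
  g <- cache$g
  dWc <- g * dlogit
  dbc <- dlogit
  dg <- params$Wc * dlogit
  if (!is.null(cache$fc_mask)) dg <- dg * cache$fc_mask
  d <- config$d_model
  ch_grads <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    cc <- cache$channels[[ch]]
    cp <- params$channels[[ch]]
    dpool <- dg[((ch - 1L) * d + 1L):(ch * d)]
    nv <- sum(cc$patch_valid)
    dX <- matrix(0, config$n_patches, d)
    dX[cc$patch_valid, ] <- matrix(dpool / nv, nv, d, byrow = TRUE)
    lgrads <- vector("list", config$n_layers)
    for (l in rev(seq_len(config$n_layers))) {
      bl <- encoder_layer_bwd(dX, cc$layers[[l]], cc$patch_valid,
                              cp$layers[[l]], config)
      dX <- bl$dX
      lgrads[[l]] <- bl$grads
    }
    dTok <- apply_drop(dX, cc$emb_mask)
    ch_grads[[ch]] <- list(W_P = t(cc$patches) %*% dTok,
                           W_pos = dTok,
                           layers = lgrads)
  }
  list(channels = ch_grads, Wc = dWc, bc = dbc)
}

# Mean BCE loss and gradient over a batch of windows (list of row indices
# into a windows tibble). Returns loss and the averaged gradient tree.
batch_grad <- function(windows, rows, params, config) {
  grads <- NULL
  loss <- 0
  for (i in rows) {
    fw <- forward_window(windows$values[[i]], windows$valid[[i]], params,
                         config, training = TRUE, keep_cache = TRUE)
    y <- windows$label[i]
    p <- min(max(fw$probability, PROB_EPS), 1 - PROB_EPS)
    loss <- loss + bce_loss(y, fw$probability)
    dlogit <- p - y                       # d BCE / d logit through sigmoid
    gi <- backward_window(dlogit, fw, params, config)
    grads <- if (is.null(grads)) gi else tree_map(`+`, grads, gi)
  }
  n <- length(rows)
  list(loss = loss / n, grads = tree_map(function(x) x / n, grads))
}
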