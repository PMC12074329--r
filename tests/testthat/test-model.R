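# Transformer components against hand arithmetic and brute-force oracles.

test_that("instance normalisation matches hand arithmetic and its contract", {
  r <- instance_normalize(c(1, 2, 3, 4))
  expect_equal(r$mu, 2.5)
  expect_equal(r$sigma, sqrt(1.25), tolerance = 1e-12)
  expect_equal(r$values, c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)

  # constant signal collapses to zeros through the epsilon guard
  expect_equal(instance_normalize(rep(7, 10))$values, rep(0, 10))

  # idempotence on an already standardised input (population SD)
  x <- c(-1.5, -0.5, 0.5, 1.5) / sqrt(1.25)
  expect_equal(instance_normalize(x)$values, x, tolerance = 1e-6)

  # masked positions are excluded from the stats and zeroed in the output
  x <- c(1, 2, 3, 4, 100, -50)
  v <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  r <- instance_normalize(x, v)
  expect_equal(r$mu, 2.5)
  expect_equal(r$values[5:6], c(0, 0))

  expect_error(instance_normalize(c(1, 2), c(FALSE, FALSE)),
               class = "ctg_degenerate_channel")
})

test_that("patching follows the patch-count law and index layout", {
  p <- make_patches(1:10, patch_len = 4, stride = 2)
  expect_equal(p$n_patches, 4L)
  expect_equal(p$patches[1, ], 1:4)
  expect_equal(p$patches[2, ], 3:6)
  expect_equal(p$patches[4, ], 7:10)

  # whole-series patch at the boundary
  p1 <- make_patches(1:8, patch_len = 8, stride = 8)
  expect_equal(p1$n_patches, 1L)
  expect_equal(p1$patches[1, ], 1:8)

  # the operating configuration: 960 steps, P = S = 16 -> 60 patches
  expect_equal(patch_count(960, 16, 16), 60L)
  expect_error(make_patches(1:5, patch_len = 6, stride = 1),
               class = "ctg_config_error")

  # patch validity: below half observed -> invalid
  v <- rep(TRUE, 10); v[1:3] <- FALSE
  pv <- make_patches(1:10, v, patch_len = 4, stride = 2)$patch_valid
  expect_equal(pv, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("patch-count law equals explicit enumeration over random triples", {
  set.seed(99)
  for (i in 1:250) {
    L <- sample(8:2000, 1)
    P <- sample(seq_len(L), 1)
    S <- sample(1:64, 1)
    expect_identical(patch_count(L, P, S), oracle_patch_count(L, P, S))
  }
})

test_that("patch embedding is the linear map plus positional rows", {
  # zero weights annihilate; positional additivity; hand product
  patches <- rbind(c(1, 2), c(1, 2), c(3, 4))
  W_P <- matrix(c(1, 0, 2, 1), 2, 2)     # columns (1,0) and (2,1)
  W_pos <- matrix(0, 3, 2)
  z <- embed_patches(patches, W_P, W_pos)
  expect_equal(z[1, ], c(1 * 1 + 2 * 0, 1 * 2 + 2 * 1))
  expect_equal(z[1, ], z[2, ])

  W_pos2 <- matrix(c(10, 20, 30, 40, 50, 60), 3, 2)
  z2 <- embed_patches(patches, W_P, W_pos2)
  expect_equal(z2 - z, W_pos2)

  expect_equal(embed_patches(patches, matrix(0, 2, 2), matrix(0, 3, 2)),
               matrix(0, 3, 2))
  expect_error(embed_patches(patches, matrix(0, 3, 2), W_pos),
               class = "ctg_config_error")
})

test_that("scaled dot-product attention matches scalar hand computation", {
  # single valid token: softmax of one = 1 -> output is its value row
  r1 <- scaled_dot_attention(matrix(1), matrix(1), matrix(5))
  expect_equal(r1$context[1, 1], 5)

  # identical keys -> uniform weights -> mean of values
  Q <- matrix(rnorm(3), 3, 1); K <- matrix(1, 3, 1); V <- matrix(c(1, 2, 6))
  r2 <- scaled_dot_attention(Q, K, V)
  expect_equal(as.numeric(r2$context), rep(3, 3))

  # 2-token toy with d_k = 1: weights (0.731, 0.269), context 0.731
  r3 <- scaled_dot_attention(matrix(c(1, 0)), matrix(c(1, 0)), matrix(c(1, 0)))
  expect_equal(r3$weights[1, ], c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-4)
  expect_equal(r3$context[1, 1], 0.7310586, tolerance = 1e-6)

  # masked keys get exactly zero weight; invalid queries return zero context
  r4 <- scaled_dot_attention(Q, K, V, key_valid = c(TRUE, TRUE, FALSE),
                             query_valid = c(TRUE, TRUE, FALSE))
  expect_equal(r4$weights[1, 3], 0)
  expect_equal(r4$context[3, 1], 0)
  expect_error(
    scaled_dot_attention(Q, K, V, key_valid = rep(FALSE, 3)),
    class = "ctg_masked_attention")
})

test_that("attention rows sum to one over valid keys in a full forward pass", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 2)
  w <- random_window(48, missing = 0.3, seed = 8)
  fw <- ctgpatch:::forward_window(w$values, w$valid, m$params, cfg,
                                  keep_cache = TRUE)
  for (ch in 1:2) {
    pv <- fw$cache$channels[[ch]]$patch_valid
    for (l in 1:cfg$n_layers) {
      for (hd in fw$cache$channels[[ch]]$layers[[l]]$attn$heads) {
        expect_equal(rowSums(hd$W[pv, , drop = FALSE]),
                     rep(1, sum(pv)), tolerance = 1e-12)
        expect_true(all(hd$W[, !pv] == 0))
      }
    }
  }
})

test_that("encoder layer with zero weights is double layer-normalisation", {
  cfg <- model_config(n_layers = 1, n_heads = 1, d_model = 4, d_ff = 4,
                      dropout = 0, fc_dropout = 0, attn_dropout = 0,
                      patch_len = 4, stride = 4, seq_len = 8)
  m <- init_model(cfg, seed = 1)
  lp <- ctgpatch:::tree_map(function(x) x * 0, m$params$channels[[1]]$layers[[1]])
  lp$g1 <- rep(1, 4); lp$g2 <- rep(1, 4)       # identity LN scale
  X <- matrix(rnorm(8), 2, 4)
  out <- encoder_layer(X, NULL, lp, cfg)
  ln <- function(M) t(apply(M, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-8)
  }))
  expect_equal(out, ln(ln(X)), tolerance = 1e-10)
})

test_that("pooling, aggregation and the head match hand arithmetic", {
  expect_equal(pool_tokens(rbind(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(pool_tokens(rbind(c(5, 5), c(9, 9)), c(TRUE, FALSE)), c(5, 5))
  expect_equal(pool_tokens(rbind(c(3, 3), c(3, 3))), c(3, 3))
  expect_error(pool_tokens(rbind(c(1, 1)), FALSE),
               class = "ctg_degenerate_window")

  expect_equal(aggregate_channels(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_equal(aggregate_channels(c(0, 0), c(0, 0)), rep(0, 4))
  expect_false(identical(aggregate_channels(c(1, 2), c(3, 4)),
                         aggregate_channels(c(3, 4), c(1, 2))))
  expect_error(aggregate_channels(c(1, 2), NULL), class = "ctg_config_error")

  expect_equal(classify(c(0, 0), c(0, 0), 0)$probability, 0.5)
  expect_equal(classify(1, 2, -1)$probability, 0.7310586, tolerance = 1e-6)
  expect_equal(classify(1, 1000, 0)$probability, 1)
})

test_that("binary cross-entropy matches hand values and its symmetry", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  p <- runif(20)
  expect_equal(bce_loss(rep(0, 20), p), bce_loss(rep(1, 20), 1 - p),
               tolerance = 1e-12)
  expect_error(bce_loss(2, 0.5), class = "ctg_label_error")
})

test_that("forward pass equals an independent straight-line composition", {
  # 1 layer, 1 head, d = 4, P = S = 4, L = 8: everything written out in
  # plain base R with no package internals.
  cfg <- model_config(n_layers = 1, n_heads = 1, d_model = 4, d_ff = 6,
                      dropout = 0, fc_dropout = 0, attn_dropout = 0,
                      patch_len = 4, stride = 4, seq_len = 8)
  m <- init_model(cfg, seed = 42)
  set.seed(7)
  vals <- rbind(fhr = runif(8), toco = runif(8))
  valid <- rbind(fhr = rep(TRUE, 8), toco = rep(TRUE, 8))

  ln <- function(M, g, b) t(apply(M, 1, function(r) {
    ((r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-8)) * g + b
  }))
  pooled <- list()
  for (ch in 1:2) {
    x <- vals[ch, ]
    mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
    xn <- (x - mu) / (sg + 1e-8)
    P <- rbind(xn[1:4], xn[5:8])
    cp <- m$params$channels[[ch]]
    X <- P %*% cp$W_P + cp$W_pos
    lp <- cp$layers[[1]]
    Q <- sweep(X %*% lp$Wq, 2, lp$bq, `+`)
    K <- sweep(X %*% lp$Wk, 2, lp$bk, `+`)
    V <- sweep(X %*% lp$Wv, 2, lp$bv, `+`)
    S <- Q %*% t(K) / 2                        # sqrt(d_k) = 2
    W <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    O <- sweep((W %*% V) %*% lp$Wo, 2, lp$bo, `+`)
    X1 <- ln(X + O, lp$g1, lp$c1)
    H <- pmax(sweep(X1 %*% lp$W1, 2, lp$f1, `+`), 0)
    FF <- sweep(H %*% lp$W2, 2, lp$f2, `+`)
    X2 <- ln(X1 + FF, lp$g2, lp$c2)
    pooled[[ch]] <- colMeans(X2)
  }
  g <- c(pooled[[1]], pooled[[2]])
  p_hand <- 1 / (1 + exp(-(sum(m$params$Wc * g) + m$params$bc)))

  p_pkg <- forward(list(values = vals, valid = valid), m)$probability
  expect_equal(p_pkg, p_hand, tolerance = 1e-5)
})

test_that("model output depends on observed samples only (mask invariance)", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 11)
  w <- random_window(48, missing = 0.35, seed = 3)
  p0 <- forward(w, m)$probability
  set.seed(10)
  for (i in 1:20) {
    w2 <- w
    for (ch in 1:2) {
      hidden <- !w$valid[ch, ]
      w2$values[ch, hidden] <- runif(sum(hidden), -5, 5)
    }
    expect_identical(forward(w2, m)$probability, p0)
  }
})

test_that("channels are processed independently up to aggregation", {
  cfg <- tiny_config()
  m <- init_model(cfg, seed = 4)
  w <- random_window(48, missing = 0.1, seed = 5)
  fw1 <- ctgpatch:::forward_window(w$values, w$valid, m$params, cfg,
                                   keep_cache = TRUE)
  w$values["toco", ] <- rev(w$values["toco", ])
  fw2 <- ctgpatch:::forward_window(w$values, w$valid, m$params, cfg,
                                   keep_cache = TRUE)
  expect_identical(fw1$cache$pooled[[1]], fw2$cache$pooled[[1]])
  expect_false(identical(fw1$cache$pooled[[2]], fw2$cache$pooled[[2]]))
})

test_that("evaluation-mode forward is bitwise deterministic", {
  cfg <- model_config(n_layers = 2, n_heads = 2, d_model = 8, d_ff = 12,
                      dropout = 0.3, fc_dropout = 0.4, attn_dropout = 0.2,
                      patch_len = 8, stride = 8, seq_len = 48)
  m <- init_model(cfg, seed = 6)
  w <- random_window(48, seed = 12)
  expect_identical(forward(w, m)$probability, forward(w, m)$probability)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- model_config(n_layers = 2, n_heads = 2, d_model = 8, d_ff = 12,
                      dropout = 0, fc_dropout = 0, attn_dropout = 0,
                      patch_len = 4, stride = 4, seq_len = 24)
  m <- init_model(cfg, seed = 3)
  w <- random_window(24, missing = 0.2, seed = 1)
  y <- 1
  fw <- ctgpatch:::forward_window(w$values, w$valid, m$params, cfg,
                                  training = TRUE, keep_cache = TRUE)
  gr <- ctgpatch:::backward_window(fw$probability - y, fw, m$params, cfg)

  loss_of <- function(params) {
    f <- ctgpatch:::forward_window(w$values, w$valid, params, cfg)
    bce_loss(y, f$probability)
  }
  eps <- 1e-6
  set.seed(44)
  check_leaf <- function(getter, setter) {
    leaf <- getter(m$params)
    j <- sample(length(leaf), 1)
    up <- leaf; up[j] <- up[j] + eps
    dn <- leaf; dn[j] <- dn[j] - eps
    num <- (loss_of(setter(m$params, up)) - loss_of(setter(m$params, dn))) /
      (2 * eps)
    expect_equal(getter(gr)[j], num, tolerance = 1e-4)
  }
  check_leaf(function(p) p$Wc, function(p, v) { p$Wc <- v; p })
  check_leaf(function(p) p$channels[[1]]$W_P,
             function(p, v) { p$channels[[1]]$W_P <- v; p })
  check_leaf(function(p) p$channels[[2]]$W_pos,
             function(p, v) { p$channels[[2]]$W_pos <- v; p })
  for (fld in c("Wq", "Wo", "W1", "W2", "g1", "c2", "bv", "f1")) {
    check_leaf(function(p) p$channels[[1]]$layers[[2]][[fld]],
               function(p, v) { p$channels[[1]]$layers[[2]][[fld]] <- v; p })
  }
})

test_that("model configuration invariants are enforced", {
  expect_error(model_config(d_model = 10, n_heads = 4),
               class = "ctg_config_error")
  expect_error(model_config(patch_len = 2000), class = "ctg_config_error")
  expect_error(model_config(dropout = 1), class = "ctg_parameter_error")
  cfg <- model_config()
  expect_equal(cfg$n_patches, 60L)
})
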