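# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately written in plain base R, independent of the
# package's own computation paths.

# Tiny transformer configuration used wherever the architecture itself is
# under test (speed, not capacity, matters there).
tiny_config <- function(L = 48L, ...) {
  model_config(n_layers = 2L, n_heads = 2L, d_model = 8L, d_ff = 12L,
               dropout = 0, fc_dropout = 0, attn_dropout = 0,
               patch_len = 8L, stride = 8L, seq_len = L, ...)
}

# A random unit-scale window with burst missingness.
random_window <- function(L = 48L, missing = 0.2, seed = 1L) {
  set.seed(seed)
  vals <- rbind(fhr = runif(L), toco = runif(L))
  valid <- rbind(fhr = runif(L) > missing, toco = runif(L) > missing)
  # guarantee at least a few observed samples per channel
  valid[, 1:4] <- TRUE
  list(values = vals, valid = valid)
}

# A windows tibble with a planted linear class signal, cheap to learn from.
toy_windows <- function(n_per_class = 20L, L = 48L, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(2 * n_per_class), function(i) {
    lab <- as.integer(i > n_per_class)
    base <- runif(1, 0.4, 0.6)
    x <- base + 0.05 * rnorm(L)
    if (lab == 1L) x <- x + 0.25 * sin(seq_len(L) / 2)  # shape signal
    tibble::tibble(
      window_id = paste0("w", i), trace_id = paste0("t", i),
      window_index = 0L, label = lab,
      days_to_delivery = sample(1:7, 1),
      values = list(rbind(fhr = pmin(pmax(x, 0), 1),
                          toco = runif(L))),
      valid = list(rbind(fhr = rep(TRUE, L), toco = rep(TRUE, L))))
  })
  dplyr::bind_rows(rows)
}

# Independent AUC oracle: tie-corrected pairwise comparison probability.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Independent Youden oracle: exhaustive scan over distinct-score thresholds
# with direct counting; ties broken toward the higher threshold.
oracle_youden <- function(scores, labels) {
  ths <- sort(unique(scores))
  j <- vapply(ths, function(t) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, 0)
  best <- max(j)
  list(threshold = max(ths[j == best]), j = best)
}

# Independent patch-count oracle: explicit enumeration of window starts.
oracle_patch_count <- function(L, P, S) {
  n <- 0L; start <- 0L
  while (start + P <= L) { n <- n + 1L; start <- start + S }
  n
}

pred_set <- function(scores, labels, days = NULL) {
  out <- tibble::tibble(score = scores, label = labels)
  if (!is.null(days)) out$days_to_delivery <- days
  out
}
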