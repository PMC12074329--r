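# Training loop, early stopping, pretrain/finetune and the search harness.

test_that("early stopping scans an AUC stream exactly as specified", {
  # improves at epochs 1 and 2, then 10 non-improving epochs -> stop at 12
  stream <- c(0.60, 0.61, rep(0.61, 10))
  r <- early_stop_scan(stream, patience = 10)
  expect_equal(r$stop_epoch, 12L)
  expect_equal(r$best_epoch, 2L)
  expect_equal(r$best_auc, 0.61)
  expect_true(r$stopped_early)

  # ties do not reset patience; strict improvement does
  r2 <- early_stop_scan(c(0.5, 0.5, 0.6, 0.55, 0.55), patience = 3)
  expect_equal(r2$best_epoch, 3L)
  expect_false(r2$stopped_early)

  # monotone stream never stops early
  r3 <- early_stop_scan(seq(0.5, 0.9, by = 0.1), patience = 2)
  expect_equal(r3$best_epoch, 5L)
  expect_false(r3$stopped_early)
})

test_that("training is deterministic, budget-capped and keeps the best epoch", {
  w <- toy_windows(12, L = 48, seed = 2)
  sp <- split_cohort(w$window_id, 0.75, stratify_by = w$label, seed = 1)
  trw <- w[w$window_id %in% sp$train, ]
  evw <- w[w$window_id %in% sp$eval, ]
  cfg <- tiny_config()
  tc <- train_config(max_epochs = 2, patience = 2, batch_size = 8,
                     learning_rate = 1e-3, seed = 5)

  f1 <- train_model(init_model(cfg, seed = 9), trw, evw, tc)
  f2 <- train_model(init_model(cfg, seed = 9), trw, evw, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  # max_epochs = 1 runs exactly one epoch regardless of patience
  t1 <- train_config(max_epochs = 1, patience = 10, batch_size = 8,
                     learning_rate = 1e-3, seed = 5)
  f3 <- train_model(init_model(cfg, seed = 9), trw, evw, t1)
  expect_equal(nrow(f3$history), 1L)

  # the checkpoint comes from the best epoch, never later
  expect_equal(f1$best_auc, max(f1$history$val_auc))
  expect_equal(f1$best_epoch, which.max(f1$history$val_auc))

  # a zero-epoch budget is the identity
  m0 <- init_model(cfg, seed = 9)
  f0 <- train_model(m0, trw, evw, train_config(max_epochs = 0, seed = 5))
  expect_identical(f0$params, m0$params)

  # single-class validation set is refused
  expect_error(
    train_model(init_model(cfg, seed = 9), trw, evw[evw$label == 1, ], tc),
    class = "ctg_auc_undefined")
})

test_that("loss decreases over early epochs on separable data", {
  w <- toy_windows(16, L = 48, seed = 7)
  sp <- split_cohort(w$window_id, 0.75, stratify_by = w$label, seed = 2)
  deltas <- vapply(1:3, function(s) {
    f <- train_model(init_model(tiny_config(), seed = s),
                     w[w$window_id %in% sp$train, ],
                     w[w$window_id %in% sp$eval, ],
                     train_config(max_epochs = 4, patience = 4,
                                  batch_size = 8, learning_rate = 1e-3,
                                  seed = s))
    f$history$train_loss[1] - min(f$history$train_loss)
  }, 0)
  expect_gt(median(deltas), 0)
})

# Two-stratum cohort with a stronger class signal near delivery.
two_stratum_windows <- function(seed) {
  strong <- simulate_cohort(24, 24, sim_params(adverse_effect = 0.3,
                                               sample_count = 96),
                            days_range = c(1, 2), seed = seed)
  weak <- simulate_cohort(24, 24, sim_params(adverse_effect = 0.85,
                                             sample_count = 96),
                          days_range = c(3, 7), seed = seed + 1000)
  weak$metadata$trace_id <- paste0("far", weak$metadata$trace_id)
  for (i in seq_along(weak$traces)) {
    weak$traces[[i]]$trace_id <- paste0("far", weak$traces[[i]]$trace_id)
  }
  prepare_windows(c(strong$traces, weak$traces),
                  window_len = 96, min_observed = 48)
}

test_that("pretrain/finetune adapts to the near-delivery stratum", {
  cfg <- tiny_config(L = 96L)
  tc <- function(seed, epochs = 3) {
    train_config(max_epochs = epochs, patience = max(1, epochs),
                 batch_size = 16, learning_rate = 1e-3, seed = seed)
  }
  gains <- vapply(1:5, function(s) {
    w <- two_stratum_windows(seed = 30 + s)
    # finetuned
    out <- pretrain_finetune(init_model(cfg, seed = s), w,
                             pretrain_config = tc(s), finetune_config = tc(s),
                             split_seed = s)
    # pretrained only (identity finetune), same eval windows
    out0 <- pretrain_finetune(init_model(cfg, seed = s), w,
                              pretrain_config = tc(s),
                              finetune_config = tc(s, epochs = 0),
                              split_seed = s)
    stopifnot(identical(out$eval_windows$window_id,
                        out0$eval_windows$window_id))
    ft <- auc(roc_curve(predict(out$model, out$eval_windows)))
    pre <- auc(roc_curve(predict(out0$model, out0$eval_windows)))
    if (s == 1L) {
      # phase bookkeeping: eval cases all lie in the finetune day range and
      # the phase-2 eval ids never appear in the phase-2 training subset
      expect_true(all(out$eval_windows$days_to_delivery[
        out$eval_windows$label == 1] <= 2))
      p2 <- select_by_days_to_delivery(w, c(0, 2), filter_controls = TRUE)
      expect_true(all(out$eval_windows$window_id %in% p2$window_id))
      expect_s3_class(out$pretrain_history, "tbl_df")
      expect_gt(nrow(out$pretrain_history), 0L)
      # identity finetune evaluates exactly like the pretrained checkpoint
      expect_equal(out0$model$best_auc, pre, tolerance = 1e-12)
    }
    ft - pre
  }, 0)
  # finetuning on the stronger near-delivery signal helps on median
  expect_gte(median(gains), 0)
})

test_that("random search finds a near-optimal config of a rigged objective", {
  # deterministic objective with a known maximiser structure over the grid
  rigged <- function(config, trial_seed) {
    0.5 + 0.1 * (config$n_layers == 4) + 0.2 * (config$patch_len == 8) +
      0.15 * (config$activation == "gelu") - 0.05 * (config$n_heads == 32)
  }
  sr <- hpo_search(hpo_space(), n_trials = 60, objective = rigged, seed = 8)
  expect_equal(nrow(sr$trials), 60L)
  expect_equal(sr$best_auc, max(sr$trials$auc))

  # brute-force the attainable maximum and require the top decile
  space <- hpo_space()
  vals <- c()
  for (nl in space$n_layers) for (pl in space$patch_len)
    for (ac in space$activation) for (nh in space$n_heads) {
      vals <- c(vals, rigged(list(n_layers = nl, patch_len = pl,
                                  activation = ac, n_heads = nh), 0))
    }
  expect_gte(sr$best_auc, quantile(vals, 0.9))

  # every sampled trial satisfies the architectural constraints
  expect_true(all(sr$trials$d_model %% sr$trials$n_heads == 0))

  # a single trial returns its own config
  s1 <- hpo_search(hpo_space(), n_trials = 1, objective = rigged, seed = 2)
  expect_equal(s1$best_trial, 1L)
  expect_identical(glance(s1)$n_trials, 1L)
})

test_that("the default search objective trains models end to end", {
  w <- toy_windows(8, L = 48, seed = 5)
  sp <- split_cohort(w$window_id, 0.75, stratify_by = w$label, seed = 1)
  space <- hpo_space(n_layers = 1L, n_heads = 2L, d_model = 8L, d_ff = 12L,
                     patch_len = 8L, stride = 8L,
                     learning_rate = 1e-3, batch_size = 8L)
  sr <- hpo_search(space, n_trials = 2, seed = 3,
                   train_windows = w[w$window_id %in% sp$train, ],
                   val_windows = w[w$window_id %in% sp$eval, ],
                   trial_epochs = 2, trial_patience = 2, seq_len = 48L)
  expect_equal(nrow(sr$trials), 2L)
  expect_true(all(sr$trials$auc >= 0 & sr$trials$auc <= 1))
})
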