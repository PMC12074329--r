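# Optimisation loop with AUC-based early stopping and the temporal
# pretrain/finetune protocol.

#' Training configuration
#'
#' @param max_epochs Epoch budget (50 for a main run, 60 per search trial);
#'   0 performs no updates (identity training).
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping; improvement means a strictly higher validation AUC.
#' @param batch_size Windows per gradient step.
#' @param learning_rate Adam step size.
#' @param seed Seed controlling initialisation order, shuffling and dropout.
#' @return A `ctg_train_config` list.
#' @export
train_config <- function(max_epochs = 50L, patience = 10L, batch_size = 48L,
                         learning_rate = 1e-4, seed = 1L) {
  check_number(max_epochs, "max_epochs", 0, Inf, integer = TRUE)
  check_number(patience, "patience", 1, Inf, integer = TRUE)
  if (patience > max_epochs) patience <- max_epochs
  check_number(batch_size, "batch_size", 1, Inf, integer = TRUE)
  check_number(learning_rate, "learning_rate", 0, Inf, closed_upper = FALSE)
  if (learning_rate <= 0) {
    abort("`learning_rate` must be positive.", class = "ctg_parameter_error")
  }
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ctg_train_config")
}

#' Early-stopping bookkeeping over a validation-AUC stream
#'
#' Scans the per-epoch AUC values in order: an epoch improves iff its AUC is
#' strictly greater than the best seen so far (ties do not reset patience).
#' Training stops after the first epoch at which `patience` consecutive
#' epochs have failed to improve, or at the end of the stream.
#'
#' @param aucs Numeric vector of per-epoch validation AUCs.
#' @param patience Non-improving epochs tolerated.
#' @return List: `best_epoch`, `best_auc`, `stop_epoch` (number of epochs
#'   actually run), `stopped_early`.
#' @export
#' @examples
#' early_stop_scan(c(0.60, 0.61, rep(0.61, 10)), patience = 10)
early_stop_scan <- function(aucs, patience) {
  best <- -Inf; best_epoch <- 0L; bad <- 0L
  for (e in seq_along(aucs)) {
    if (aucs[e] > best) {
      best <- aucs[e]; best_epoch <- e; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        return(list(best_epoch = best_epoch, best_auc = best,
                    stop_epoch = e, stopped_early = TRUE))
      }
    }
  }
  list(best_epoch = best_epoch, best_auc = best,
       stop_epoch = length(aucs), stopped_early = FALSE)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

val_auc_of <- function(model, windows) {
  preds <- predict.ctg_model(model, windows)
  auc(roc_curve(preds))
}

#' Train the patch transformer
#'
#' Minimises mean binary cross-entropy with Adam. After every epoch the
#' validation AUC is computed; training stops when it has not strictly
#' improved for `patience` consecutive epochs or at `max_epochs`. The
#' returned model carries the parameters of the best-AUC epoch, never a
#' later one. Fully deterministic given the seeds (single-threaded).
#'
#' @param model A `ctg_model` (fresh from [init_model()] or a checkpoint to
#'   finetune from; all parameters are updated either way).
#' @param train_windows,val_windows Windows tibbles from [prepare_windows()]
#'   with a `label` column; the validation set must contain both classes.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return The model with elements `history` (tibble: epoch, train_loss,
#'   val_auc), `best_epoch`, `best_auc` added, class `ctg_model`.
#' @export
train_model <- function(model, train_windows, val_windows,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "ctg_model"), inherits(config, "ctg_train_config"))
  if (nrow(train_windows) == 0L || nrow(val_windows) == 0L) {
    abort("Empty training or validation set.", class = "ctg_train_error")
  }
  if (length(unique(val_windows$label)) < 2L) {
    abort("Validation set must contain both classes (AUC undefined).",
          class = "ctg_auc_undefined")
  }
  if (config$max_epochs == 0L) {
    model$history <- tibble::tibble(epoch = integer(), train_loss = double(),
                                    val_auc = double())
    model$best_epoch <- 0L
    model$best_auc <- val_auc_of(model, val_windows)
    return(model)
  }
  n <- nrow(train_windows)
  params <- model$params
  opt <- adam_init(params)
  best_params <- params
  best <- -Inf; best_epoch <- 0L; bad <- 0L
  hist <- vector("list", config$max_epochs)
  local_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, n)]
        bg <- batch_grad(train_windows, rows, params, model$config)
        losses <- c(losses, bg$loss)
        up <- adam_step(params, bg$grads, opt, config$learning_rate)
        params <- up$params; opt <- up$state
      }
      model$params <- params
      va <- val_auc_of(model, val_windows)
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_loss = mean(losses),
                                      val_auc = va)
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f  val AUC %.4f\n",
                    epoch, mean(losses), va))
      }
      if (va > best) {
        best <- va; best_epoch <- epoch; bad <- 0L
        best_params <- params
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best_epoch
  model$best_auc <- best
  model
}

#' Temporal pretrain/finetune protocol
#'
#' Phase 1 trains from scratch on windows whose adverse cases were recorded
#' in the `pretrain_days` range before delivery; phase 2 initialises from the
#' phase-1 best checkpoint and continues (all parameters updated) on the
#' `finetune_days` subset with its own early stopping.
#'
#' @param model A fresh `ctg_model`.
#' @param windows Windows tibble with `label` and `days_to_delivery`.
#' @param pretrain_days,finetune_days Inclusive day ranges, e.g. `c(3, 7)`
#'   and `c(0, 2)`.
#' @param pretrain_config,finetune_config [train_config()]s per phase.
#' @param val_fraction Fraction of each subset held out for validation.
#' @param split_seed Seed for the within-phase splits.
#' @return List: `model` (finetuned), `pretrain_history`,
#'   `finetune_history`, `eval_windows` (the held-out finetune-phase split).
#' @export
pretrain_finetune <- function(model, windows,
                              pretrain_days = c(3, 7),
                              finetune_days = c(0, 2),
                              pretrain_config = train_config(),
                              finetune_config = train_config(),
                              val_fraction = 0.2, split_seed = 1L) {
  phase_sets <- function(days, seed) {
    sub <- select_by_days_to_delivery(windows, days, filter_controls = TRUE)
    if (nrow(sub) == 0L) {
      abort("Empty temporal subset.", class = "ctg_subset_error")
    }
    sp <- split_cohort(sub$window_id, 1 - val_fraction,
                       stratify_by = sub$label, seed = seed)
    list(train = sub[sub$window_id %in% sp$train, ],
         eval = sub[sub$window_id %in% sp$eval, ])
  }
  p1 <- phase_sets(pretrain_days, split_seed)
  m1 <- train_model(model, p1$train, p1$eval, pretrain_config)
  p2 <- phase_sets(finetune_days, split_seed + 1L)
  m2 <- train_model(m1, p2$train, p2$eval, finetune_config)
  list(model = m2, pretrain_history = m1$history,
       finetune_history = m2$history, eval_windows = p2$eval)
}
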