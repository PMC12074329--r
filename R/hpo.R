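# Hyperparameter search harness with a pluggable sampler.

#' Hyperparameter search space
#'
#' The default grids span encoder depth 3-6; heads \{4, 8, 16, 32\}; model
#' width \{64, ..., 640\}; feed-forward width \{128, ..., 640\}; dropout rates
#' in \[0.1, 0.5\]; learning rates \{1e-6, ..., 1e-3\}; batch sizes
#' \{16, 32, 48, 64\}; patch lengths \{4, 8, 16, 32\}; strides \{4, 8, 16\};
#' and the three feed-forward activations.
#'
#' @param ... Named overrides of any grid (each a vector; the dropout entries
#'   are length-2 continuous ranges).
#' @return A `ctg_hpo_space` list of grids.
#' @export
hpo_space <- function(...) {
  space <- list(
    n_layers = 3:6,
    n_heads = c(4L, 8L, 16L, 32L),
    d_model = c(64L, 128L, 192L, 256L, 384L, 512L, 640L),
    d_ff = c(128L, 192L, 256L, 320L, 384L, 512L, 640L),
    dropout = c(0.1, 0.5),
    fc_dropout = c(0.1, 0.5),
    attn_dropout = c(0.1, 0.5),
    learning_rate = c(1e-6, 5e-6, 1e-5, 5e-5, 1e-4, 5e-4, 1e-3),
    batch_size = c(16L, 32L, 48L, 64L),
    patch_len = c(4L, 8L, 16L, 32L),
    stride = c(4L, 8L, 16L),
    activation = c("relu", "gelu", "elu"))
  over <- list(...)
  space[names(over)] <- over
  structure(space, class = "ctg_hpo_space")
}

# Draw one candidate; continuous for the dropout ranges, uniform over grids
# otherwise. Invalid combinations (width not divisible by heads, patch longer
# than the window) are resampled, never trained.
sample_hpo_config <- function(space, seq_len = 960L, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    cand <- list(
      n_layers = sample(space$n_layers, 1),
      n_heads = sample(space$n_heads, 1),
      d_model = sample(space$d_model, 1),
      d_ff = sample(space$d_ff, 1),
      dropout = runif(1, space$dropout[1], space$dropout[2]),
      fc_dropout = runif(1, space$fc_dropout[1], space$fc_dropout[2]),
      attn_dropout = runif(1, space$attn_dropout[1], space$attn_dropout[2]),
      learning_rate = sample(space$learning_rate, 1),
      batch_size = sample(space$batch_size, 1),
      patch_len = sample(space$patch_len, 1),
      stride = sample(space$stride, 1),
      activation = sample(space$activation, 1))
    if (cand$d_model %% cand$n_heads == 0L && cand$patch_len <= seq_len) {
      return(cand)
    }
  }
  abort("Could not sample a valid configuration.", class = "ctg_search_error")
}

#' Hyperparameter search
#'
#' Runs `n_trials` trials: each samples a candidate from the space (invalid
#' combinations are resampled before any training), evaluates it with
#' `objective`, and records the score. The sampler is pluggable: the built-in
#' `"random"` sampler draws uniformly; pass a function
#' `function(space, seq_len) -> config` to plug in an external optimiser
#' (e.g. a Bayesian sampler) behind the same interface.
#'
#' @param space A [hpo_space()].
#' @param n_trials Number of trials (the reference protocol uses 100).
#' @param objective `function(config, trial_seed) -> validation AUC`. The
#'   default trains on the supplied windows with a 60-epoch budget and
#'   patience 10 and returns the best validation AUC.
#' @param sampler `"random"` or a sampling function.
#' @param seed Integer seed for the whole search.
#' @param train_windows,val_windows Needed only by the default objective.
#' @param trial_epochs,trial_patience Per-trial training budget for the
#'   default objective.
#' @param seq_len Window length used for validity checks.
#' @return A `ctg_hpo` list: `best_config`, `best_auc`, `best_trial`, and
#'   `trials` (tibble with one row per trial: trial, auc and the sampled
#'   hyperparameters).
#' @export
hpo_search <- function(space = hpo_space(), n_trials = 10L,
                       objective = NULL, sampler = "random", seed = 1L,
                       train_windows = NULL, val_windows = NULL,
                       trial_epochs = 60L, trial_patience = 10L,
                       seq_len = 960L) {
  check_number(n_trials, "n_trials", 1, Inf, integer = TRUE)
  draw <- if (is.function(sampler)) {
    sampler
  } else if (identical(sampler, "random")) {
    function(space, seq_len) sample_hpo_config(space, seq_len)
  } else {
    abort("Unknown sampler.", class = "ctg_search_error")
  }
  if (is.null(objective)) {
    if (is.null(train_windows) || is.null(val_windows)) {
      abort("The default objective needs train_windows and val_windows.",
            class = "ctg_search_error")
    }
    objective <- function(config, trial_seed) {
      mc <- model_config(
        n_layers = config$n_layers, n_heads = config$n_heads,
        d_model = config$d_model, d_ff = config$d_ff,
        dropout = config$dropout, fc_dropout = config$fc_dropout,
        attn_dropout = config$attn_dropout, patch_len = config$patch_len,
        stride = config$stride, activation = config$activation,
        seq_len = seq_len)
      tc <- train_config(max_epochs = trial_epochs,
                         patience = trial_patience,
                         batch_size = config$batch_size,
                         learning_rate = config$learning_rate,
                         seed = trial_seed)
      fit <- train_model(init_model(mc, seed = trial_seed),
                         train_windows, val_windows, tc)
      fit$best_auc
    }
  }
  rows <- vector("list", n_trials)
  failures <- list()
  local_seed(seed, {
    trial_seeds <- sample.int(2^30, n_trials)
    for (t in seq_len(n_trials)) {
      cand <- draw(space, seq_len)
      auc_t <- tryCatch(objective(cand, trial_seeds[t]), error = function(e) {
        failures[[length(failures) + 1L]] <<- conditionMessage(e)
        NA_real_
      })
      rows[[t]] <- tibble::as_tibble(c(list(trial = t, auc = auc_t), cand))
    }
  })
  trials <- dplyr::bind_rows(rows)
  if (all(is.na(trials$auc))) {
    abort(paste0("All trials failed: ",
                 paste(unique(unlist(failures)), collapse = "; ")),
          class = "ctg_search_error")
  }
  best_trial <- which.max(trials$auc)
  best_config <- as.list(trials[best_trial,
                                setdiff(names(trials), c("trial", "auc"))])
  structure(list(best_config = best_config,
                 best_auc = trials$auc[best_trial],
                 best_trial = best_trial, trials = trials),
            class = "ctg_hpo")
}

#' @export
print.ctg_hpo <- function(x, ...) {
  cat(sprintf("<ctg_hpo: %d trials, best AUC %.4f (trial %d)>\n",
              nrow(x$trials), x$best_auc, x$best_trial))
  invisible(x)
}
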