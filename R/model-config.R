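# Model configuration and parameter initialisation.

#' Transformer configuration
#'
#' Hyperparameters of the patch transformer. Defaults are the tuned operating
#' configuration for one-hour CTG windows: 6 encoder layers, 4 attention
#' heads, model width 512, feed-forward width 128, dropout 0.1 / attention
#' dropout 0.2 / pre-head dropout 0.4, non-overlapping patches of length 16,
#' ReLU feed-forward activation.
#'
#' @param n_layers Encoder layers.
#' @param n_heads Attention heads; must divide `d_model`.
#' @param d_model Token embedding width.
#' @param d_ff Feed-forward hidden width.
#' @param dropout Dropout rate after patch embedding and inside the FFN.
#' @param fc_dropout Dropout rate before the classification head.
#' @param attn_dropout Dropout rate on attention weights.
#' @param patch_len Patch length P in steps.
#' @param stride Patch stride S in steps (`stride < patch_len` gives
#'   overlapping patches).
#' @param kernel_size Width of the optional input smoothing convolution.
#' @param smooth_input Apply the (identity-initialised, non-trained) input
#'   smoothing convolution after instance normalisation? Off by default.
#' @param activation One of "relu", "gelu", "elu".
#' @param seq_len Window length L in steps.
#' @param n_channels Number of signal channels (FHR, TOCO).
#' @return A `ctg_config` list; `n_patches` is derived as
#'   `floor((seq_len - patch_len) / stride) + 1`.
#' @export
model_config <- function(n_layers = 6L, n_heads = 4L, d_model = 512L,
                         d_ff = 128L, dropout = 0.1, fc_dropout = 0.4,
                         attn_dropout = 0.2, patch_len = 16L, stride = 16L,
                         kernel_size = 15L, smooth_input = FALSE,
                         activation = c("relu", "gelu", "elu"),
                         seq_len = 960L, n_channels = 2L) {
  activation <- match.arg(activation)
  check_number(n_layers, "n_layers", 1, Inf, integer = TRUE)
  check_number(n_heads, "n_heads", 1, Inf, integer = TRUE)
  check_number(d_model, "d_model", 1, Inf, integer = TRUE)
  check_number(d_ff, "d_ff", 1, Inf, integer = TRUE)
  check_number(patch_len, "patch_len", 1, Inf, integer = TRUE)
  check_number(stride, "stride", 1, Inf, integer = TRUE)
  check_number(seq_len, "seq_len", 1, Inf, integer = TRUE)
  for (nm in c("dropout", "fc_dropout", "attn_dropout")) {
    check_number(get(nm), nm, 0, 1, closed_upper = FALSE)
  }
  if (patch_len > seq_len) {
    abort("`patch_len` must not exceed `seq_len`.", class = "ctg_config_error")
  }
  if (d_model %% n_heads != 0L) {
    abort("`d_model` must be divisible by `n_heads`.", class = "ctg_config_error")
  }
  structure(
    list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         d_model = as.integer(d_model), d_ff = as.integer(d_ff),
         dropout = dropout, fc_dropout = fc_dropout,
         attn_dropout = attn_dropout,
         patch_len = as.integer(patch_len), stride = as.integer(stride),
         kernel_size = as.integer(kernel_size), smooth_input = smooth_input,
         activation = activation, seq_len = as.integer(seq_len),
         n_channels = as.integer(n_channels),
         n_patches = patch_count(seq_len, patch_len, stride)),
    class = "ctg_config")
}

#' Patch-count law
#'
#' Number of patches obtained from a length-`seq_len` series with patch
#' length `patch_len` and stride `stride`:
#' `floor((seq_len - patch_len) / stride) + 1`.
#'
#' @param seq_len,patch_len,stride Integers with `patch_len <= seq_len`.
#' @return Integer patch count N.
#' @export
patch_count <- function(seq_len, patch_len, stride) {
  if (patch_len > seq_len) {
    abort("`patch_len` must not exceed `seq_len`.", class = "ctg_config_error")
  }
  as.integer((seq_len - patch_len) %/% stride + 1L)
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialise a patch-transformer model
#'
#' Builds the full parameter set: per channel a patch projection `W_P`
#' (P x d) and a learned positional table `W_pos` (N x d, small-variance
#' normal init), per layer the attention projections, layer norms and
#' feed-forward weights, and a single classification head over the
#' concatenated channel summaries (2d weights + bias).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation.
#' @return A `ctg_model` object (list: `config`, `params`, `seed`).
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ctg_config"))
  d <- config$d_model; dff <- config$d_ff
  P <- config$patch_len; N <- config$n_patches
  local_seed(seed, {
    channel <- function() {
      layers <- lapply(seq_len(config$n_layers), function(l) list(
        Wq = glorot(d, d), bq = rep(0, d),
        Wk = glorot(d, d), bk = rep(0, d),
        Wv = glorot(d, d), bv = rep(0, d),
        Wo = glorot(d, d), bo = rep(0, d),
        g1 = rep(1, d), c1 = rep(0, d),
        W1 = glorot(d, dff), f1 = rep(0, dff),
        W2 = glorot(dff, d), f2 = rep(0, d),
        g2 = rep(1, d), c2 = rep(0, d)))
      list(W_P = glorot(P, d),
           W_pos = matrix(rnorm(N * d, 0, 0.02), N, d),
           layers = layers)
    }
    params <- list(channels = lapply(seq_len(config$n_channels),
                                     function(i) channel()),
                   Wc = rnorm(config$n_channels * d, 0, 0.02),
                   bc = 0)
    structure(list(config = config, params = params, seed = seed),
              class = "ctg_model")
  })
}

#' @export
print.ctg_model <- function(x, ...) {
  n_par <- sum(unlist(rapply(x$params, length, how = "list")))
  cat(sprintf(paste0("<ctg_model: %d layers, %d heads, d_model %d, ",
                     "%d patches of %d, %s parameters>\n"),
              x$config$n_layers, x$config$n_heads, x$config$d_model,
              x$config$n_patches, x$config$patch_len,
              format(n_par, big.mark = ",")))
  invisible(x)
}

#' Model card: hyperparameters and training provenance as JSON
#'
#' Summarises a model's configuration, initialisation seed, parameter count
#' and (if trained) its history into a plain list, optionally written as a
#' JSON model card next to a serialized checkpoint.
#'
#' @param model A `ctg_model`.
#' @param path Optional path to write the JSON card to.
#' @return The card as a list, invisibly if written.
#' @export
model_card <- function(model, path = NULL) {
  card <- list(
    config = unclass(model$config),
    seed = model$seed,
    n_parameters = sum(unlist(rapply(model$params, length, how = "unlist"))),
    best_epoch = model$best_epoch %||% NA_integer_,
    best_auc = model$best_auc %||% NA_real_,
    history = if (!is.null(model$history)) as.data.frame(model$history))
  if (is.null(path)) return(card)
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(card)
}
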