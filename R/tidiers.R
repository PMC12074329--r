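# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   labs theme_minimal sec_axis scale_y_continuous
#' @export
ggplot2::autoplot

#' Tidy a fitted model's parameter inventory
#'
#' @param x A `ctg_model`.
#' @param ... Unused.
#' @return Tibble: `component`, `n_parameters`.
#' @method tidy ctg_model
#' @export
tidy.ctg_model <- function(x, ...) {
  leaves <- unlist(rapply(x$params, length, how = "unlist"))
  tibble::tibble(component = names(leaves), n_parameters = unname(leaves))
}

#' @rdname tidy.ctg_model
#' @return `glance()`: one-row tibble with the architecture, total parameter
#'   count and (if trained) best epoch / best validation AUC.
#' @method glance ctg_model
#' @export
glance.ctg_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers, n_heads = x$config$n_heads,
    d_model = x$config$d_model, d_ff = x$config$d_ff,
    patch_len = x$config$patch_len, stride = x$config$stride,
    n_patches = x$config$n_patches,
    n_parameters = sum(unlist(rapply(x$params, length, how = "unlist"))),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_auc = x$best_auc %||% NA_real_)
}

#' Tidy a matching result
#'
#' @param x A `ctg_match` from [propensity_match()].
#' @param ... Unused.
#' @return Long tibble: `covariate`, `stage` (before/after), `smd`.
#' @method tidy ctg_match
#' @export
tidy.ctg_match <- function(x, ...) {
  tidyr::pivot_longer(x$smd, c("before", "after"),
                      names_to = "stage", values_to = "smd")
}

#' @rdname tidy.ctg_match
#' @method glance ctg_match
#' @export
glance.ctg_match <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), balanced = x$balanced,
                 status = x$status, max_smd_after = max(x$smd$after))
}

#' Tidy a hyperparameter search
#'
#' @param x A `ctg_hpo` from [hpo_search()].
#' @param ... Unused.
#' @return The per-trial tibble (`tidy`) or a one-row best-trial summary
#'   (`glance`).
#' @method tidy ctg_hpo
#' @export
tidy.ctg_hpo <- function(x, ...) x$trials

#' @rdname tidy.ctg_hpo
#' @method glance ctg_hpo
#' @export
glance.ctg_hpo <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$trials), best_trial = x$best_trial,
                 best_auc = x$best_auc)
}

#' Plot an ROC curve
#'
#' @param object A `ctg_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ctg_roc
#' @export
autoplot.ctg_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#d95f02") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC curve (AUC = %.3f)", auc(object))) +
    theme_minimal()
}

#' Plot a days-to-delivery sweep
#'
#' @param object A `ctg_sweep` from [temporal_sweep()].
#' @param ... Unused.
#' @return A ggplot of AUC against the day threshold.
#' @method autoplot ctg_sweep
#' @export
autoplot.ctg_sweep <- function(object, ...) {
  ggplot(object[!object$flagged, ],
         aes(x = .data$max_days, y = .data$auc)) +
    geom_line(colour = "#1b9e77") + geom_point() +
    labs(x = "Days-to-delivery threshold", y = "AUC",
         title = "AUC by days-to-delivery threshold") +
    theme_minimal()
}

#' Plot a training history
#'
#' @param model A trained `ctg_model` (with a `history` element).
#' @return A ggplot of training loss and validation AUC per epoch.
#' @export
plot_history <- function(model) {
  h <- model$history
  stopifnot(!is.null(h))
  long <- tidyr::pivot_longer(h, c("train_loss", "val_auc"),
                              names_to = "series", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$series)) +
    geom_line() +
    labs(x = "Epoch", y = NULL, colour = NULL,
         title = "Training loss and validation AUC") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
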