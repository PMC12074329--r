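# ROC analysis, operating-point selection and the days-to-delivery sweep.
#
# A "prediction set" is any tibble with a `score` column (probabilities) and
# a `label` column (0/1); predict.ctg_model() produces one. The decision
# rule is everywhere "positive iff score >= threshold".

check_pred <- function(pred) {
  stopifnot(all(c("score", "label") %in% names(pred)))
  if (any(pred$score < 0 | pred$score > 1)) {
    abort("Scores must be probabilities in [0, 1].", class = "ctg_pred_error")
  }
  if (length(unique(pred$label)) < 2L) {
    abort("Both classes are required; AUC is undefined on one class.",
          class = "ctg_auc_undefined")
  }
  pred
}

#' Empirical ROC curve
#'
#' Thresholds are the distinct scores in decreasing order, preceded by an
#' `Inf` sentinel (no positives). TPR and FPR are monotone non-decreasing
#' along the curve.
#'
#' @param pred Prediction set (tibble with `score`, `label`).
#' @return A `ctg_roc` tibble: `threshold`, `tpr`, `fpr`.
#' @export
#' @examples
#' pred <- tibble::tibble(score = c(.1, .4, .35, .8), label = c(0, 0, 1, 1))
#' roc_curve(pred)
roc_curve <- function(pred) {
  check_pred(pred)
  th <- c(Inf, sort(unique(pred$score), decreasing = TRUE))
  n1 <- sum(pred$label == 1)
  n0 <- sum(pred$label == 0)
  tpr <- vapply(th, function(t) sum(pred$score >= t & pred$label == 1) / n1, 0)
  fpr <- vapply(th, function(t) sum(pred$score >= t & pred$label == 0) / n0, 0)
  structure(tibble::tibble(threshold = th, tpr = tpr, fpr = fpr),
            class = c("ctg_roc", "tbl_df", "tbl", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over FPR; with the threshold-at-every-distinct-score
#' construction this equals the tie-corrected Mann-Whitney probability that
#' a random positive outscores a random negative (ties count one half).
#'
#' @param roc A [roc_curve()] result (or a prediction set, which is
#'   converted first).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  if (!inherits(roc, "ctg_roc")) roc <- roc_curve(roc)
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# Rank-statistic AUC (tie-corrected Mann-Whitney), used as the cross-check
# route in tests and asserted equal to the trapezoid.
auc_rank <- function(pred) {
  check_pred(pred)
  r <- rank(pred$score)
  n1 <- sum(pred$label == 1); n0 <- sum(pred$label == 0)
  (sum(r[pred$label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metric panel at a threshold
#'
#' Applies "positive iff score >= threshold" and reports the confusion
#' counts with sensitivity, specificity, PPV, NPV, F1 and accuracy.
#' Zero-denominator metrics are reported as `NA` (undefined), never as 0.
#'
#' @param pred Prediction set.
#' @param threshold Decision threshold.
#' @return One-row tibble: threshold, tp, fp, tn, fn, sensitivity,
#'   specificity, ppv, npv, f1, accuracy.
#' @export
metrics_at <- function(pred, threshold) {
  pos <- pred$score >= threshold
  tp <- sum(pos & pred$label == 1); fp <- sum(pos & pred$label == 0)
  fn <- sum(!pos & pred$label == 1); tn <- sum(!pos & pred$label == 0)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else {
    2 * ppv * sens / (ppv + sens)
  }
  tibble::tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1,
                 accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Operating point maximising Youden's J
#'
#' J = sensitivity + specificity - 1, maximised over the ROC thresholds by
#' exhaustive scan; ties are broken toward the *higher* threshold (the more
#' specific operating point, favouring fewer false alarms).
#'
#' @param roc A [roc_curve()] result or prediction set.
#' @return List: `threshold`, `j`.
#' @export
youden_threshold <- function(roc) {
  if (!inherits(roc, "ctg_roc")) roc <- roc_curve(roc)
  finite <- roc[is.finite(roc$threshold), ]
  j <- finite$tpr - finite$fpr
  best <- max(j)
  cand <- finite$threshold[j == best]
  list(threshold = max(cand), j = best)
}

#' Threshold meeting a sensitivity (or specificity) floor
#'
#' `threshold_at_sensitivity()` returns the highest threshold whose
#' sensitivity is at least `target` — i.e. the most specific operating point
#' subject to the sensitivity floor. `threshold_at_specificity()` is the
#' symmetric operation: the lowest threshold whose specificity is at least
#' `target`, maximising sensitivity subject to the specificity floor.
#'
#' @param roc A [roc_curve()] result or prediction set.
#' @param target Floor in (0, 1\].
#' @return The selected threshold.
#' @export
threshold_at_sensitivity <- function(roc, target = 0.90) {
  check_number(target, "target", 0, 1, closed_upper = TRUE)
  if (!inherits(roc, "ctg_roc")) roc <- roc_curve(roc)
  ok <- roc$threshold[is.finite(roc$threshold) & roc$tpr >= target]
  if (length(ok) == 0L) {
    abort("Sensitivity target unreachable.", class = "ctg_unreachable_target")
  }
  max(ok)
}

#' @rdname threshold_at_sensitivity
#' @export
threshold_at_specificity <- function(roc, target = 0.90) {
  check_number(target, "target", 0, 1, closed_upper = TRUE)
  if (!inherits(roc, "ctg_roc")) roc <- roc_curve(roc)
  ok <- roc$threshold[is.finite(roc$threshold) & (1 - roc$fpr) >= target]
  if (length(ok) == 0L) {
    abort("Specificity target unreachable.", class = "ctg_unreachable_target")
  }
  min(ok)
}

#' Evaluate the four standard operating points
#'
#' Default (0.5), Youden's J maximiser, the high-sensitivity floor and the
#' high-specificity floor, each with its full metric panel.
#'
#' @param pred Prediction set.
#' @param sens_target,spec_target Floors for the high-sensitivity /
#'   high-specificity points.
#' @return A tibble with a `kind` column and one metric-panel row per
#'   operating point (unreachable floors are dropped with a warning).
#' @export
operating_points <- function(pred, sens_target = 0.90, spec_target = 0.90) {
  roc <- roc_curve(pred)
  pts <- list(default = 0.5, youden = youden_threshold(roc)$threshold)
  for (k in c("high_sensitivity", "high_specificity")) {
    th <- tryCatch(
      if (k == "high_sensitivity") threshold_at_sensitivity(roc, sens_target)
      else threshold_at_specificity(roc, spec_target),
      ctg_unreachable_target = function(e) {
        warn(sprintf("%s floor unreachable; operating point dropped.", k))
        NULL
      })
    if (!is.null(th)) pts[[k]] <- th
  }
  dplyr::bind_rows(lapply(names(pts), function(k) {
    dplyr::mutate(metrics_at(pred, pts[[k]]), kind = k, .before = 1L)
  }))
}

#' Days-to-delivery evaluation sweep
#'
#' For each day threshold `d`, evaluates the prediction set restricted to
#' all controls plus the adverse cases recorded within `d` days of delivery,
#' reporting the AUC and the case count. Rows whose adverse subset is empty
#' are flagged, not dropped.
#'
#' @param pred Prediction set that also carries `days_to_delivery`.
#' @param day_thresholds Integer vector of upper bounds (default 1:7).
#' @return A `ctg_sweep` tibble: `max_days`, `auc`, `n_cases`, `n_controls`,
#'   `flagged`.
#' @export
temporal_sweep <- function(pred, day_thresholds = 1:7) {
  stopifnot("days_to_delivery" %in% names(pred))
  rows <- lapply(day_thresholds, function(d) {
    sub <- pred[pred$label == 0 |
                  (pred$label == 1 & pred$days_to_delivery <= d), ]
    n_cases <- sum(sub$label == 1)
    if (n_cases == 0L || sum(sub$label == 0) == 0L) {
      return(tibble::tibble(max_days = d, auc = NA_real_,
                            n_cases = n_cases,
                            n_controls = sum(sub$label == 0),
                            flagged = TRUE))
    }
    tibble::tibble(max_days = d, auc = auc(roc_curve(sub)),
                   n_cases = n_cases, n_controls = sum(sub$label == 0),
                   flagged = FALSE)
  })
  structure(dplyr::bind_rows(rows),
            class = c("ctg_sweep", "tbl_df", "tbl", "data.frame"))
}
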