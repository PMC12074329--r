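# Cohort balancing: standardised mean differences, one-to-one propensity
# matching, stratified splitting and days-to-delivery selection.

#' Standardised mean difference between two groups
#'
#' `|mean1 - mean0| / sqrt((s1^2 + s0^2) / 2)` with sample variances, the
#' usual two-group balance diagnostic for matched cohorts.
#'
#' @param data A data frame.
#' @param covariate Name of the numeric covariate column.
#' @param group Name of the binary group column (0/1).
#' @return The SMD (dimensionless, non-negative).
#' @export
#' @examples
#' d <- data.frame(g = rep(0:1, each = 4), x = c(1:4, 2:5))
#' compute_smd(d, "x", "g")
compute_smd <- function(data, covariate, group = "label") {
  x <- data[[covariate]]
  g <- data[[group]]
  x1 <- x[g == 1]; x0 <- x[g == 0]
  if (length(x1) == 0L || length(x0) == 0L) {
    abort("Both groups must be non-empty.", class = "ctg_smd_error")
  }
  pooled <- (var(x1) + var(x0)) / 2
  if (!is.finite(pooled) || pooled <= 0) {
    abort("Pooled variance is zero or undefined; SMD is not defined.",
          class = "ctg_smd_error")
  }
  abs(mean(x1) - mean(x0)) / sqrt(pooled)
}

#' One-to-one propensity-score matching with SMD audit
#'
#' Fits a logistic propensity model of the label on the covariates, then
#' greedily pairs each case with its nearest unused control on the logit
#' scale, cases processed in descending propensity. SMDs for every covariate
#' are reported before and after matching; the cohort is flagged balanced iff
#' all post-matching SMDs fall below `balance_threshold`.
#'
#' @param data Cohort metadata with an id column, a binary label column and
#'   the covariates.
#' @param covariates Character vector of covariate column names.
#' @param id,label Column names for the unit id and binary label.
#' @param caliper Optional maximum |logit distance| for a pair, expressed in
#'   standard deviations of the logit; `NULL` disables it.
#' @param balance_threshold SMD threshold for the balance flag.
#' @param seed Seed (used only to break exact distance ties reproducibly).
#' @return A `ctg_match` object: `pairs` tibble (case_id, control_id,
#'   distance), `smd` tibble (covariate, before, after), `balanced`,
#'   `status` ("ok" or "partial"), `matched_ids`.
#' @export
propensity_match <- function(data, covariates, id = "trace_id",
                             label = "label", caliper = NULL,
                             balance_threshold = 0.10, seed = 1L) {
  g <- data[[label]]
  if (sum(g == 1) < 1L || sum(g == 0) < 1L) {
    abort("Need at least one case and one control.", class = "ctg_match_error")
  }
  fml <- stats::reformulate(covariates, response = label)
  fit <- glm(fml, data = data, family = binomial())
  logit <- as.numeric(predict(fit, type = "link"))

  case_idx <- which(g == 1)
  ctrl_idx <- which(g == 0)
  partial <- length(ctrl_idx) < length(case_idx)
  if (partial) {
    warn("Fewer controls than cases: matching will be partial.",
         class = "ctg_match_partial")
  }
  cal <- if (is.null(caliper)) Inf else caliper * sd(logit)

  pairs <- local_seed(seed, {
    # Deterministic tie-break: jitter far below data scale.
    eps <- runif(length(logit), 0, 1e-9)
    score <- logit + eps
    used <- logical(length(ctrl_idx))
    res <- list()
    for (ci in case_idx[order(score[case_idx], decreasing = TRUE)]) {
      free <- which(!used)
      if (length(free) == 0L) break
      d <- abs(score[ctrl_idx[free]] - score[ci])
      j <- free[which.min(d)]
      if (min(d) <= cal) {
        used[j] <- TRUE
        res[[length(res) + 1L]] <- tibble::tibble(
          case_id = data[[id]][ci],
          control_id = data[[id]][ctrl_idx[j]],
          distance = abs(logit[ctrl_idx[j]] - logit[ci]))
      }
    }
    dplyr::bind_rows(res)
  })
  if (nrow(pairs) == 0L) {
    abort("No admissible pairs under the caliper.", class = "ctg_match_error")
  }

  matched_ids <- c(pairs$case_id, pairs$control_id)
  matched <- data[data[[id]] %in% matched_ids, , drop = FALSE]
  # SMD is undefined on degenerate matched sets (e.g. a single pair); the
  # audit reports NA there rather than failing the whole match.
  smd_or_na <- function(dd, v) {
    tryCatch(compute_smd(dd, v, label), ctg_smd_error = function(e) NA_real_)
  }
  smd <- tibble::tibble(
    covariate = covariates,
    before = vapply(covariates, function(v) smd_or_na(data, v), 0),
    after = vapply(covariates, function(v) smd_or_na(matched, v), 0))

  structure(list(pairs = pairs, smd = smd,
                 balanced = all(smd$after < balance_threshold),  # NA if undefined
                 status = if (partial) "partial" else "ok",
                 matched_ids = matched_ids,
                 propensity = tibble::tibble(id = data[[id]], logit = logit)),
            class = "ctg_match")
}

#' @export
print.ctg_match <- function(x, ...) {
  cat(sprintf("<ctg_match: %d pairs (%s), balanced = %s>\n",
              nrow(x$pairs), x$status, x$balanced))
  print(x$smd)
  invisible(x)
}

#' Stratified train/validation split
#'
#' Splits ids so that the training set holds `floor(train_fraction * N)` ids
#' overall, allocating per-stratum floors and topping up the strata with the
#' largest fractional remainders until the total is exact. Deterministic
#' given the seed.
#'
#' @param ids Unique id vector.
#' @param train_fraction Fraction of ids assigned to training.
#' @param stratify_by Optional vector (same length as `ids`) of stratum
#'   labels, e.g. the outcome label.
#' @param seed Integer seed.
#' @return A list with `train` and `eval` id vectors (disjoint, exhaustive).
#' @export
#' @examples
#' sp <- split_cohort(1:10, 0.8, stratify_by = rep(0:1, 5), seed = 1)
#' lengths(sp)
split_cohort <- function(ids, train_fraction = 0.8, stratify_by = NULL,
                         seed = 1L) {
  n <- length(ids)
  if (n < 2L) abort("Need at least 2 ids to split.", class = "ctg_split_error")
  if (anyDuplicated(ids)) {
    abort("`ids` must be unique.", class = "ctg_split_error")
  }
  check_number(train_fraction, "train_fraction", 0, 1)
  strata <- if (is.null(stratify_by)) rep(1L, n) else as.character(stratify_by)
  target <- floor(train_fraction * n)
  local_seed(seed, {
    lv <- unique(strata)
    sizes <- vapply(lv, function(s) sum(strata == s), 0L)
    exact <- train_fraction * sizes
    base <- floor(exact)
    deficit <- target - sum(base)
    extra <- rep(0L, length(lv))
    if (deficit > 0) {
      ord <- order(exact - base, decreasing = TRUE)
      extra[ord[seq_len(deficit)]] <- 1L
    } else if (deficit < 0) {
      ord <- order(exact - base)
      extra[ord[seq_len(-deficit)]] <- -1L
    }
    train <- character(0)
    train_idx <- integer(0)
    for (k in seq_along(lv)) {
      idx <- which(strata == lv[k])
      n_k <- base[k] + extra[k]
      train_idx <- c(train_idx, sample(idx, n_k))
    }
    list(train = ids[sort(train_idx)], eval = ids[sort(setdiff(seq_len(n), train_idx))])
  })
}

#' Select cohort records by days to delivery
#'
#' Retains adverse-class records whose `days_to_delivery` lies within the
#' bound; controls are kept unfiltered by default (set
#' `filter_controls = TRUE` to apply the same bound to both classes).
#'
#' @param cohort A metadata tibble with `label` and `days_to_delivery`.
#' @param max_days Either a single upper bound (days <= max_days) or a length-2
#'   inclusive range `c(lo, hi)`.
#' @param filter_controls Apply the bound to controls too?
#' @return The filtered tibble; warns (class `ctg_empty_subset`) if the
#'   adverse subset comes back empty.
#' @export
select_by_days_to_delivery <- function(cohort, max_days,
                                       filter_controls = FALSE) {
  if (length(max_days) == 1L) max_days <- c(0, max_days)
  stopifnot(length(max_days) == 2L)
  in_range <- cohort$days_to_delivery >= max_days[1] &
    cohort$days_to_delivery <= max_days[2]
  keep <- if (filter_controls) in_range else in_range | cohort$label == 0L
  out <- cohort[keep, , drop = FALSE]
  if (!any(out$label == 1L)) {
    warn("No adverse records left after the days-to-delivery filter.",
         class = "ctg_empty_subset")
  }
  out
}
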