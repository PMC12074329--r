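# Signal conditioning, quality filtering and fixed-length windowing.
#
# Pipeline: clean_channels() clips raw channels into their physical ranges,
# scale_unit() maps them onto [0, 1] and converts the -1 sentinel into an
# explicit per-sample validity mask, quality_filter() drops traces with too
# much dropout, and windowize() cuts unit-scaled traces into 960-step windows
# anchored at the delivery-proximal end of the recording.

FHR_RANGE <- c(50, 250)
TOCO_RANGE <- c(0, 100)
WINDOW_LEN <- 960L

#' Clip raw channels into their physical ranges
#'
#' Non-missing FHR samples are clipped into \[50, 250\] bpm and TOCO into
#' \[0, 100\]; the `-1` missing sentinel is preserved untouched.
#'
#' @param trace A [ctg_trace()] on the raw scale.
#' @return The trace with clipped channels.
#' @export
clean_channels <- function(trace) {
  if (!inherits(trace, "ctg_trace") || length(trace$fhr) == 0L) {
    abort("`trace` must be a non-empty ctg_trace.", class = "ctg_validation_error")
  }
  obs_f <- trace$fhr != CTG_SENTINEL
  obs_t <- trace$toco != CTG_SENTINEL
  trace$fhr[obs_f] <- pmin(pmax(trace$fhr[obs_f], FHR_RANGE[1]), FHR_RANGE[2])
  trace$toco[obs_t] <- pmin(pmax(trace$toco[obs_t], TOCO_RANGE[1]), TOCO_RANGE[2])
  trace
}

#' Scale cleaned channels onto the unit interval
#'
#' FHR maps by `(x - 50) / 200`, TOCO by `x / 100`. Missing samples are
#' recorded in per-channel logical masks (`TRUE` = observed) and their values
#' set to the 0.0 fill; from here on the `-1` sentinel no longer exists.
#'
#' @param trace A cleaned [ctg_trace()].
#' @return The trace with `fhr`/`toco` in \[0, 1\] plus `fhr_mask` and
#'   `toco_mask` fields, class `ctg_trace_scaled`.
#' @export
scale_unit <- function(trace) {
  if (!inherits(trace, "ctg_trace")) {
    abort("`trace` must be a ctg_trace.", class = "ctg_validation_error")
  }
  obs_f <- trace$fhr != CTG_SENTINEL
  obs_t <- trace$toco != CTG_SENTINEL
  if (any(trace$fhr[obs_f] < FHR_RANGE[1] | trace$fhr[obs_f] > FHR_RANGE[2]) ||
      any(trace$toco[obs_t] < TOCO_RANGE[1] | trace$toco[obs_t] > TOCO_RANGE[2])) {
    abort("Out-of-range values present; run clean_channels() first.",
          class = "ctg_validation_error")
  }
  trace$fhr <- ifelse(obs_f, (trace$fhr - FHR_RANGE[1]) / diff(FHR_RANGE), 0)
  trace$toco <- ifelse(obs_t, trace$toco / TOCO_RANGE[2], 0)
  trace$fhr_mask <- obs_f
  trace$toco_mask <- obs_t
  class(trace) <- c("ctg_trace_scaled", class(trace))
  trace
}

#' Trace quality filter
#'
#' Keeps a trace iff the missing fraction pooled over both channels is at
#' most `max_missing` (strictly more than the threshold excludes).
#'
#' @param trace A [ctg_trace()] (raw, with `-1` sentinels).
#' @param max_missing Exclusion threshold on the joint missing fraction.
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
quality_filter <- function(trace, max_missing = 0.30) {
  frac <- mean(c(trace$fhr, trace$toco) == CTG_SENTINEL)
  frac <= max_missing
}

#' Segment a unit-scaled trace into fixed 960-step windows
#'
#' Windows are taken from the end of the trace backwards, so the hour nearest
#' delivery is always a complete window (`window_index` 0). A leading
#' remainder shorter than 960 steps is kept as a right-padded window iff it
#' has at least `min_observed` observed steps (a step counts as observed when
#' both channel masks are TRUE); padding positions are mask-false with the
#' 0.0 fill.
#'
#' @param trace A trace from [scale_unit()].
#' @param window_len Window length in steps.
#' @param min_observed Minimum fully observed steps for a padded remainder
#'   window to be admitted.
#' @return A tibble with one row per window: `trace_id`, `window_index`
#'   (0 = nearest delivery), `label`, `days_to_delivery`, and list-columns
#'   `values` (2 x 960 matrix, rows `fhr`, `toco`) and `valid` (2 x 960
#'   logical).
#' @export
windowize <- function(trace, window_len = WINDOW_LEN, min_observed = 480L) {
  if (!inherits(trace, "ctg_trace_scaled")) {
    abort("`trace` must be cleaned and unit-scaled (see scale_unit()).",
          class = "ctg_validation_error")
  }
  T_len <- length(trace$fhr)
  k <- T_len %/% window_len
  r <- T_len - k * window_len
  out <- list()
  # Full windows, walking backwards from the end.
  for (j in seq_len(k)) {
    idx <- (T_len - j * window_len + 1):(T_len - (j - 1) * window_len)
    out[[length(out) + 1L]] <- list(
      window_index = j - 1L,
      values = rbind(fhr = trace$fhr[idx], toco = trace$toco[idx]),
      valid = rbind(fhr = trace$fhr_mask[idx], toco = trace$toco_mask[idx]))
  }
  # Leading remainder: admit as a padded window iff >= min_observed steps
  # observed on both channels.
  if (r > 0) {
    idx <- seq_len(r)
    n_obs <- sum(trace$fhr_mask[idx] & trace$toco_mask[idx])
    if (n_obs >= min_observed) {
      pad <- window_len - r
      out[[length(out) + 1L]] <- list(
        window_index = k,
        values = rbind(fhr = c(trace$fhr[idx], rep(0, pad)),
                       toco = c(trace$toco[idx], rep(0, pad))),
        valid = rbind(fhr = c(trace$fhr_mask[idx], rep(FALSE, pad)),
                      toco = c(trace$toco_mask[idx], rep(FALSE, pad))))
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(trace_id = character(), window_index = integer(),
                          label = integer(), days_to_delivery = integer(),
                          values = list(), valid = list()))
  }
  tibble::tibble(
    trace_id = trace$trace_id,
    window_index = vapply(out, `[[`, 0L, "window_index"),
    label = trace$label,
    days_to_delivery = trace$days_to_delivery,
    values = lapply(out, `[[`, "values"),
    valid = lapply(out, `[[`, "valid"))
}

#' Preprocess a whole cohort into model-ready windows
#'
#' Convenience wrapper: quality-filters, clips, unit-scales and windows every
#' trace, returning a single windows tibble with a `window_id`.
#'
#' @param traces List of [ctg_trace()].
#' @param max_missing Quality-filter threshold (see [quality_filter()]).
#' @param window_len,min_observed Passed to [windowize()].
#' @return A windows tibble (see [windowize()]) with a `window_id` column.
#' @export
prepare_windows <- function(traces, max_missing = 0.30,
                            window_len = WINDOW_LEN, min_observed = 480L) {
  keep <- vapply(traces, quality_filter, TRUE, max_missing = max_missing)
  parts <- lapply(traces[keep], function(tr) {
    windowize(scale_unit(clean_channels(tr)),
              window_len = window_len, min_observed = min_observed)
  })
  w <- dplyr::bind_rows(parts)
  if (nrow(w)) {
    w <- dplyr::mutate(w,
      window_id = paste0(.data$trace_id, "_w", .data$window_index),
      .before = 1L)
  }
  w
}
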