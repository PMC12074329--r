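# Plain-text persistence for traces and cohort metadata.

#' Write / read a CTG trace as delimited text
#'
#' The on-disk dialect is a three-column CSV (`index`, `fhr`, `toco`) with
#' `-1` marking missing samples; clinical metadata travels in the cohort
#' metadata table, not the signal file.
#'
#' @param trace A [ctg_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   [ctg_trace()] (label and days-to-delivery must be supplied or joined from
#'   the metadata table afterwards).
#' @export
write_trace <- function(trace, path) {
  # %.17g guarantees binary64 round-trip through the text file
  lines <- c("index,fhr,toco",
             sprintf("%d,%.17g,%.17g", seq_along(trace$fhr) - 1L,
                     trace$fhr, trace$toco))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @param trace_id Id to attach; defaults to the file stem.
#' @param label,days_to_delivery,covariates Metadata to attach.
#' @export
read_trace <- function(path, trace_id = sub("\\.csv$", "", basename(path)),
                       label = 0L, days_to_delivery = 1L,
                       covariates = numeric()) {
  # base strtod parsing is correctly rounded, preserving the %.17g
  # round-trip guarantee of write_trace()
  d <- utils::read.csv(path, colClasses = c("integer", "numeric", "numeric"))
  ctg_trace(trace_id, d$fhr, d$toco, label = label,
            days_to_delivery = days_to_delivery, covariates = covariates)
}

#' Write / read a cohort (traces + metadata) to a directory
#'
#' One CSV per trace plus `cohort.csv` holding trace_id, label,
#' days_to_delivery and covariates.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a cohort list (`traces`, `metadata`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$metadata, file.path(dir, "cohort.csv"))
  for (tr in cohort$traces) {
    write_trace(tr, file.path(dir, paste0(tr$trace_id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  metadata <- readr::read_csv(file.path(dir, "cohort.csv"),
                              col_types = readr::cols())
  cov_cols <- setdiff(names(metadata), c("trace_id", "label", "days_to_delivery"))
  traces <- lapply(seq_len(nrow(metadata)), function(i) {
    row <- metadata[i, ]
    read_trace(file.path(dir, paste0(row$trace_id, ".csv")),
               trace_id = row$trace_id, label = row$label,
               days_to_delivery = row$days_to_delivery,
               covariates = unlist(row[cov_cols]))
  })
  list(traces = traces, metadata = metadata)
}
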