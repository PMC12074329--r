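# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble as_tibble
#' @importFrom stats rnorm runif rpois rgeom rbinom plogis qlogis sd var
#'   glm binomial predict filter quantile
#' @importFrom utils head tail
NULL

# Missing-value sentinel used in raw trace files and raw-scale channels.
CTG_SENTINEL <- -1

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "ctg_parameter_error")
  }
  ok_upper <- if (closed_upper) x <= upper else x < upper
  if (x < lower || !ok_upper) {
    abort(sprintf("`%s` = %s is outside its admissible range [%s, %s%s.",
                  name, format(x), format(lower), format(upper),
                  if (closed_upper) "]" else ")"),
          class = "ctg_parameter_error")
  }
  if (integer && x != trunc(x)) {
    abort(sprintf("`%s` must be an integer.", name),
          class = "ctg_parameter_error")
  }
  invisible(x)
}

sigmoid <- function(x) plogis(x)

# Numerically stable row-wise softmax; -Inf entries get exactly zero weight.
row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e[is.nan(e)] <- 0           # rows that were all -Inf
  s <- rowSums(e)
  s[s == 0] <- 1
  e / s
}
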