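# Synthetic cardiotocography generator.
#
# Emulates one-hour, two-channel antepartum CTG recordings on the 960-step
# grid (one sample per 3.75 s): a slowly wandering fetal heart rate (FHR)
# baseline, band-limited short-term variability, transient accelerations,
# decelerations optionally time-locked to uterine contractions, smooth
# unimodal contraction bumps on the tocodynamometer (TOCO) channel, and
# bursty signal dropout marked with the -1 sentinel on the raw scale.

#' Simulation parameters for synthetic CTG traces
#'
#' Bundles the generative settings used by [simulate_trace()] and
#' [simulate_cohort()]. Defaults describe an unremarkable term antepartum
#' recording; the `adverse_effect` multiplier (applied only to traces with an
#' adverse label) scales variability and the acceleration rate down and the
#' deceleration rate up, planting a class signal in waveform shape.
#'
#' @param baseline_fhr_mean Mean FHR baseline in bpm; must lie in the normal
#'   clinical band \[110, 160\].
#' @param baseline_fhr_sd Between- and within-trace baseline spread in bpm.
#' @param stv_amplitude Short-term variability amplitude (bpm, the SD of the
#'   band-limited variability component).
#' @param accel_rate Expected accelerations per hour.
#' @param decel_rate Expected spontaneous decelerations per hour.
#' @param contraction_rate Expected uterine contractions per hour.
#' @param decel_coupling Probability in \[0, 1\] that a contraction triggers a
#'   time-locked deceleration.
#' @param adverse_effect Dimensionless severity multiplier `m < 1`: adverse
#'   traces use `stv_amplitude * m`, `accel_rate * m` and `decel_rate / m`.
#' @param missing_rate Stationary fraction of samples lost per channel,
#'   in \[0, 1).
#' @param missing_burst_len Mean dropout burst length in samples.
#' @param sample_count Number of samples per trace (960 = one hour).
#'
#' @return An object of class `ctg_sim_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(stv_amplitude = 8)
#' tr <- simulate_trace(p, label = 0, seed = 1)
sim_params <- function(baseline_fhr_mean = 135,
                       baseline_fhr_sd = 8,
                       stv_amplitude = 6,
                       accel_rate = 8,
                       decel_rate = 2,
                       contraction_rate = 10,
                       decel_coupling = 0.5,
                       adverse_effect = 0.5,
                       missing_rate = 0.1,
                       missing_burst_len = 20,
                       sample_count = 960) {
  check_number(baseline_fhr_mean, "baseline_fhr_mean", 110, 160)
  check_number(baseline_fhr_sd, "baseline_fhr_sd", 0, Inf)
  check_number(stv_amplitude, "stv_amplitude", 0, Inf)
  check_number(accel_rate, "accel_rate", 0, Inf)
  check_number(decel_rate, "decel_rate", 0, Inf)
  check_number(contraction_rate, "contraction_rate", 0, Inf)
  check_number(decel_coupling, "decel_coupling", 0, 1)
  check_number(adverse_effect, "adverse_effect", 0, Inf, closed_upper = FALSE)
  if (adverse_effect <= 0) {
    abort("`adverse_effect` must be positive.", class = "ctg_parameter_error")
  }
  check_number(missing_rate, "missing_rate", 0, 1, closed_upper = FALSE)
  check_number(missing_burst_len, "missing_burst_len", 1, Inf)
  check_number(sample_count, "sample_count", 1, Inf, integer = TRUE)
  structure(
    list(baseline_fhr_mean = baseline_fhr_mean,
         baseline_fhr_sd = baseline_fhr_sd,
         stv_amplitude = stv_amplitude,
         accel_rate = accel_rate,
         decel_rate = decel_rate,
         contraction_rate = contraction_rate,
         decel_coupling = decel_coupling,
         adverse_effect = adverse_effect,
         missing_rate = missing_rate,
         missing_burst_len = missing_burst_len,
         sample_count = as.integer(sample_count)),
    class = "ctg_sim_params")
}

#' Construct a CTG trace object
#'
#' A `ctg_trace` holds the two raw-scale channels (`-1` marks missing
#' samples), the binary outcome label and clinical metadata.
#'
#' @param trace_id Character id.
#' @param fhr Numeric vector, bpm or `-1`.
#' @param toco Numeric vector, 0-100 or `-1`; same length as `fhr`.
#' @param label 0 (normal) or 1 (adverse outcome).
#' @param days_to_delivery Non-negative integer days.
#' @param covariates Named numeric vector of matching covariates.
#' @return A `ctg_trace` object.
#' @export
ctg_trace <- function(trace_id, fhr, toco, label = 0L,
                      days_to_delivery = 1L, covariates = numeric()) {
  if (length(fhr) != length(toco)) {
    abort("`fhr` and `toco` must have equal length.",
          class = "ctg_validation_error")
  }
  if (!label %in% c(0L, 1L)) {
    abort("`label` must be 0 or 1.", class = "ctg_validation_error")
  }
  check_number(days_to_delivery, "days_to_delivery", 0, Inf, integer = TRUE)
  structure(
    list(trace_id = as.character(trace_id),
         fhr = as.numeric(fhr), toco = as.numeric(toco),
         label = as.integer(label),
         days_to_delivery = as.integer(days_to_delivery),
         covariates = covariates),
    class = "ctg_trace")
}

#' @export
print.ctg_trace <- function(x, ...) {
  miss <- mean(c(x$fhr, x$toco) == CTG_SENTINEL)
  cat(sprintf("<ctg_trace %s: %d samples, label %d, %d day(s) to delivery, %.1f%% missing>\n",
              x$trace_id, length(x$fhr), x$label, x$days_to_delivery, 100 * miss))
  invisible(x)
}

#' @method as_tibble ctg_trace
#' @export
as_tibble.ctg_trace <- function(x, ...) {
  tibble::tibble(index = seq_along(x$fhr) - 1L, fhr = x$fhr, toco = x$toco)
}

# Smooth standardized low-frequency noise of length n (moving-average filter).
smooth_noise <- function(n, span) {
  z <- rnorm(n + 2 * span)
  k <- rep(1 / (2 * span + 1), 2 * span + 1)
  s <- stats::filter(z, k, sides = 2)
  s <- s[(span + 1):(span + n)]
  s <- as.numeric(s)
  if (sd(s) < 1e-12) return(rep(0, n))
  (s - mean(s)) / sd(s)
}

# Gaussian bump of given center (sample index), half-duration sigma (samples)
# and peak amplitude, evaluated on 1:n.
bump <- function(n, center, sigma, amplitude) {
  t <- seq_len(n)
  amplitude * exp(-0.5 * ((t - center) / sigma)^2)
}

#' Simulate one synthetic CTG trace
#'
#' Generates a two-channel recording on the 3.75 s grid. The FHR channel is a
#' clamped slow baseline walk plus band-limited variability, positive
#' acceleration bumps (~+18 bpm, 15-40 s) and negative decelerations, some
#' time-locked shortly after contraction peaks. The TOCO channel is a resting
#' tone plus smooth unimodal contraction bumps. An adverse label rescales the
#' event rates and variability by `adverse_effect`. Dropout is injected with
#' [inject_missingness()]. Output is deterministic in `(params, label, seed)`.
#'
#' @param params A [sim_params()] object.
#' @param label 0 or 1; 1 applies the adverse-effect multiplier.
#' @param seed Integer seed.
#' @param trace_id Id string for the trace.
#' @param days_to_delivery Metadata carried on the trace.
#' @param covariates Named numeric vector carried on the trace.
#' @return A [ctg_trace()] with FHR in \[50, 250\] or `-1`, TOCO in
#'   \[0, 100\] or `-1`.
#' @export
#' @examples
#' tr <- simulate_trace(sim_params(), label = 1, seed = 7)
#' range(tr$fhr[tr$fhr != -1])
simulate_trace <- function(params, label = 0L, seed = 1L,
                           trace_id = sprintf("trace%06d", seed),
                           days_to_delivery = 1L, covariates = numeric()) {
  if (!inherits(params, "ctg_sim_params")) {
    abort("`params` must come from sim_params().", class = "ctg_parameter_error")
  }
  if (!label %in% c(0L, 1L)) {
    abort("`label` must be 0 or 1.", class = "ctg_parameter_error")
  }
  n <- params$sample_count
  hours <- n / 960                       # grid: 960 samples per hour
  m <- if (label == 1L) params$adverse_effect else 1
  stv <- params$stv_amplitude * m
  accel_rate <- params$accel_rate * m
  decel_rate <- params$decel_rate / m

  local_seed(seed, {
    # Baseline: offset plus slow wander, deviation clamped to +/- 2.5 SD so a
    # quiet trace stays within the clinical baseline band.
    dev <- rnorm(1, 0, 0.6) + 0.6 * smooth_noise(n, span = 120)
    dev <- pmin(pmax(dev, -2.5), 2.5)
    fhr <- params$baseline_fhr_mean + params$baseline_fhr_sd * dev

    # Short-term variability: band-limited noise at amplitude `stv`.
    if (stv > 0) fhr <- fhr + stv * smooth_noise(n, span = 2)

    # Accelerations: transient positive bumps, >= +15 bpm for 15-40 s.
    n_acc <- rpois(1, accel_rate * hours)
    if (n_acc > 0) {
      for (i in seq_len(n_acc)) {
        fhr <- fhr + bump(n, center = runif(1, 1, n),
                          sigma = runif(1, 2, 5),
                          amplitude = 15 + abs(rnorm(1, 3, 2)))
      }
    }

    # Contractions on TOCO: smooth unimodal bumps, 60-90 s wide.
    toco <- 8 + 2 * smooth_noise(n, span = 6)
    n_ctr <- rpois(1, params$contraction_rate * hours)
    ctr_centers <- if (n_ctr > 0) runif(n_ctr, 1, n) else numeric()
    for (c0 in ctr_centers) {
      toco <- toco + bump(n, c0, sigma = runif(1, 6, 10),
                          amplitude = runif(1, 40, 80))
    }

    # Decelerations: spontaneous, plus contraction-coupled dips lagging the
    # contraction peak by ~15 s.
    dec_centers <- runif(rpois(1, decel_rate * hours), 1, n)
    # Coupled dips require some deceleration tendency (decel_rate > 0).
    p_couple <- if (decel_rate > 0) params$decel_coupling else 0
    coupled <- ctr_centers[runif(length(ctr_centers)) < p_couple]
    coupled <- coupled + rnorm(length(coupled), 4, 1)
    for (c0 in c(dec_centers, coupled)) {
      fhr <- fhr - bump(n, c0, sigma = runif(1, 4, 8),
                        amplitude = 20 + abs(rnorm(1, 5, 3)))
    }

    fhr <- pmin(pmax(fhr, 50), 250)
    toco <- pmin(pmax(toco, 0), 100)

    tr <- ctg_trace(trace_id, fhr, toco, label = label,
                    days_to_delivery = days_to_delivery,
                    covariates = covariates)
    inject_missingness(tr, rate = params$missing_rate,
                       burst_len = params$missing_burst_len,
                       seed = seed + 1L)
  })
}

# Alternating-renewal dropout mask: missing runs are geometric with mean
# `burst_len`, observed runs with mean burst_len*(1-rate)/rate, so the
# stationary missing fraction is `rate` and mean burst length `burst_len`.
missing_mask <- function(n, rate, burst_len) {
  if (rate <= 0) return(rep(FALSE, n))
  mean_obs <- burst_len * (1 - rate) / rate
  state <- runif(1) < rate               # TRUE = missing
  out <- logical(0)
  while (length(out) < n) {
    len <- if (state) rgeom(1, 1 / burst_len) + 1 else rgeom(1, 1 / mean_obs) + 1
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n)]
}

#' Inject bursty missingness into a trace
#'
#' Replaces samples with the `-1` sentinel according to a two-state
#' alternating-renewal process whose stationary missing fraction is `rate`
#' and whose mean dropout burst length is `burst_len` samples. Each channel
#' receives an independent dropout mask.
#'
#' @param trace A [ctg_trace()].
#' @param rate Target missing fraction per channel, in \[0, 1).
#' @param burst_len Mean burst length in samples (>= 1).
#' @param seed Integer seed.
#' @return The trace with sentinels injected.
#' @export
inject_missingness <- function(trace, rate, burst_len = 20, seed = 1L) {
  if (!inherits(trace, "ctg_trace")) {
    abort("`trace` must be a ctg_trace.", class = "ctg_parameter_error")
  }
  check_number(rate, "rate", 0, 1, closed_upper = FALSE)
  check_number(burst_len, "burst_len", 1, Inf)
  if (rate == 0) return(trace)
  local_seed(seed, {
    n <- length(trace$fhr)
    trace$fhr[missing_mask(n, rate, burst_len)] <- CTG_SENTINEL
    trace$toco[missing_mask(n, rate, burst_len)] <- CTG_SENTINEL
    trace
  })
}

#' Simulate a labelled CTG cohort
#'
#' Draws `n_normal` control and `n_adverse` case traces plus a metadata table
#' with days-to-delivery (uniform over `days_range`) and clinical matching
#' covariates (gestational age, maternal age, BMI, parity). Covariates are
#' shifted for the adverse class so that propensity matching is nontrivial.
#'
#' @param n_normal,n_adverse Trace counts per class.
#' @param params A [sim_params()] object used for every trace.
#' @param days_range Integer range (inclusive) for days to delivery,
#'   within \[1, 7\].
#' @param seed Integer seed; the whole cohort is deterministic in it.
#' @return A list with `traces` (list of [ctg_trace()]) and `metadata`
#'   (a tibble: trace_id, label, days_to_delivery, covariates).
#' @export
#' @examples
#' coh <- simulate_cohort(3, 2, sim_params(sample_count = 240), seed = 1)
#' coh$metadata
simulate_cohort <- function(n_normal, n_adverse, params = sim_params(),
                            days_range = c(1L, 7L), seed = 1L) {
  check_number(n_normal, "n_normal", 0, Inf, integer = TRUE)
  check_number(n_adverse, "n_adverse", 0, Inf, integer = TRUE)
  if (length(days_range) != 2L || days_range[1] < 1 || days_range[2] > 7 ||
      days_range[1] > days_range[2]) {
    abort("`days_range` must be an increasing pair within [1, 7].",
          class = "ctg_parameter_error")
  }
  n <- n_normal + n_adverse
  labels <- c(rep(0L, n_normal), rep(1L, n_adverse))
  local_seed(seed, {
    days <- sample(seq(days_range[1], days_range[2]), n, replace = TRUE)
    # Label-correlated covariates: ~0.4-0.5 SD shifts for the adverse class.
    ga <- rnorm(n, 276, 8) - 4 * labels           # gestational age, days
    ma <- rnorm(n, 30, 5) + 2.5 * labels          # maternal age, years
    bmi <- rnorm(n, 26, 4) + 2 * labels
    parity <- rpois(n, 1 + 0.3 * labels)
    trace_seeds <- sample.int(2^30, n)
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      cov_i <- c(gestational_age = ga[i], maternal_age = ma[i],
                 bmi = bmi[i], parity = as.numeric(parity[i]))
      traces[[i]] <- simulate_trace(
        params, label = labels[i], seed = trace_seeds[i],
        trace_id = sprintf("trace%05d", i),
        days_to_delivery = days[i], covariates = cov_i)
    }
    metadata <- tibble::tibble(
      trace_id = vapply(traces, `[[`, "", "trace_id"),
      label = labels,
      days_to_delivery = as.integer(days),
      gestational_age = ga, maternal_age = ma, bmi = bmi,
      parity = as.numeric(parity))
    list(traces = traces, metadata = metadata)
  })
}
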