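# Stepwise insertion-event detection and conductance statistics.

#' Construct a step-event set
#'
#' @param time event times in seconds (non-decreasing).
#' @param delta_current step amplitudes in pA.
#' @param holding_voltage holding potential in mV (for pA/mV = nS conversion);
#'   may be NA if conductances are not yet assigned.
#' @param delta_conductance step conductances in nS, or NULL to leave unset.
#' @param provenance free-text description of the source trace.
#' @return object of class `step_events` (a data frame with attributes
#'   `holding_voltage` and `provenance`).
#' @export
step_events <- function(time, delta_current,
                        holding_voltage = NA_real_,
                        delta_conductance = NULL,
                        provenance = "") {
  stopifnot(length(time) == length(delta_current))
  if (length(time) > 1 && any(diff(time) < 0)) stop("event times must be non-decreasing")
  df <- data.frame(time = as.numeric(time),
                   delta_current = as.numeric(delta_current),
                   delta_conductance = if (is.null(delta_conductance))
                     rep(NA_real_, length(time)) else as.numeric(delta_conductance))
  structure(df, class = c("step_events", "data.frame"),
            holding_voltage = holding_voltage, provenance = provenance)
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> n = %d, V = %g mV\n", nrow(x),
              attr(x, "holding_voltage")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Detect stepwise insertion events in a current trace
#'
#' Two-sided moving-mean difference detector: at each sample the mean of the
#' next `window` samples minus the mean of the previous `window` samples is
#' compared against `min_step`. Contiguous supra-threshold candidates are
#' reduced to the local maximum of the statistic, candidates closer than
#' `dead_time` are merged keeping the larger, and each accepted event's
#' amplitude is re-estimated as the difference of flanking plateau means
#' (offset by a small guard region to avoid filter-smeared edges). Only
#' positive (insertion) steps are retained by default, matching persistent,
#' non-gating pores.
#'
#' @param trace a [current_trace()].
#' @param min_step detection threshold in pA; default 6 x the robust noise
#'   estimate of [estimate_noise_sd()].
#' @param window one-sided window length in samples (default 1 percent of the
#'   sampling rate, i.e. 10 ms).
#' @param dead_time minimum separation between events in seconds (default
#'   0.02).
#' @param guard samples excluded on each side of the step edge when
#'   estimating plateau means (default 5).
#' @param direction "up" (default) to keep insertions only, "both" to keep
#'   both polarities.
#' @return a [step_events()] object.
#' @export
detect_steps <- function(trace, min_step = NULL, window = NULL,
                         dead_time = 0.02, guard = 5, direction = c("up", "both")) {
  stopifnot(inherits(trace, "current_trace"))
  direction <- match.arg(direction)
  x <- trace$samples
  fs <- trace$sampling_rate
  n <- length(x)
  if (is.null(window)) window <- max(2L, round(0.01 * fs))
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2 samples")
  if (n < 2L * window) stop("trace shorter than two windows")
  if (is.null(min_step)) min_step <- 6 * estimate_noise_sd(trace)
  if (min_step <= 0) stop("min_step must be positive")

  cs <- cumsum(c(0, x))
  # stat[k] = mean(x[(k+1)..(k+w)]) - mean(x[(k-w+1)..k]) for k in w..(n-w)
  k <- window:(n - window)
  fwd <- (cs[k + window + 1] - cs[k + 1]) / window
  bwd <- (cs[k + 1] - cs[k - window + 1]) / window
  stat <- fwd - bwd
  score <- if (direction == "up") stat else abs(stat)

  pass <- score >= min_step
  if (!any(pass)) {
    return(step_events(numeric(0), numeric(0),
                       holding_voltage = trace$holding_voltage,
                       provenance = "detect_steps"))
  }
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand_idx <- vapply(runs, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(score[seg])]
  }, integer(1))
  cand_score <- score[cand_idx]
  ord <- order(cand_idx)
  cand_idx <- cand_idx[ord]; cand_score <- cand_score[ord]

  # dead-time merge keeping the largest statistic
  min_sep <- dead_time * fs
  keep <- logical(length(cand_idx))
  i <- 1L
  while (i <= length(cand_idx)) {
    grp <- i
    while (grp < length(cand_idx) &&
           cand_idx[grp + 1L] - cand_idx[grp] < min_sep) grp <- grp + 1L
    sel <- (i:grp)[which.max(cand_score[i:grp])]
    keep[sel] <- TRUE
    i <- grp + 1L
  }
  idx <- cand_idx[keep]

  # re-estimate amplitude from flanking plateau means with a guard region
  sample_idx <- idx + window - 1L  # index into x of the last pre-step sample
  amp <- vapply(sample_idx, function(s) {
    lo <- max(1L, s - guard - window + 1L):max(1L, s - guard)
    hi <- min(n, s + guard + 1L):min(n, s + guard + window)
    mean(x[hi]) - mean(x[lo])
  }, numeric(1))

  ev <- step_events(time = (sample_idx - 1L) / fs, delta_current = amp,
                    holding_voltage = trace$holding_voltage,
                    provenance = "detect_steps")
  conductance_of_events(ev)
}

#' Assign conductances to step events
#'
#' delta_conductance = delta_current / holding_voltage; with current in pA
#' and voltage in mV the ratio is in nS.
#'
#' @param events a [step_events()] object.
#' @param holding_voltage holding potential in mV; defaults to the value
#'   carried by `events`.
#' @return the event set with `delta_conductance` filled in.
#' @export
conductance_of_events <- function(events, holding_voltage = NULL) {
  stopifnot(inherits(events, "step_events"))
  v <- if (is.null(holding_voltage)) attr(events, "holding_voltage") else holding_voltage
  if (is.null(v) || is.na(v) || v == 0) stop("holding voltage must be nonzero")
  events$delta_conductance <- events$delta_current / v
  attr(events, "holding_voltage") <- v
  events
}

#' Conductance histogram and summary statistics of step events
#'
#' Bins are half-open lower-inclusive intervals [k w, (k+1) w). The median
#' uses the lower-interpolation convention (for even n, the lower of the two
#' middle order statistics), so the reported median is always an observed
#' event amplitude.
#'
#' @param events a [step_events()] with conductances assigned.
#' @param bin_width histogram bin width in nS (default 1).
#' @return list with `histogram` (data frame `bin_lower`, `bin_upper`,
#'   `count`), `median` (nS, NA with `median_defined = FALSE` for an empty
#'   set), `mean`, and `n`.
#' @export
event_statistics <- function(events, bin_width = 1) {
  stopifnot(inherits(events, "step_events"), bin_width > 0)
  g <- events$delta_conductance
  n <- length(g)
  if (n == 0L) {
    return(list(histogram = data.frame(bin_lower = numeric(0),
                                       bin_upper = numeric(0),
                                       count = integer(0)),
                median = NA_real_, median_defined = FALSE,
                mean = NA_real_, n = 0L))
  }
  bins <- floor(g / bin_width)
  tab <- table(bins)
  lower <- as.numeric(names(tab)) * bin_width
  hist_df <- data.frame(bin_lower = lower, bin_upper = lower + bin_width,
                        count = as.integer(tab))
  sorted <- sort(g)
  med <- sorted[ceiling(n / 2)]  # lower-interpolation median
  list(histogram = hist_df, median = med, median_defined = TRUE,
       mean = mean(g), n = n)
}

#' Bilayer seal check
#'
#' Verifies that an unperturbed bilayer conducts below threshold before
#' peptide addition: the mean current of a short baseline trace at each test
#' voltage is regressed on voltage and the slope (pA/mV = nS) is the leak
#' conductance estimate.
#'
#' Note the default threshold mirrors a printed figure of 0.01 pS; this is
#' far below conventional seal criteria (0.01 nS would be typical) and is
#' deliberately a configuration value, not a constant.
#'
#' @param traces list of [current_trace()] objects, one per test voltage
#'   (each trace's `holding_voltage` is used).
#' @param threshold_pS acceptance threshold on |leak conductance| in pS.
#' @return list with `conductance_nS`, `conductance_pS`, `pass`, and the
#'   per-voltage mean currents.
#' @export
seal_check <- function(traces, threshold_pS = 0.01) {
  stopifnot(is.list(traces), length(traces) >= 2L)
  v <- vapply(traces, function(tr) tr$holding_voltage, numeric(1))
  if (length(unique(v)) < 2L) stop("need at least two distinct test voltages")
  i_mean <- vapply(traces, function(tr) mean(tr$samples), numeric(1))
  fit <- stats::lm(i_mean ~ v)
  g_nS <- unname(stats::coef(fit)[2])
  list(conductance_nS = g_nS,
       conductance_pS = g_nS * 1000,
       pass = abs(g_nS * 1000) < threshold_pS,
       voltages_mV = v, mean_currents_pA = i_mean)
}

#' Final plateau conductance of a trace
#'
#' Mean current over the tail of the trace divided by the holding voltage.
#' The tail starts a short margin after `after_time` (typically the last
#' detected event) so the estimate is not biased by step edges.
#'
#' @param trace a [current_trace()].
#' @param after_time start of the plateau in seconds (default 0).
#' @param margin settling margin in seconds skipped after `after_time`.
#' @return total conductance in nS.
#' @export
final_plateau_conductance <- function(trace, after_time = 0, margin = 0.05) {
  stopifnot(inherits(trace, "current_trace"))
  if (trace$holding_voltage == 0) stop("holding voltage must be nonzero")
  n <- length(trace$samples)
  i0 <- min(n - 1L, max(1L, ceiling((after_time + margin) * trace$sampling_rate)))
  mean(trace$samples[i0:n]) / trace$holding_voltage
}
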