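# Current-trace container and low-pass Bessel filtering.

#' Construct a voltage-clamp current trace
#'
#' Uniformly sampled current time series with recording metadata. Times are
#' implicit: sample k (1-based) is at time (k - 1) / sampling_rate.
#'
#' @param samples numeric vector of current values in pA.
#' @param sampling_rate sampling rate in Hz.
#' @param holding_voltage holding potential in mV (cis relative to trans).
#' @param salt free-text salt condition (e.g. "150 mM KCl").
#' @param filter_history character vector describing filters already applied;
#'   append-only.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, holding_voltage,
                          salt = "150 mM KCl", filter_history = character()) {
  stopifnot(is.numeric(samples), length(samples) >= 2L,
            is.numeric(sampling_rate), sampling_rate > 0)
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = sampling_rate,
         holding_voltage = holding_voltage,
         salt = salt,
         filter_history = filter_history),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g Hz (%.3f s), V = %g mV, %s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$holding_voltage, x$salt))
  if (length(x$filter_history)) {
    cat("  filters:", paste(x$filter_history, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Time axis of a trace
#' @param trace a [current_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

# Reverse Bessel polynomial coefficients theta_n(s) = sum a_k s^k,
# a_k = (2n-k)! / (2^(n-k) k! (n-k)!), ascending order.
reverse_bessel_coef <- function(n) {
  k <- 0:n
  exp(lfactorial(2 * n - k) - (n - k) * log(2) - lfactorial(k) - lfactorial(n - k))
}

# Analog low-pass Bessel prototype normalized so |H(i w)| = 1/sqrt(2) at
# w = 1 (-3 dB cutoff normalization). Returns poles and gain of
# H(s) = g / prod(s - p).
bessel_prototype <- function(order) {
  a <- reverse_bessel_coef(order)
  # magnitude^2 of the delay-normalized prototype at frequency w
  mag2 <- function(w) {
    h <- a[1] / sum(a * (1i * w)^(0:order))
    Re(h * Conj(h))
  }
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-6, 10),
                       tol = 1e-12)$root
  p <- polyroot(a) / w3  # scale so the -3 dB point sits at w = 1
  g <- Re(prod(-p))      # unity DC gain
  # delay-normalized prototype has unit DC group delay; after -3 dB
  # renormalization the DC delay is w3 seconds (at unit cutoff)
  list(poles = p, gain = g, dc_delay = w3)
}

#' Digital low-pass Bessel filter
#'
#' Applies an order-n digital Bessel low-pass filter (analog prototype
#' discretized by the bilinear transform with cutoff pre-warping, so the
#' -3 dB point lands exactly on `cutoff`). The filter is run forward once and
#' the output is shifted back by the filter's low-frequency group delay, so
#' steps stay aligned in time while the single-pass magnitude response is
#' preserved.
#'
#' @param trace a [current_trace()].
#' @param cutoff -3 dB cutoff frequency in Hz (default 1000); must be below
#'   the Nyquist frequency.
#' @param order filter order (default 8).
#' @return a new `current_trace` with filtered samples and an updated
#'   `filter_history`.
#' @export
bessel_lowpass <- function(trace, cutoff = 1000, order = 8) {
  stopifnot(inherits(trace, "current_trace"))
  fs <- trace$sampling_rate
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  proto <- bessel_prototype(order)
  w_a <- 2 * fs * tan(pi * cutoff / fs)  # pre-warped analog cutoff (rad/s)
  dig <- signal::bilinear(Sz = numeric(0), Sp = proto$poles * w_a,
                          Sg = proto$gain * w_a^order, T = 1 / fs)
  arma <- signal::as.Arma(signal::Zpg(zero = dig$zero, pole = dig$pole,
                                      gain = Re(dig$gain)))
  b <- Re(arma$b); a <- Re(arma$a)
  b <- b * (sum(a) / sum(b))  # pin DC gain to exactly 1
  y <- as.numeric(signal::filter(b, a, trace$samples))
  # compensate the (approximately constant) group delay of the Bessel filter:
  # DC delay of the analog design is dc_delay / w_a seconds
  d <- round(proto$dc_delay / w_a * fs)
  if (d > 0 && d < length(y)) {
    y <- c(y[(d + 1):length(y)], rep(y[length(y)], d))
  }
  current_trace(y, fs, trace$holding_voltage, trace$salt,
                c(trace$filter_history,
                  sprintf("bessel_lowpass(cutoff=%g Hz, order=%d)", cutoff, order)))
}

#' Robust baseline-noise estimate
#'
#' Estimates the standard deviation of the baseline noise from scaled median
#' absolute deviation of first differences (dividing by sqrt(2) since
#' differencing doubles the noise variance). Insensitive to the sparse large
#' steps produced by pore insertions.
#'
#' @param trace a [current_trace()] or numeric vector.
#' @return noise standard deviation in pA.
#' @export
estimate_noise_sd <- function(trace) {
  x <- if (inherits(trace, "current_trace")) trace$samples else trace
  stats::mad(diff(x)) / sqrt(2)
}
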