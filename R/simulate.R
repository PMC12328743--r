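# Synthetic-data generators: every downstream stage of the pipeline can be
# exercised against known ground truth without any recording hardware.
# Each generator is a pure function of (parameters, seed).

#' Simulate a planar-bilayer insertion trace
#'
#' Emulates a voltage-clamp recording in which pore insertions arrive as a
#' homogeneous Poisson process, each adding a persistent conductance step
#' (pores do not gate or close), on a white-Gaussian-noise baseline:
#' I(t) = V * sum of G_k for events at or before t, plus noise.
#'
#' Defaults emulate the study conditions: a broad right-tailed (lognormal)
#' single-pore conductance distribution with median 10.8 nS, ~20 insertions
#' per minute of recording, and a noise floor keeping step signal-to-noise
#' at or above ~5.
#'
#' @param sampling_rate sampling rate in Hz (default 5000).
#' @param duration recording length in seconds (default 60).
#' @param holding_voltage holding potential in mV (default 50).
#' @param baseline_noise_sd Gaussian noise sd in pA (default 20).
#' @param insertion_rate Poisson insertion rate in events/s (default 1/3).
#' @param amplitude_model list: `distribution` = "lognormal" (parameters
#'   `median_nS`, `sdlog`) or "fixed" (parameter `value_nS`).
#' @param event_times optional explicit event times in s, overriding the
#'   Poisson draw (for constructing exact staircases).
#' @param event_conductances optional explicit conductances in nS paired with
#'   `event_times`.
#' @param seed integer seed; the generator is bit-reproducible given the seed.
#' @return list with `trace` (a [current_trace()]) and `truth` (list with
#'   `event_times`, `event_conductances`, `final_total_conductance`).
#' @export
simulate_trace <- function(sampling_rate = 5000, duration = 60,
                           holding_voltage = 50, baseline_noise_sd = 20,
                           insertion_rate = 1 / 3,
                           amplitude_model = list(distribution = "lognormal",
                                                  median_nS = 10.8, sdlog = 0.5),
                           event_times = NULL, event_conductances = NULL,
                           seed = 1) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  stopifnot(duration > 0, baseline_noise_sd >= 0, insertion_rate >= 0)
  n <- round(sampling_rate * duration)
  withr::local_seed(seed)

  if (is.null(event_times)) {
    n_ev <- stats::rpois(1, insertion_rate * duration)
    event_times <- sort(stats::runif(n_ev, 0, duration))
  } else {
    event_times <- sort(event_times)
    n_ev <- length(event_times)
  }
  if (is.null(event_conductances)) {
    event_conductances <- switch(
      amplitude_model$distribution,
      lognormal = stats::rlnorm(n_ev, meanlog = log(amplitude_model$median_nS),
                                sdlog = amplitude_model$sdlog),
      fixed = rep(amplitude_model$value_nS, n_ev),
      stop("unknown amplitude distribution: ", amplitude_model$distribution)
    )
  }
  stopifnot(length(event_conductances) == n_ev)

  t <- (seq_len(n) - 1) / sampling_rate
  g_total <- numeric(n)
  if (n_ev > 0) {
    # cumulative conductance: number of events at or before each sample time
    idx <- findInterval(t, event_times)
    csum <- c(0, cumsum(event_conductances))
    g_total <- csum[idx + 1]
  }
  current <- holding_voltage * g_total
  if (baseline_noise_sd > 0) {
    current <- current + stats::rnorm(n, 0, baseline_noise_sd)
  }
  list(
    trace = current_trace(current, sampling_rate, holding_voltage,
                          salt = "150 mM KCl",
                          filter_history = sprintf("simulate_trace(seed=%d)", seed)),
    truth = list(event_times = event_times,
                 event_conductances = event_conductances,
                 final_total_conductance = sum(event_conductances))
  )
}

#' Simulate current-voltage point sets
#'
#' Ohmic I/V points per conductance level: I = G (V - reversal) + noise.
#'
#' @param levels conductance levels in nS.
#' @param reversal reversal potential in mV (default 0: non-selective pore).
#' @param voltages test voltages in mV (default 7 points spanning +/- 50).
#' @param noise_sd Gaussian current noise sd in pA.
#' @param seed integer seed.
#' @return data frame with columns `level` (label), `conductance_nS`,
#'   `voltage_mV`, `current_pA`.
#' @export
simulate_iv <- function(levels, reversal = 0,
                        voltages = seq(-50, 50, length.out = 7),
                        noise_sd = 0, seed = 1) {
  stopifnot(length(levels) >= 1L, length(unique(voltages)) >= 2L,
            noise_sd >= 0)
  withr::local_seed(seed)
  out <- do.call(rbind, lapply(seq_along(levels), function(j) {
    i <- levels[j] * (voltages - reversal)
    if (noise_sd > 0) i <- i + stats::rnorm(length(voltages), 0, noise_sd)
    data.frame(level = sprintf("G%d", j), conductance_nS = levels[j],
               voltage_mV = voltages, current_pA = i)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a stoichiometry-vs-confidence metrics table
#'
#' Emulates a multimer-prediction scan: ipTM follows a unimodal Gaussian
#' profile over stoichiometry n centered at `peak_n`, pTM a slightly flatter
#' version of the same profile, both plus Gaussian noise and clipped to
#' [0, 1].
#'
#' @param n_range integer stoichiometries scanned.
#' @param peak_n stoichiometry at which confidence peaks (must lie in
#'   `n_range`).
#' @param peak_score peak ipTM value (default 0.38, matching the low model
#'   confidence typical of large peptide rings).
#' @param width Gaussian width of the profile in stoichiometry units.
#' @param noise_sd sd of the additive score noise.
#' @param baseline floor score far from the peak.
#' @param round_label label stored in the `round` column.
#' @param seed integer seed.
#' @return a data frame (class `multimer_metrics`) with columns `n`, `iptm`,
#'   `ptm`, `mean_plddt`, `round`.
#' @export
simulate_metrics_table <- function(n_range = 2:25, peak_n = 21,
                                   peak_score = 0.38, width = 4,
                                   noise_sd = 0, baseline = 0.1,
                                   round_label = "round1", seed = 1) {
  n_range <- as.integer(n_range)
  if (!(peak_n %in% n_range)) stop("peak_n must lie within n_range")
  stopifnot(noise_sd >= 0, width > 0)
  withr::local_seed(seed)
  prof <- baseline + (peak_score - baseline) *
    exp(-(n_range - peak_n)^2 / (2 * width^2))
  iptm <- prof
  ptm <- baseline + (prof - baseline) * 0.8 + 0.05
  plddt <- 55 + 90 * (prof - baseline)
  if (noise_sd > 0) {
    iptm <- iptm + stats::rnorm(length(n_range), 0, noise_sd)
    ptm <- ptm + stats::rnorm(length(n_range), 0, noise_sd)
    plddt <- plddt + stats::rnorm(length(n_range), 0, 100 * noise_sd)
  }
  multimer_metrics(data.frame(
    n = n_range,
    iptm = pmin(pmax(iptm, 0), 1),
    ptm = pmin(pmax(ptm, 0), 1),
    mean_plddt = pmin(pmax(plddt, 0), 100),
    round = round_label
  ))
}

#' Simulate an electrospray charge-state spectrum
#'
#' Charge ladder from [predict_charge_ladder()] plus Gaussian m/z jitter.
#'
#' @param mass neutral mass in Da.
#' @param charges charge states (default 3:6).
#' @param mz_noise_sd m/z jitter sd in Th.
#' @param proton_mass proton mass in Da.
#' @param seed integer seed.
#' @return a `charge_peaks` object.
#' @export
simulate_spectrum <- function(mass, charges = 3:6, mz_noise_sd = 0,
                              proton_mass = PROTON_MASS[["paper"]], seed = 1) {
  stopifnot(mass > 0, mz_noise_sd >= 0)
  withr::local_seed(seed)
  ladder <- predict_charge_ladder(mass, charges, proton_mass)
  if (mz_noise_sd > 0) {
    ladder$mz <- ladder$mz + stats::rnorm(nrow(ladder), 0, mz_noise_sd)
  }
  ladder
}
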