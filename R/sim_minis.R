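#' Voltage-clamp current trace
#'
#' @param samples Current samples, pA (inward negative).
#' @param sampling_rate Hz.
#' @param holding_potential mV (-70 for excitatory, 0 for inhibitory
#'   recordings).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_rate, holding_potential = -70) {
  if (!(sampling_rate > 0)) stop("sampling_rate must be > 0", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 holding_potential = holding_potential,
                 duration = length(samples) / sampling_rate),
            class = "current_trace")
}

#' Configuration of the miniature-event simulator
#'
#' Emulates a TTX voltage-clamp recording: event onsets follow a
#' homogeneous Poisson process, each event adds a biexponential kernel
#' `A * (exp(-t/decay_tau) - exp(-t/rise_tau))` rescaled so its extremum
#' equals the drawn amplitude, and Gaussian noise is added.
#'
#' @param rate Event rate, Hz.
#' @param amplitude_mean Mean peak amplitude, pA (negative = inward).
#' @param amplitude_cv Coefficient of variation of amplitudes.
#' @param rise_tau,decay_tau Kernel time constants, ms (`rise < decay`).
#' @param noise_sd Additive Gaussian noise sd, pA.
#' @param duration Recording length, s.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return An object of class `mini_sim_config`.
#' @export
mini_sim_config <- function(rate = 3, amplitude_mean = -20,
                            amplitude_cv = 0.2, rise_tau = 0.5,
                            decay_tau = 5, noise_sd = 2, duration = 120,
                            sampling_rate = 10000, seed = 1L) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (!(rise_tau > 0 && decay_tau > rise_tau)) {
    stop("need 0 < rise_tau < decay_tau", call. = FALSE)
  }
  if (!(duration > 0)) stop("duration must be > 0", call. = FALSE)
  structure(list(rate = rate, amplitude_mean = amplitude_mean,
                 amplitude_cv = amplitude_cv, rise_tau = rise_tau,
                 decay_tau = decay_tau, noise_sd = noise_sd,
                 duration = duration, sampling_rate = sampling_rate,
                 seed = as.integer(seed)),
            class = "mini_sim_config")
}

# biexponential kernel sampled at fs, normalized to extremum +1
biexp_kernel <- function(rise_tau_ms, decay_tau_ms, sampling_rate,
                         length_ms = 8 * decay_tau_ms) {
  t_ms <- seq(0, length_ms, by = 1000 / sampling_rate)
  k <- exp(-t_ms / decay_tau_ms) - exp(-t_ms / rise_tau_ms)
  k / max(k)
}

#' Simulate a miniature-current recording with known events
#'
#' @param config A [mini_sim_config()].
#' @return List with `trace` ([current_trace()]) and `events` (data frame
#'   of ground truth: onset_s, amplitude_pA).
#' @export
simulate_mepsc_trace <- function(config) {
  stopifnot(inherits(config, "mini_sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  onsets <- numeric(0)
  if (config$rate > 0) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, config$rate)
      if (t >= config$duration) break
      onsets <- c(onsets, t)
    }
  }
  amps <- stats::rnorm(length(onsets), config$amplitude_mean,
                       abs(config$amplitude_mean) * config$amplitude_cv)
  kern <- biexp_kernel(config$rise_tau, config$decay_tau, fs)
  y <- numeric(n)
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] * fs) + 1
    idx <- i0:min(i0 + length(kern) - 1, n)
    y[idx] <- y[idx] + amps[i] * kern[seq_along(idx)]
  }
  if (config$noise_sd > 0) {
    y <- y + stats::rnorm(n, 0, config$noise_sd)
  }
  list(trace = current_trace(y, fs, -70),
       events = data.frame(onset_s = onsets, amplitude_pA = amps))
}

#' Simulate a voltage-step seal test of an RC cell model
#'
#' Whole-cell response to a voltage step through an access resistance:
#' a capacitive transient of amplitude `dV/Ra` decaying with
#' `tau = Cm * (Ra * Rm / (Ra + Rm))` onto a steady state `dV/(Ra+Rm)`,
#' on top of the holding (leak) current.
#'
#' @param leak_pA Holding current before the step, pA.
#' @param ra_mohm Access (series) resistance, MOhm.
#' @param rm_mohm Membrane resistance, MOhm.
#' @param cm_pf Membrane capacitance, pF.
#' @param step_mv Step amplitude, mV.
#' @param step_start_s,step_dur_s Step onset and duration, s.
#' @param duration,sampling_rate Trace length (s) and rate (Hz).
#' @param noise_sd Gaussian noise sd, pA.
#' @param seed Integer seed.
#' @return List with `trace` ([current_trace()]), the step parameters and
#'   the ground-truth circuit values.
#' @export
simulate_seal_test <- function(leak_pA = -50, ra_mohm = 10, rm_mohm = 500,
                               cm_pf = 60, step_mv = -5,
                               step_start_s = 0.05, step_dur_s = 0.1,
                               duration = 0.2, sampling_rate = 50000,
                               noise_sd = 0, seed = 1L) {
  set.seed(as.integer(seed))
  fs <- sampling_rate
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  i_pa <- rep(leak_pA, length(t))
  in_step <- t >= step_start_s & t < step_start_s + step_dur_s
  tau_ms <- cm_pf * (ra_mohm * rm_mohm / (ra_mohm + rm_mohm)) * 1e-3
  i_ss <- 1000 * step_mv / (ra_mohm + rm_mohm)       # pA
  i_peak <- 1000 * step_mv / ra_mohm
  tp <- (t[in_step] - step_start_s) * 1000           # ms since step
  i_pa[in_step] <- leak_pA + i_ss + (i_peak - i_ss) * exp(-tp / tau_ms)
  if (noise_sd > 0) i_pa <- i_pa + stats::rnorm(length(i_pa), 0, noise_sd)
  list(trace = current_trace(i_pa, fs, -70),
       step_mv = step_mv, step_start_s = step_start_s,
       step_dur_s = step_dur_s,
       truth = list(leak_pA = leak_pA, ra_mohm = ra_mohm,
                    rm_mohm = rm_mohm, cm_pf = cm_pf, tau_ms = tau_ms))
}
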