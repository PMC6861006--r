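#' Miniature-event detection template
#'
#' Biexponential template used by the sliding scaled-template detector.
#' Defaults follow typical quantal kinetics: 0.5 ms rise / 5 ms decay for
#' excitatory (inward, at -70 mV) and 1 ms / 10 ms for inhibitory
#' (outward, at 0 mV) events; in practice templates are tuned per
#' preparation, so all parameters are configurable.
#'
#' @param rise_tau,decay_tau Time constants, ms (`rise < decay`).
#' @param length_ms Template length, ms (default `5 * decay_tau`).
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param sampling_rate Hz.
#' @return An object of class `event_template` with the sampled waveform
#'   normalized to a peak of -1 (inward) or +1 (outward).
#' @export
event_template <- function(rise_tau = 0.5, decay_tau = 5, length_ms = NULL,
                           polarity = c("inward", "outward"),
                           sampling_rate = 10000) {
  polarity <- match.arg(polarity)
  if (is.null(length_ms)) length_ms <- 5 * decay_tau
  if (!(rise_tau > 0 && decay_tau > rise_tau && length_ms > decay_tau)) {
    stop("need 0 < rise_tau < decay_tau < length_ms", call. = FALSE)
  }
  w <- biexp_kernel(rise_tau, decay_tau, sampling_rate, length_ms)
  if (polarity == "inward") w <- -w
  structure(list(samples = w, rise_tau = rise_tau, decay_tau = decay_tau,
                 length_ms = length_ms, polarity = polarity,
                 sampling_rate = sampling_rate),
            class = "event_template")
}

# linear cross-correlation sum_j y[i+j-1] w[j] for i = 1 .. n-N+1, via FFT
sliding_dot <- function(y, w) {
  n <- length(y); nw <- length(w)
  L <- stats::nextn(n + nw, 2)
  fy <- stats::fft(c(y, numeric(L - n)))
  fw <- stats::fft(c(w, numeric(L - nw)))
  full <- Re(stats::fft(fy * Conj(fw), inverse = TRUE)) / L
  full[seq_len(n - nw + 1)]
}

#' Detect miniature events by sliding scaled-template matching
#'
#' At every lag the template is optimally scaled and offset onto the
#' trace by least squares; the detection criterion is the fitted scale
#' divided by the standard error of the fit. Events are local maxima of
#' the criterion above `criterion_threshold`, separated by at least the
#' refractory interval; each event's amplitude is the fitted
#' baseline-to-peak excursion (scale times the template peak).
#'
#' @param trace A [current_trace()].
#' @param template An [event_template()] (sampling rates must match).
#' @param criterion_threshold Detection criterion threshold (default 4).
#' @param refractory_s Minimum event separation, seconds (default: the
#'   larger of template rise time + 2 ms and half the template length, so
#'   one event cannot be counted twice along its own decay).
#' @param min_amplitude_pA Minimum absolute fitted amplitude (default
#'   2 pA); guards against degenerate near-zero-residual matches on very
#'   clean baselines.
#' @return Data frame with one row per event: `onset_s`, `amplitude_pA`,
#'   `score`.
#' @export
detect_events <- function(trace, template, criterion_threshold = 4,
                          refractory_s = NULL, min_amplitude_pA = 2) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(template, "event_template"))
  if (abs(trace$sampling_rate - template$sampling_rate) > 1e-9) {
    stop("trace and template sampling rates differ", call. = FALSE)
  }
  if (is.null(refractory_s)) {
    refractory_s <- max(template$rise_tau + 2, template$length_ms / 2) / 1000
  }
  y <- trace$samples
  w <- template$samples
  n <- length(y); nw <- length(w)
  if (nw >= n) stop("template longer than trace", call. = FALSE)
  sum_w <- sum(w); sum_w2 <- sum(w * w)
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y * y))
  i <- seq_len(n - nw + 1)
  sy <- cy[i + nw] - cy[i]
  sy2 <- cy2[i + nw] - cy2[i]
  syw <- sliding_dot(y, w)
  denom <- sum_w2 - sum_w^2 / nw
  scale <- (syw - sy * sum_w / nw) / denom
  offset <- (sy - scale * sum_w) / nw
  sse <- sy2 + scale^2 * sum_w2 + nw * offset^2 -
    2 * (scale * syw + offset * sy - scale * offset * sum_w)
  sse <- pmax(sse, 0)
  crit <- scale / sqrt(sse / (nw - 1))
  crit[!is.finite(crit)] <- ifelse(scale[!is.finite(crit)] > 0, Inf, 0)
  m <- length(crit)
  peak_w <- w[which.max(abs(w))]
  is_peak <- crit > criterion_threshold &
    crit >= c(-Inf, crit[-m]) & crit >= c(crit[-1], -Inf) &
    abs(scale * peak_w) >= min_amplitude_pA
  cand <- which(is_peak)
  refr <- round(refractory_s * trace$sampling_rate)
  keep <- integer(0)
  last <- -Inf
  for (ix in cand) {
    if (ix - last >= refr) {
      keep <- c(keep, ix)
      last <- ix
    }
  }
  data.frame(onset_s = (keep - 1) / trace$sampling_rate,
             amplitude_pA = scale[keep] * peak_w,
             score = crit[keep])
}

#' Passive-property quality control from a seal-test recording
#'
#' Estimates the leak (pre-step holding) current, access and membrane
#' resistance from the capacitive transient peak and the steady-state
#' step response, the transient decay time constant by log-linear fit,
#' and the capacitance as `Cm = tau / Ra`. A cell is included when its
#' leak current is not more negative than `leak_min_pA` and its membrane
#' resistance is at least `rm_min_mohm`; if the transient fit fails, tau
#' and capacitance are returned as `NA` and inclusion is decided on the
#' available criteria.
#'
#' @param seal A list with `trace` ([current_trace()]), `step_mv`,
#'   `step_start_s`, `step_dur_s` (as returned by
#'   [simulate_seal_test()]).
#' @param leak_min_pA Exclusion bound on the leak current, pA
#'   (default -200; more negative excludes).
#' @param rm_min_mohm Minimum membrane resistance, MOhm (default 100).
#' @return An object of class `cell_qc`: `leak_pA`, `ra_mohm`,
#'   `rm_mohm`, `tau_ms`, `cm_pf`, `include`.
#' @export
qc_cell <- function(seal, leak_min_pA = -200, rm_min_mohm = 100) {
  tr <- seal$trace
  stopifnot(inherits(tr, "current_trace"))
  fs <- tr$sampling_rate
  t <- (seq_along(tr$samples) - 1) / fs
  pre <- tr$samples[t < seal$step_start_s]
  if (length(pre) < 2) stop("no pre-step samples", call. = FALSE)
  leak <- mean(pre)
  in_step <- which(t >= seal$step_start_s &
                     t < seal$step_start_s + seal$step_dur_s)
  ystep <- tr$samples[in_step]
  ns <- length(ystep)
  i_ss <- mean(ystep[floor(ns * 0.8):ns])
  ipk_idx <- which.max(abs(ystep - leak))
  i_peak <- ystep[ipk_idx]
  ra <- 1000 * seal$step_mv / (i_peak - leak)
  rtot <- 1000 * seal$step_mv / (i_ss - leak)
  rm <- rtot - ra
  # log-linear fit of the transient decay toward the steady state
  dev <- ystep - i_ss
  sgn <- sign(dev[ipk_idx])
  fitidx <- seq(ipk_idx, ns)
  ok <- which(sgn * dev[fitidx] > 0.02 * abs(dev[ipk_idx]))
  fit <- tryCatch({
    idx <- fitidx[ok]
    if (length(idx) < 5) stop("transient too short")
    tt <- (idx - ipk_idx) / fs * 1000            # ms
    co <- stats::coef(stats::lm(log(sgn * dev[idx]) ~ tt))
    tau <- -1 / co[[2]]
    if (!is.finite(tau) || tau <= 0) stop("nonpositive tau")
    tau
  }, error = function(e) NA_real_)
  tau_ms <- fit
  cm_pf <- if (is.na(tau_ms)) NA_real_ else 1000 * tau_ms / ra
  structure(list(leak_pA = leak, ra_mohm = ra, rm_mohm = rm,
                 tau_ms = tau_ms, cm_pf = cm_pf,
                 include = (leak >= leak_min_pA) && (rm >= rm_min_mohm)),
            class = "cell_qc")
}

#' Summarize detected miniature events
#'
#' @param events Data frame from [detect_events()] (or with columns
#'   `onset_s`, `amplitude_pA`).
#' @param duration Analyzed duration, seconds.
#' @return List: `frequency_hz` (= n / duration), `mean_amplitude_pA`
#'   (`NA` when no events), `n_events`, `duration_s`.
#' @export
summarize_minis <- function(events, duration) {
  if (!(duration > 0)) stop("duration must be > 0", call. = FALSE)
  n <- nrow(events)
  list(frequency_hz = n / duration,
       mean_amplitude_pA = if (n > 0) mean(events$amplitude_pA)
                           else NA_real_,
       n_events = n, duration_s = duration)
}

#' Group statistics for per-cell summaries
#'
#' Dispatches the field-standard two-group and multi-group tests:
#' pooled-variance unpaired t (`"t"`), Welch t (`"welch"`),
#' Mann-Whitney (`"mann_whitney"`), one-way ANOVA (`"anova"`) or
#' Kruskal-Wallis (`"kruskal_wallis"`).
#'
#' @param groups Named list (>= 2) of numeric vectors, each of length
#'   >= 2.
#' @param test Test name.
#' @return List: `test`, `statistic`, `p_value`, `descriptives` (group,
#'   n, mean, sem).
#' @export
compare_groups <- function(groups,
                           test = c("t", "welch", "mann_whitney", "anova",
                                    "kruskal_wallis")) {
  if (length(test) == 1 && !test %in% c("t", "welch", "mann_whitney",
                                        "anova", "kruskal_wallis")) {
    stop("unknown test name: ", test, call. = FALSE)
  }
  test <- match.arg(test)
  k <- length(groups)
  if (k < 2 || any(vapply(groups, length, integer(1)) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  if (test %in% c("t", "welch", "mann_whitney") && k != 2) {
    stop("two-sample test requires exactly 2 groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  ht <- switch(test,
    t = stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE),
    welch = stats::t.test(groups[[1]], groups[[2]]),
    mann_whitney = stats::wilcox.test(groups[[1]], groups[[2]],
                                      exact = FALSE),
    anova = stats::oneway.test(values ~ fac, var.equal = TRUE),
    kruskal_wallis = stats::kruskal.test(values, fac))
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
       descriptives = data.frame(
         group = names(groups),
         n = vapply(groups, length, integer(1)),
         mean = vapply(groups, mean, numeric(1)),
         sem = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)),
                      numeric(1))))
}
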