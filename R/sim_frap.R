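#' Acquisition schedule for a FRAP experiment
#'
#' Builds the sampling protocol of a bouton FRAP experiment: a pre-bleach
#' baseline, the bleach time, and the post-bleach recovery samples.
#'
#' The `"standard"` protocol images the baseline every 30 s for 3 min
#' (7 frames including t = 0), then records recovery every 30 s for the
#' first 3 min post-bleach and every 5 min thereafter, ending 73 min
#' (4380 s) after the bleach so that the commonly reported 68-min
#' (4080 s) timepoint falls exactly on a sample. The `"fast"` protocol
#' samples recovery every 5 s to resolve the fast exchange component.
#'
#' @param mode `"standard"` or `"fast"`.
#' @param baseline_interval Baseline frame spacing in seconds.
#' @param baseline_span Baseline duration in seconds (bleach occurs at its
#'   end).
#' @param recovery_interval_early,recovery_span_early Spacing and span (s) of
#'   the early post-bleach phase (standard mode).
#' @param recovery_interval_late,recovery_span_late Spacing (s) of the late
#'   phase and total recovery span (s) (standard mode).
#' @param fast_interval,fast_span Spacing and span (s) of recovery sampling
#'   in fast mode.
#' @return An object of class `frap_schedule` with fields `baseline_times`
#'   (absolute s, ending at the bleach), `bleach_time` (s), `recovery_times`
#'   (s post-bleach) and `mode`.
#' @examples
#' sch <- make_schedule("standard")
#' max(sch$recovery_times) / 60   # 73 min of recovery
#' @export
make_schedule <- function(mode = c("standard", "fast"),
                          baseline_interval = NULL,
                          baseline_span = NULL,
                          recovery_interval_early = 30,
                          recovery_span_early = 180,
                          recovery_interval_late = 300,
                          recovery_span_late = 4380,
                          fast_interval = 5,
                          fast_span = 300) {
  mode <- match.arg(mode)
  chk <- c(recovery_interval_early, recovery_span_early,
           recovery_interval_late, recovery_span_late,
           fast_interval, fast_span, baseline_interval, baseline_span)
  if (any(chk <= 0)) {
    stop("schedule intervals and spans must be positive", call. = FALSE)
  }
  if (mode == "standard") {
    if (is.null(baseline_interval)) baseline_interval <- 30
    if (is.null(baseline_span)) baseline_span <- 180
    baseline <- seq(0, baseline_span, by = baseline_interval)
    early <- seq(recovery_interval_early, recovery_span_early,
                 by = recovery_interval_early)
    late <- seq(recovery_span_early + recovery_interval_late,
                recovery_span_late, by = recovery_interval_late)
    recovery <- c(early, late)
  } else {
    if (is.null(baseline_interval)) baseline_interval <- 5
    if (is.null(baseline_span)) baseline_span <- 30
    baseline <- seq(0, baseline_span, by = baseline_interval)
    recovery <- seq(fast_interval, fast_span, by = fast_interval)
  }
  out <- list(baseline_times = baseline,
              bleach_time = baseline[length(baseline)],
              recovery_times = recovery,
              mode = mode)
  class(out) <- "frap_schedule"
  validate_schedule(out)
  out
}

validate_schedule <- function(s) {
  stopifnot(inherits(s, "frap_schedule"))
  if (length(s$baseline_times) == 0 || length(s$recovery_times) == 0) {
    stop("schedule needs baseline and recovery samples", call. = FALSE)
  }
  if (any(s$baseline_times < 0) || any(s$recovery_times <= 0)) {
    stop("times must be nonnegative and recovery strictly post-bleach",
         call. = FALSE)
  }
  if (any(diff(s$baseline_times) <= 0) || any(diff(s$recovery_times) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(s)
}

#' Two-component FRAP recovery model
#'
#' Parameterizes fluorescence recovery as the sum of a fast and a slow
#' exponential component, each written with a half-life: the plateau `P`
#' is the mobile fraction (asymptotic recovered fraction of the bleached
#' signal), `f` the share of the plateau carried by the fast component,
#' and `h_f < h_s` the component half-lives in seconds. The biexponential
#' form is the closed-form recovery of a bouton cluster exchanging
#' material with an effectively unbleached axonal super-pool through two
#' kinetically distinct routes.
#'
#' @param plateau Mobile fraction P in `[0, 1.05]` (small overshoot
#'   tolerated).
#' @param fast_fraction Fast-component share f in `[0, 1]`.
#' @param half_fast,half_slow Component half-lives in seconds,
#'   `0 < half_fast < half_slow`.
#' @return An object of class `recovery_model`.
#' @seealso [recovery_curve()], [tau_to_halflife()]
#' @export
recovery_model <- function(plateau = 0.7, fast_fraction = 0.4,
                           half_fast = 60, half_slow = 1200) {
  if (!is.finite(plateau) || plateau < 0 || plateau > 1.05) {
    stop("plateau must lie in [0, 1.05]", call. = FALSE)
  }
  if (!is.finite(fast_fraction) || fast_fraction < 0 || fast_fraction > 1) {
    stop("fast_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!(half_fast > 0) || !(half_slow > half_fast)) {
    stop("half-lives must satisfy 0 < half_fast < half_slow", call. = FALSE)
  }
  structure(list(plateau = plateau, fast_fraction = fast_fraction,
                 half_fast = half_fast, half_slow = half_slow),
            class = "recovery_model")
}

#' Convert an exponential time constant to a half-life
#'
#' Recovery components are parameterized by half-lives `h`; for a rate
#' description `1 - exp(-t / tau)` the equivalent half-life is
#' `h = tau * log(2)`.
#'
#' @param tau Time constant(s), seconds.
#' @return Half-life(s), seconds.
#' @export
tau_to_halflife <- function(tau) tau * log(2)

#' @rdname tau_to_halflife
#' @param h Half-life(s), seconds.
#' @export
halflife_to_tau <- function(h) h / log(2)

#' Evaluate the double-exponential recovery curve
#'
#' Computes `R(t) = P * (f * (1 - 2^(-t/h_f)) + (1 - f) * (1 - 2^(-t/h_s)))`,
#' the normalized recovery at time `t` seconds after the bleach:
#' `R(0) = 0`, `R` is nondecreasing, and `R(Inf) = P`.
#'
#' @param model A [recovery_model()].
#' @param t Times in seconds since bleach (vector, all `>= 0`).
#' @return Recovered fraction at each `t`.
#' @examples
#' m <- recovery_model(0.7, 1.0, 60, 1200)
#' recovery_curve(m, 60)  # = 0.35: one half-life of a pure fast component
#' @export
recovery_curve <- function(model, t) {
  stopifnot(inherits(model, "recovery_model"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- model$plateau; f <- model$fast_fraction
  p * (f * (1 - 2^(-t / model$half_fast)) +
         (1 - f) * (1 - 2^(-t / model$half_slow)))
}

#' Configuration of the synthetic FRAP trace generator
#'
#' @param recovery_model Ground-truth [recovery_model()].
#' @param bleach_depth Fraction of the baseline bouton signal removed by the
#'   bleach (the protocol targets 50%).
#' @param acquisition_bleach_rate Multiplicative per-acquired-frame retention
#'   factor shared by boutons and the whole-cell reference (1 = no
#'   acquisition photobleaching).
#' @param noise_sd Additive Gaussian noise, as a fraction of the baseline
#'   signal of each series.
#' @param n_boutons Number of bleached boutons per experiment (the protocol
#'   bleaches five per field).
#' @param baseline_level Mean pre-bleach integrated bouton intensity (AU).
#' @param cell_level Whole-cell reference intensity (AU).
#' @param background_level Constant per-pixel background level (AU).
#' @param seed Integer seed; the generator is a pure function of its
#'   configuration including the seed.
#' @param schedule A [make_schedule()] object.
#' @return An object of class `frap_sim_config`.
#' @export
frap_sim_config <- function(recovery_model = svpool::recovery_model(),
                            bleach_depth = 0.5,
                            acquisition_bleach_rate = 0.999,
                            noise_sd = 0.05,
                            n_boutons = 5,
                            baseline_level = 1000,
                            cell_level = 20000,
                            background_level = 50,
                            seed = 1L,
                            schedule = make_schedule("standard")) {
  if (!(bleach_depth > 0 && bleach_depth < 1)) {
    stop("bleach_depth must lie in (0, 1)", call. = FALSE)
  }
  if (!(acquisition_bleach_rate > 0 && acquisition_bleach_rate <= 1)) {
    stop("acquisition_bleach_rate must lie in (0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_boutons < 1) stop("n_boutons must be >= 1", call. = FALSE)
  stopifnot(inherits(recovery_model, "recovery_model"))
  validate_schedule(schedule)
  structure(list(recovery_model = recovery_model,
                 bleach_depth = bleach_depth,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 noise_sd = noise_sd, n_boutons = n_boutons,
                 baseline_level = baseline_level, cell_level = cell_level,
                 background_level = background_level,
                 seed = as.integer(seed), schedule = schedule),
            class = "frap_sim_config")
}

#' A per-bouton FRAP trace with its reference series
#'
#' Container pairing a bouton's raw integrated-intensity series with the
#' whole-cell reference and background series needed for photobleaching
#' correction and normalization. `background_raw` is the per-pixel mean
#' background; `bouton_area` and `cell_area` (pixels) scale it to each
#' ROI's integration area (both default to 1, i.e. background already on
#' the same scale as the ROI series).
#'
#' @param timestamps Acquisition times, seconds (absolute).
#' @param bouton_raw Integrated bouton intensity per frame.
#' @param cell_reference_raw Integrated whole-cell reference intensity.
#' @param background_raw Per-pixel mean background intensity per frame.
#' @param bleach_index Index (1-based) of the first post-bleach sample.
#' @param bouton_area,cell_area ROI areas in pixels used for background
#'   scaling.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(timestamps, bouton_raw, cell_reference_raw,
                       background_raw, bleach_index,
                       bouton_area = 1, cell_area = 1) {
  n <- length(timestamps)
  if (length(bouton_raw) != n || length(cell_reference_raw) != n ||
      length(background_raw) != n) {
    stop("all series must have the length of timestamps", call. = FALSE)
  }
  if (!(bleach_index > 1 && bleach_index <= n)) {
    stop("bleach_index must lie strictly inside the trace", call. = FALSE)
  }
  structure(list(timestamps = as.numeric(timestamps),
                 bouton_raw = as.numeric(bouton_raw),
                 cell_reference_raw = as.numeric(cell_reference_raw),
                 background_raw = as.numeric(background_raw),
                 bleach_index = as.integer(bleach_index),
                 bouton_area = bouton_area, cell_area = cell_area),
            class = "frap_trace")
}

#' Simulate FRAP traces from the two-pool exchange model
#'
#' Generates `n_boutons` raw bouton traces plus a shared whole-cell
#' reference and a constant background series. Pre-bleach frames carry the
#' baseline level; the bleach removes `bleach_depth` of it, and recovery
#' follows [recovery_curve()] with the model clock starting at the first
#' post-bleach acquisition (the laser pass and the first post-bleach frame
#' are treated as coincident). Every acquired frame multiplies bouton and
#' cell signal alike by `acquisition_bleach_rate`, so ratio correction can
#' cancel acquisition photobleaching exactly; background is constant.
#' Gaussian noise of sd `noise_sd * baseline` is added per series.
#'
#' @param config A [frap_sim_config()].
#' @return A list with `traces` (list of [frap_trace()]), the ground-truth
#'   `model`, `config`, and `bleach_factors` (the per-frame acquisition
#'   retention actually applied).
#' @export
simulate_frap_trace <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  sch <- config$schedule
  t_abs <- c(sch$baseline_times, sch$bleach_time + sch$recovery_times)
  n_pre <- length(sch$baseline_times)
  n <- length(t_abs)
  bleach_index <- n_pre + 1L
  # model clock: zero at the first post-bleach acquisition
  t_model <- c(rep(0, n_pre),
               sch$recovery_times - sch$recovery_times[1])
  rec <- recovery_curve(config$recovery_model, t_model)
  d <- config$bleach_depth
  signal_frac <- c(rep(1, n_pre), (1 - d) + d * rec[bleach_index:n])
  fade <- config$acquisition_bleach_rate^(seq_len(n) - 1)

  set.seed(config$seed)
  traces <- vector("list", config$n_boutons)
  b0 <- config$baseline_level
  cell_clean <- config$cell_level * fade
  bg <- rep(config$background_level, n)
  for (i in seq_len(config$n_boutons)) {
    bouton <- b0 * signal_frac * fade +
      stats::rnorm(n, 0, config$noise_sd * b0)
    cell <- cell_clean + stats::rnorm(n, 0, config$noise_sd * config$cell_level)
    traces[[i]] <- frap_trace(t_abs, bouton + bg, cell + bg, bg, bleach_index)
  }
  list(traces = traces, model = config$recovery_model, config = config,
       bleach_factors = fade)
}

#' Simulate normalized FRAP traces with independent residual noise
#'
#' Draws traces directly on the normalized scale: pre-bleach samples at 1
#' and post-bleach samples at `recovery_curve(model, t) + e` with iid
#' Gaussian `e`. This is the generating model under which least-squares
#' recovery fitting and the extra sum-of-squares F test are exactly
#' calibrated, and is therefore the generator used for fit-calibration
#' and power studies. (Running raw traces through [normalize_trace()]
#' instead anchors every trace to its own noisy first post-bleach sample,
#' which correlates residuals within a trace - see the methods vignette.)
#'
#' @param model Ground-truth [recovery_model()].
#' @param n_traces Number of traces.
#' @param noise_sd Residual sd on the normalized scale.
#' @param schedule A [make_schedule()] object.
#' @param seed Integer seed.
#' @return List of `normalized_frap_trace` objects (all `qc_pass = TRUE`).
#' @export
simulate_normalized_traces <- function(model, n_traces = 20,
                                       noise_sd = 0.05,
                                       schedule = make_schedule("standard"),
                                       seed = 1L) {
  stopifnot(inherits(model, "recovery_model"))
  validate_schedule(schedule)
  set.seed(as.integer(seed))
  t_abs <- c(schedule$baseline_times,
             schedule$bleach_time + schedule$recovery_times)
  n_pre <- length(schedule$baseline_times)
  bi <- n_pre + 1L
  t_model <- c(rep(0, n_pre), schedule$recovery_times -
                 schedule$recovery_times[1])
  rec <- recovery_curve(model, t_model)
  lapply(seq_len(n_traces), function(i) {
    v <- c(rep(1, n_pre), rec[bi:length(rec)] +
             stats::rnorm(length(rec) - n_pre, 0, noise_sd))
    structure(list(timestamps_post = t_abs - t_abs[bi],
                   time_since_bleach = t_abs - t_abs[bi - 1L],
                   values = v, bleach_index = bi,
                   photobleach_fraction = 0, qc_pass = TRUE),
              class = "normalized_frap_trace")
  })
}
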