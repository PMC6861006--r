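#' Background-subtract, bleach-correct and full-scale normalize a FRAP trace
#'
#' The processing chain of bouton FRAP quantification:
#' 1. subtract the (area-scaled) background from the bouton and whole-cell
#'    series;
#' 2. divide the bouton by the cell reference rescaled to its own
#'    pre-bleach mean (ratio photobleaching correction - acquisition
#'    bleaching shared multiplicatively by bouton and cell cancels
#'    exactly);
#' 3. full-scale normalize so the pre-bleach mean is 1 and the first
#'    post-bleach sample is 0:
#'    `v(t) = (F(t) - F_post0) / (F_pre - F_post0)`.
#'
#' The photobleach fraction (signal the cell reference lost over the
#' experiment) is recorded for quality control.
#'
#' @param trace A [frap_trace()].
#' @param qc_threshold Maximum tolerated photobleach fraction (see
#'   [qc_photobleaching()]).
#' @param edge_n Number of leading/trailing cell-reference samples
#'   averaged when computing the photobleach fraction.
#' @return An object of class `normalized_frap_trace` with fields
#'   `timestamps_post` (s, zero at the first post-bleach sample, pre-bleach
#'   samples negative), `time_since_bleach` (s, zero at the bleach),
#'   `values`, `bleach_index`, `photobleach_fraction` and `qc_pass`.
#' @export
normalize_trace <- function(trace, qc_threshold = 0.60, edge_n = 3) {
  stopifnot(inherits(trace, "frap_trace"))
  n <- length(trace$timestamps)
  bi <- trace$bleach_index
  b <- trace$bouton_raw - trace$background_raw * trace$bouton_area
  cc <- trace$cell_reference_raw - trace$background_raw * trace$cell_area
  if (any(cc <= 0)) {
    stop("photobleaching correction failed: nonpositive corrected cell ",
         "reference", call. = FALSE)
  }
  pre <- seq_len(bi - 1)
  corr <- b / (cc / mean(cc[pre]))
  f_pre <- mean(corr[pre])
  f0 <- corr[bi]
  if (!(f_pre > f0)) {
    stop("degenerate bleach: pre-bleach mean does not exceed the first ",
         "post-bleach value", call. = FALSE)
  }
  v <- (corr - f0) / (f_pre - f0)
  k <- min(edge_n, n)
  pb <- 1 - mean(cc[(n - k + 1):n]) / mean(cc[seq_len(k)])
  # bleach happens between the last baseline frame and the first recovery
  # frame; both clocks are kept (model fitting uses the first-sample origin)
  out <- structure(
    list(timestamps_post = trace$timestamps - trace$timestamps[bi],
         time_since_bleach = trace$timestamps - trace$timestamps[bi - 1],
         values = v, bleach_index = bi, photobleach_fraction = pb,
         qc_pass = NA),
    class = "normalized_frap_trace")
  out$qc_pass <- qc_photobleaching(out, qc_threshold)
  out
}

#' Photobleaching quality control
#'
#' Experiments whose whole-cell reference lost more than the threshold
#' fraction of its signal (default 60%, a phototoxicity risk) are
#' discarded; exactly at the threshold passes.
#'
#' @param ntrace A [normalize_trace()] result (or anything with a
#'   `photobleach_fraction` field).
#' @param threshold Maximum tolerated fraction lost (default 0.60).
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
qc_photobleaching <- function(ntrace, threshold = 0.60) {
  ntrace$photobleach_fraction <= threshold
}

# post-bleach (t, v) points of one normalized trace, model clock
post_points <- function(ntrace) {
  idx <- ntrace$bleach_index:length(ntrace$values)
  data.frame(t = ntrace$timestamps_post[idx], v = ntrace$values[idx])
}

pool_points <- function(traces, mode) {
  pts <- do.call(rbind, lapply(traces, post_points))
  if (mode == "averaged") {
    key <- round(pts$t, 6)
    agg <- stats::aggregate(pts$v, list(t = key), mean)
    pts <- data.frame(t = agg$t, v = agg$x)
  }
  pts[order(pts$t), ]
}

# profiled residual sum of squares: given the two half-lives, the two
# component amplitudes enter linearly and are solved exactly (nonnegative)
biexp_profile_ss <- function(lh, t, v) {
  h1 <- exp(lh[1]); h2 <- exp(lh[2])
  g1 <- 1 - 2^(-t / h1)
  g2 <- 1 - 2^(-t / h2)
  a11 <- sum(g1 * g1); a12 <- sum(g1 * g2); a22 <- sum(g2 * g2)
  b1 <- sum(g1 * v); b2 <- sum(g2 * v)
  det <- a11 * a22 - a12 * a12
  if (abs(det) > 1e-12 * max(a11 * a22, 1e-300)) {
    a <- (b1 * a22 - b2 * a12) / det
    b <- (b2 * a11 - b1 * a12) / det
  } else {
    a <- if (a11 > 0) b1 / a11 else 0
    b <- 0
  }
  if (a < 0 || b < 0) {
    # active nonnegativity constraint: best single-component solutions
    a1 <- if (a11 > 0) max(b1 / a11, 0) else 0
    b1s <- if (a22 > 0) max(b2 / a22, 0) else 0
    ss_a <- sum((v - a1 * g1)^2)
    ss_b <- sum((v - b1s * g2)^2)
    if (ss_a <= ss_b) { a <- a1; b <- 0 } else { a <- 0; b <- b1s }
  }
  list(ss = sum((v - a * g1 - b * g2)^2), a = a, b = b)
}

default_halflife_starts <- function() {
  rbind(c(10, 300), c(30, 600), c(60, 1200), c(120, 3000),
        c(5, 100), c(30, 5000), c(200, 4000), c(60, 300))
}

#' Fit the double-exponential recovery model to normalized FRAP traces
#'
#' Nonlinear least squares of
#' `R(t) = P * (f * (1 - 2^(-t/h_f)) + (1 - f) * (1 - 2^(-t/h_s)))`
#' on the post-bleach samples. The search is by variable projection: the
#' two component amplitudes are profiled out exactly (linear, constrained
#' nonnegative) and the two half-lives optimized on the log scale by
#' Nelder-Mead from multiple starts; ties break by lowest SS then lowest
#' fast half-life. Pooled mode (default) fits all per-trace points, giving
#' well-defined residual degrees of freedom; averaged mode fits the mean
#' trace, mirroring the classical protocol of fitting the average of all
#' normalized traces.
#'
#' @param traces List of [normalize_trace()] results (QC failures are
#'   dropped), or a single one.
#' @param mode `"pooled"` or `"averaged"`.
#' @param h_bounds Half-life search box, seconds.
#' @param extra_starts Optional matrix of additional `(h_f, h_s)` starts.
#' @param keep_qc_failures Keep traces with `qc_pass == FALSE`.
#' @return An object of class `double_exp_fit`: `plateau`,
#'   `fast_fraction`, `half_fast`, `half_slow`, `residual_ss`, `n_points`,
#'   `n_params` (= 4), `se` (approximate parameter standard errors),
#'   `flags` (e.g. a vanishing component leaving the other half-life
#'   unidentifiable), `mode` and the fitted `points`.
#' @export
fit_double_exponential <- function(traces, mode = c("pooled", "averaged"),
                                   h_bounds = c(1, 1e5),
                                   extra_starts = NULL,
                                   keep_qc_failures = FALSE) {
  mode <- match.arg(mode)
  if (inherits(traces, "normalized_frap_trace")) traces <- list(traces)
  if (!keep_qc_failures) {
    traces <- Filter(function(x) isTRUE(x$qc_pass), traces)
  }
  if (length(traces) == 0) {
    stop("no QC-passing traces to fit", call. = FALSE)
  }
  pts <- pool_points(traces, mode)
  if (sum(pts$t > 0) < 5) {
    stop("need at least 5 post-bleach samples", call. = FALSE)
  }
  t <- pts$t; v <- pts$v
  lb <- log(h_bounds[1]); ub <- log(h_bounds[2])
  starts <- default_halflife_starts()
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fn <- function(lh) {
      lh <- pmin(pmax(lh, lb), ub)
      biexp_profile_ss(lh, t, v)$ss
    }
    opt <- tryCatch(
      stats::optim(log(starts[i, ]), fn, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 3000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    lh <- pmin(pmax(opt$par, lb), ub)
    sol <- biexp_profile_ss(lh, t, v)
    cand <- list(lh = lh, ss = sol$ss, a = sol$a, b = sol$b)
    if (is.null(best) || cand$ss < best$ss - 1e-15 ||
        (abs(cand$ss - best$ss) <= 1e-15 &&
         min(exp(cand$lh)) < min(exp(best$lh)))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("double-exponential fit failed to converge from all starts (",
         nrow(starts), " starts, ", length(t), " points)", call. = FALSE)
  }
  h <- exp(best$lh); amp <- c(best$a, best$b)
  ord <- order(h)
  h <- h[ord]; amp <- amp[ord]
  p <- amp[1] + amp[2]
  f <- if (p > 0) amp[1] / p else NA_real_
  flags <- character(0)
  if (is.na(f) || f > 0.99) {
    flags <- c(flags, "slow component vanishes: half_slow unidentifiable")
  }
  if (!is.na(f) && f < 0.01) {
    flags <- c(flags, "fast component vanishes: half_fast unidentifiable")
  }
  if (any(abs(log(h) - lb) < 1e-6) || any(abs(log(h) - ub) < 1e-6)) {
    flags <- c(flags, "half-life at search bound")
  }
  se <- biexp_param_se(p, f, h[1], h[2], t, v, best$ss)
  structure(list(plateau = p, fast_fraction = f, half_fast = h[1],
                 half_slow = h[2], residual_ss = best$ss,
                 n_points = length(t), n_params = 4L, se = se,
                 flags = flags, mode = mode, points = pts),
            class = "double_exp_fit")
}

# asymptotic standard errors from the residual Jacobian at the optimum
biexp_param_se <- function(p, f, hf, hs, t, v, ss) {
  se <- c(plateau = NA_real_, fast_fraction = NA_real_,
          half_fast = NA_real_, half_slow = NA_real_)
  n <- length(t)
  if (n <= 4 || is.na(f)) return(se)
  gf <- 1 - 2^(-t / hf); gs <- 1 - 2^(-t / hs)
  dgf <- -2^(-t / hf) * t * log(2) / hf^2
  dgs <- -2^(-t / hs) * t * log(2) / hs^2
  jac <- cbind(f * gf + (1 - f) * gs, p * (gf - gs), p * f * dgf,
               p * (1 - f) * dgs)
  jtj <- crossprod(jac)
  cov <- tryCatch(solve(jtj) * ss / (n - 4), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  se
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf(paste0("double-exponential FRAP fit (%s, %d points)\n",
                     "  plateau (mobile fraction) = %.4f\n",
                     "  fast fraction             = %.4f\n",
                     "  half-lives                = %.4g s / %.4g s\n",
                     "  residual SS               = %.6g\n"),
              x$mode, x$n_points, x$plateau, x$fast_fraction,
              x$half_fast, x$half_slow, x$residual_ss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate a fitted double-exponential recovery at given times
#'
#' @param fit A `double_exp_fit`.
#' @param t Seconds since the post-bleach time origin.
#' @return Fitted recovery values.
#' @export
predict_double_exp <- function(fit, t) {
  recovery_curve(recovery_model(min(fit$plateau, 1.05), fit$fast_fraction,
                                fit$half_fast, fit$half_slow), t)
}

#' Extra sum-of-squares F test for divergence of FRAP recovery curves
#'
#' Fits one shared double-exponential model to the pooled points of all
#' groups and separate models per group, and asks whether the separate
#' fits reduce the residual sum of squares enough - relative to the extra
#' parameters spent - to reject the shared model:
#' `F = ((ss_shared - ss_separate) / (df_shared - df_separate)) /
#'      (ss_separate / df_separate)`
#' with `df_shared = N - 4` and `df_separate = N - 4k` for `k` groups.
#' Each per-group fit is seeded with the shared solution as an extra
#' start, which guarantees the nesting `ss_shared >= ss_separate`.
#'
#' @param groups Named list (>= 2) of lists of [normalize_trace()] results.
#' @param mode Fit mode, as in [fit_double_exponential()].
#' @param alpha Significance level for the verdict.
#' @return An object of class `f_test_result`: `f_ratio`, `df_num`,
#'   `df_den`, `p_value`, `ss_shared`, `ss_separate`, `verdict`
#'   (`"shared"` or `"divergent"`), and the per-group and shared fits.
#' @export
extra_ss_f_test <- function(groups, mode = c("pooled", "averaged"),
                            alpha = 0.05) {
  mode <- match.arg(mode)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  shared_fit <- fit_double_exponential(unlist(groups, recursive = FALSE),
                                       mode = mode)
  seed_start <- matrix(c(shared_fit$half_fast, shared_fit$half_slow), 1)
  fits <- lapply(groups, fit_double_exponential, mode = mode,
                 extra_starts = seed_start)
  ss_shared <- shared_fit$residual_ss
  ss_separate <- sum(vapply(fits, `[[`, numeric(1), "residual_ss"))
  n_tot <- sum(vapply(fits, `[[`, numeric(1), "n_points"))
  df_shared <- n_tot - 4
  df_separate <- n_tot - 4 * k
  if (df_separate <= 0) stop("too few points for separate fits",
                             call. = FALSE)
  if (ss_separate <= 0 && ss_shared > 0) {
    f_ratio <- Inf; p <- 0
  } else if (ss_separate <= 0) {
    f_ratio <- 0; p <- 1
  } else {
    f_ratio <- ((ss_shared - ss_separate) / (df_shared - df_separate)) /
      (ss_separate / df_separate)
    f_ratio <- max(f_ratio, 0)
    p <- stats::pf(f_ratio, df_shared - df_separate, df_separate,
                   lower.tail = FALSE)
  }
  structure(list(f_ratio = f_ratio, df_num = df_shared - df_separate,
                 df_den = df_separate, p_value = p, ss_shared = ss_shared,
                 ss_separate = ss_separate,
                 verdict = if (p < alpha) "divergent" else "shared",
                 alpha = alpha, shared_fit = shared_fit, group_fits = fits),
            class = "f_test_result")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf(paste0("extra sum-of-squares F test (%d groups)\n",
                     "  F(%d, %d) = %.4g, p = %.4g -> %s\n",
                     "  SS shared = %.6g, SS separate = %.6g\n"),
              length(x$group_fits), x$df_num, x$df_den, x$f_ratio,
              x$p_value, x$verdict, x$ss_shared, x$ss_separate))
  invisible(x)
}

#' Compare recovery between groups at a fixed post-bleach timepoint
#'
#' Reads each trace's normalized recovery at the post-bleach sample
#' nearest the query time (default 4080 s = 68 min, a sample of the
#' standard schedule) and compares groups with an unpaired t or
#' Mann-Whitney test; with more than two groups each is tested against
#' the reference group.
#'
#' @param groups Named list (>= 2) of lists of [normalize_trace()] results.
#' @param query_time Seconds since the bleach (default 4080 = 68 min).
#' @param test `"t"` (pooled-variance unpaired) or `"mann_whitney"`.
#' @param reference Index or name of the reference group (default 1).
#' @return An object of class `timepoint_comparison`: `query_time`,
#'   `group_values`, per-group `summary` (n, mean, sem), and for two
#'   groups `statistic`/`p_value` (otherwise one row per comparison in
#'   `comparisons`).
#' @export
recovery_at_timepoint <- function(groups, query_time = 4080,
                                  test = c("t", "mann_whitney"),
                                  reference = 1) {
  test <- match.arg(test)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  value_at <- function(ntr) {
    idx <- ntr$bleach_index:length(ntr$values)
    tt <- ntr$time_since_bleach[idx]
    j <- which.min(abs(tt - query_time))
    gap <- stats::median(diff(sort(unique(tt))))
    if (abs(tt[j] - query_time) > gap / 2 + 1e-9) {
      stop("missing timepoint: no sample within half an inter-sample ",
           "interval of ", query_time, " s", call. = FALSE)
    }
    ntr$values[idx][j]
  }
  vals <- lapply(groups, function(g) vapply(g, value_at, numeric(1)))
  if (any(vapply(vals, length, integer(1)) < 2)) {
    stop("each group needs >= 2 traces", call. = FALSE)
  }
  summ <- data.frame(group = names(vals),
                     n = vapply(vals, length, integer(1)),
                     mean = vapply(vals, mean, numeric(1)),
                     sem = vapply(vals, function(x) {
                       stats::sd(x) / sqrt(length(x))
                     }, numeric(1)))
  run_test <- function(x, y) {
    if (test == "t") {
      ht <- stats::t.test(x, y, var.equal = TRUE)
    } else {
      ht <- stats::wilcox.test(x, y, exact = FALSE)
    }
    c(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  out <- list(query_time = query_time, test = test, group_values = vals,
              summary = summ)
  if (k == 2) {
    r <- run_test(vals[[1]], vals[[2]])
    out$statistic <- r[["statistic"]]; out$p_value <- r[["p_value"]]
  } else {
    ref <- if (is.character(reference)) which(names(vals) == reference)
           else reference
    others <- setdiff(seq_len(k), ref)
    cmp <- t(vapply(others, function(i) run_test(vals[[ref]], vals[[i]]),
                    numeric(2)))
    out$comparisons <- data.frame(group = names(vals)[others],
                                  statistic = cmp[, 1], p_value = cmp[, 2])
  }
  class(out) <- "timepoint_comparison"
  out
}
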