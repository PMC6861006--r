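test_that("normalization anchors pre-bleach mean at 1 and bleach sample at 0", {
  cfg <- frap_sim_config(noise_sd = 0.05, n_boutons = 4, seed = 21)
  for (tr in simulate_frap_trace(cfg)$traces) {
    nt <- normalize_trace(tr)
    pre <- seq_len(nt$bleach_index - 1)
    expect_equal(mean(nt$values[pre]), 1, tolerance = 1e-9)
    expect_identical(nt$values[nt$bleach_index], 0)
  }
})

test_that("normalization errors on degenerate inputs", {
  # constant bouton and cell: no bleach happened
  flat <- frap_trace(0:9, rep(5, 10), rep(50, 10), rep(0, 10), 6)
  expect_error(normalize_trace(flat), "degenerate bleach")
  # nonpositive corrected cell reference
  bad <- frap_trace(0:9, c(rep(5, 5), rep(2, 5)), rep(1, 10), rep(2, 10), 6)
  expect_error(normalize_trace(bad), "nonpositive corrected cell")
})

test_that("normalizing an already-normalized trace is the identity", {
  nt <- pipeline_group(0.7, 1, 31, noise_sd = 0.03)[[1]]
  again <- normalize_trace(frap_trace(
    nt$time_since_bleach - nt$time_since_bleach[1], nt$values,
    rep(1, length(nt$values)), rep(0, length(nt$values)),
    nt$bleach_index))
  expect_equal(again$values, nt$values, tolerance = 1e-12)
})

test_that("photobleaching QC discards only above-threshold loss", {
  mk <- function(pb) structure(list(photobleach_fraction = pb),
                               class = "normalized_frap_trace")
  expect_false(qc_photobleaching(mk(0.65)))
  expect_true(qc_photobleaching(mk(0)))
  expect_true(qc_photobleaching(mk(0.60)))   # 'exceeded' read strictly
  expect_false(qc_photobleaching(mk(0.60001)))
})

test_that("photobleach fraction reflects cell-reference signal loss", {
  cfg <- frap_sim_config(noise_sd = 0, acquisition_bleach_rate = 0.95,
                         n_boutons = 1, seed = 1)
  tr <- simulate_frap_trace(cfg)$traces[[1]]
  nt <- normalize_trace(tr)
  nf <- length(tr$timestamps)
  # ratio of trailing to leading geometric means collapses to rate^(nf-3)
  expect_equal(nt$photobleach_fraction, 1 - 0.95^(nf - 3),
               tolerance = 1e-9)
  expect_false(nt$qc_pass)   # ~68% of the reference signal was lost
})

test_that("noiseless double-exponential fit recovers parameters to 1e-6", {
  nt <- simulate_normalized_traces(recovery_model(0.7, 0.4, 60, 1200),
                                   1, 0, seed = 1)
  fit <- fit_double_exponential(nt)
  expect_equal(fit$plateau, 0.7, tolerance = 1e-6)
  expect_equal(fit$fast_fraction, 0.4, tolerance = 1e-6)
  expect_equal(fit$half_fast, 60, tolerance = 1e-6 * 60)
  expect_equal(fit$half_slow, 1200, tolerance = 1e-6 * 1200)
  expect_lt(fit$residual_ss, 1e-12)
  expect_equal(fit$n_params, 4L)
})

test_that("single-exponential data collapses the fit and is flagged", {
  # one component carries the whole plateau; the other is unidentifiable
  nt <- simulate_normalized_traces(recovery_model(0.6, 1, 120, 3000),
                                   1, 0, seed = 1)
  fit <- fit_double_exponential(nt)
  expect_equal(fit$plateau, 0.6, tolerance = 1e-4)
  dominant <- if (fit$fast_fraction > 0.5) fit$half_fast else fit$half_slow
  expect_equal(dominant, 120, tolerance = 1e-3)
  expect_true(length(fit$flags) > 0)
})

test_that("fit requires enough post-bleach samples and QC-passing traces", {
  nt <- simulate_normalized_traces(recovery_model(), 2, 0.05, seed = 3)
  nt[[1]]$qc_pass <- FALSE
  nt[[2]]$qc_pass <- FALSE
  expect_error(fit_double_exponential(nt), "QC-passing")
  short <- nt[[1]]
  keep <- 1:(short$bleach_index + 3)
  short <- structure(list(timestamps_post = short$timestamps_post[keep],
                          time_since_bleach = short$time_since_bleach[keep],
                          values = short$values[keep],
                          bleach_index = short$bleach_index,
                          photobleach_fraction = 0, qc_pass = TRUE),
                     class = "normalized_frap_trace")
  expect_error(fit_double_exponential(list(short)), "at least 5")
})

test_that("fitted SS beats a coarse 4-parameter grid search", {
  for (seed in c(51, 52)) {
    nt <- simulate_normalized_traces(recovery_model(0.65, 0.35, 80, 1500),
                                     5, 0.08, seed = seed)
    fit <- fit_double_exponential(nt, mode = "averaged")
    pts <- fit$points
    hgrid <- exp(seq(log(1), log(1e5), length.out = 20))
    best <- Inf
    for (hf in hgrid) for (hs in hgrid) {
      if (hf >= hs) next
      for (p in seq(0, 1.2, length.out = 20)) {
        for (f in seq(0, 1, length.out = 20)) {
          ss <- biexp_ss_direct(p, f, hf, hs, pts$t, pts$v)
          if (ss < best) best <- ss
        }
      }
    }
    expect_lte(fit$residual_ss, best + 1e-12)
  }
})

test_that("averaged and pooled modes agree on balanced noiseless data", {
  nt <- simulate_normalized_traces(recovery_model(0.7, 0.4, 60, 1200),
                                   4, 0, seed = 2)
  fp <- fit_double_exponential(nt, mode = "pooled")
  fa <- fit_double_exponential(nt, mode = "averaged")
  expect_equal(fp$plateau, fa$plateau, tolerance = 1e-6)
  expect_equal(fp$n_points, 4 * fa$n_points)
})

test_that("identical noiseless groups give F = 0 and p = 1", {
  g <- simulate_normalized_traces(recovery_model(0.7, 0.4, 60, 1200),
                                  3, 0, seed = 5)
  ft <- extra_ss_f_test(list(a = g, b = g))
  expect_equal(ft$f_ratio, 0)
  expect_equal(ft$p_value, 1)
  expect_equal(ft$ss_shared, ft$ss_separate, tolerance = 1e-12)
  expect_equal(ft$verdict, "shared")
})

test_that("duplicated noisy groups stay under the shared model", {
  g <- norm_group(0.7, 10, 71, noise_sd = 0.08)
  ft <- extra_ss_f_test(list(a = g, b = g))
  expect_lte(ft$ss_separate, ft$ss_shared + 1e-12)
  expect_lt(ft$f_ratio, 1e-6)
  expect_gt(ft$p_value, 0.999)
})

test_that("F-test nesting and scale invariance hold on random groups", {
  for (seed in c(81, 82, 83)) {
    g1 <- norm_group(0.73, 8, seed, noise_sd = 0.08)
    g2 <- norm_group(0.60, 8, seed + 500, noise_sd = 0.08)
    ft <- extra_ss_f_test(list(a = g1, b = g2))
    expect_gte(ft$ss_shared, ft$ss_separate - 1e-12)
    expect_equal(ft$df_num, 4)
    expect_equal(ft$df_den, ft$shared_fit$n_points - 8)
    # common multiplicative rescaling leaves F unchanged
    resc <- function(g, k) lapply(g, function(x) {
      x$values <- k * x$values
      x
    })
    ft2 <- extra_ss_f_test(list(a = resc(g1, 3.7), b = resc(g2, 3.7)))
    expect_equal(ft2$f_ratio, ft$f_ratio, tolerance = 1e-4)
  }
})

test_that("F-test power grows with the plateau separation", {
  power_at <- function(dp, reps = 25) {
    mean(vapply(seq_len(reps), function(r) {
      g1 <- norm_group(0.6, 10, 2000 + 2 * r, noise_sd = 0.1)
      g2 <- norm_group(0.6 + dp, 10, 2001 + 2 * r, noise_sd = 0.1)
      extra_ss_f_test(list(a = g1, b = g2))$p_value < 0.05
    }, logical(1)))
  }
  p <- c(power_at(0.02), power_at(0.10), power_at(0.30))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.9)
})

test_that("timepoint comparison reads the 68-min sample exactly", {
  g1 <- norm_group(0.73, 10, 91)
  g2 <- norm_group(0.53, 10, 92)
  tp <- recovery_at_timepoint(list(a = g1, b = g2), query_time = 4080)
  # group means near the model value at the 68-min sample
  m1 <- recovery_curve(recovery_model(0.73, 0.4, 60, 1200), 4080 - 30)
  expect_lt(abs(tp$summary$mean[1] - m1), 2 * tp$summary$sem[1] + 0.02)
  expect_lt(tp$p_value, 0.01)
  # identical groups: exchangeable null
  tpn <- recovery_at_timepoint(list(a = g1, b = g1))
  expect_gt(tpn$p_value, 0.99)
  # off-grid query errors
  expect_error(recovery_at_timepoint(list(a = g1, b = g2),
                                     query_time = 4600),
               "missing timepoint")
})

test_that("timepoint comparison with >2 groups tests each against reference", {
  g1 <- norm_group(0.73, 8, 93)
  g2 <- norm_group(0.53, 8, 94)
  g3 <- norm_group(0.73, 8, 95)
  tp <- recovery_at_timepoint(list(wt = g1, mut = g2, resc = g3),
                              test = "mann_whitney")
  expect_equal(nrow(tp$comparisons), 2)
  expect_lt(tp$comparisons$p_value[tp$comparisons$group == "mut"], 0.05)
})
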