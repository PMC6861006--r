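test_that("a static spot draws a constant-position vertical ridge", {
  mc <- movie_config(punctum_speeds_um_s = numeric(0),
                     punctum_starts_um = numeric(0),
                     punctum_amplitudes = numeric(0),
                     bouton_positions_um = 20, noise_sd = 0, duration = 5)
  mv <- render_axon_timelapse(mc)
  ky <- build_kymograph(mv$stack, mc$axon_path)
  peaks <- apply(ky$data, 1, which.max)
  expect_equal(length(unique(peaks)), 1)
  expect_equal((unique(peaks) - 1) * ky$pixel_size, 20, tolerance = 0.5)
})

test_that("an empty stack yields an all-zero kymograph", {
  st <- image_stack(array(0, c(5, 32, 64)), 0:4, 0.2)
  ky <- build_kymograph(st, rbind(c(16, 4), c(16, 60)))
  expect_true(all(ky$data == 0))
  expect_equal(nrow(ky$data), 5)
})

test_that("kymograph geometry validates its inputs", {
  st <- image_stack(array(1, c(3, 16, 16)), 0:2, 0.2)
  expect_error(build_kymograph(st, rbind(c(8, 1), c(8, 40))), "outside")
  expect_error(build_kymograph(st, rbind(c(8, 4), c(8, 12)), width_px = 0),
               "width_px")
})

test_that("track speed is the segmental mean with pauses included", {
  expect_equal(track_speed(track(c(0, 1, 2), c(0, 1.2, 2.4))), 1.2)
  # 2.0 and 1.0 um/s segments of equal duration average to 1.5
  expect_equal(track_speed(track(c(0, 1, 2), c(0, 2, 3))), 1.5)
  # a pause contributes a zero-speed segment
  expect_equal(track_speed(track(c(0, 1, 2), c(0, 0, 3))), 1.5)
  expect_error(track(c(0, 0, 1), c(0, 1, 2)), "strictly increasing")
})

test_that("track speed is unsigned and reversal-invariant", {
  set.seed(7)
  for (i in 1:20) {
    tt <- cumsum(runif(6, 0.1, 1))
    pos <- cumsum(rnorm(6))
    fwd <- track(tt, pos)
    rev_tr <- track(tt, -pos)
    expect_equal(track_speed(fwd), track_speed(rev_tr))
  }
})

test_that("auto-tracing recovers a single punctum to pixel accuracy", {
  mc <- movie_config(punctum_speeds_um_s = 1.2, punctum_starts_um = 8,
                     noise_sd = 0, bouton_positions_um = numeric(0))
  mv <- render_axon_timelapse(mc)
  ky <- build_kymograph(mv$stack, mc$axon_path)
  trks <- detect_tracks(ky, min_frames = 20)
  expect_length(trks, 1)
  tr <- trks[[1]]
  # endpoints within 1 px of the ground-truth path offset
  t0 <- tr$times[1]; t1 <- tr$times[length(tr$times)]
  expect_lt(abs(tr$positions_um[1] - (8 + 1.2 * t0)), 1 * 0.2 + 0.05)
  expect_lt(abs(tr$positions_um[length(tr$times)] - (8 + 1.2 * t1)),
            1 * 0.2 + 0.05)
})

test_that("a blank kymograph yields no tracks", {
  ky <- build_kymograph(image_stack(array(0, c(6, 32, 64)), 0:5, 0.2),
                        rbind(c(16, 4), c(16, 60)))
  expect_length(detect_tracks(ky), 0)
})

test_that("two non-crossing puncta give two tracks with correct directions", {
  mc <- movie_config(punctum_speeds_um_s = c(1.0, -1.0),
                     punctum_starts_um = c(2, 46), duration = 15,
                     noise_sd = 0, bouton_positions_um = numeric(0))
  mv <- render_axon_timelapse(mc)
  trks <- detect_tracks(build_kymograph(mv$stack, mc$axon_path),
                        min_frames = 20)
  expect_length(trks, 2)
  vel <- sort(vapply(trks, track_velocity, numeric(1)))
  expect_equal(vel, c(-1.0, 1.0), tolerance = 0.05)
})

test_that("auto-traced speeds across the physiological range are accurate", {
  for (v in c(0.5, 1.0, 1.75, 2.5)) {
    mc <- movie_config(punctum_speeds_um_s = v, punctum_starts_um = 4,
                       noise_sd = 0, bouton_positions_um = numeric(0))
    mv <- render_axon_timelapse(mc)
    trks <- detect_tracks(build_kymograph(mv$stack, mc$axon_path),
                          min_frames = 15)
    expect_length(trks, 1)
    expect_lt(abs(track_speed(trks[[1]]) - v) / v, 0.05)
  }
})

test_that("constant cross-section traffic normalizes to the frame count", {
  st <- image_stack(array(5, c(151, 20, 20)), (0:150) / 5, 0.2)
  tm <- cumulative_traffic(st, rbind(c(5, 10), c(15, 10)))
  expect_equal(tm$per_frame_normalized, rep(1, 151))
  expect_equal(tm$cumulative, 151)
})

test_that("added transits raise cumulative traffic by their closed form", {
  base <- array(5, c(151, 20, 20))
  st0 <- image_stack(base, (0:150) / 5, 0.2)
  line <- rbind(c(5, 10), c(15, 10))
  c0 <- cumulative_traffic(st0, line)$cumulative
  per_line_baseline <- cumulative_traffic(st0, line)$per_frame_raw[1]
  vals <- vapply(c(2, 5, 9), function(k) {
    a <- base
    a[seq(20, by = 12, length.out = k), , 10] <-
      a[seq(20, by = 12, length.out = k), , 10] + 3   # transient frames
    cumulative_traffic(image_stack(a, (0:150) / 5, 0.2), line)$cumulative
  }, numeric(1))
  # each transient adds (transient integral / baseline) to the sum
  transient <- 3 * 11 / per_line_baseline   # 11 line samples
  expect_equal(vals, c0 + c(2, 5, 9) * transient, tolerance = 1e-9)
  expect_true(all(diff(vals) > 0))
})

test_that("cumulative traffic is invariant to global intensity rescaling", {
  set.seed(13)
  a <- array(runif(30 * 20 * 20, 1, 2), c(30, 20, 20))
  st <- image_stack(a, 0:29, 0.2)
  st2 <- image_stack(7.7 * a, 0:29, 0.2)
  line <- rbind(c(4, 9), c(16, 9))
  expect_equal(cumulative_traffic(st2, line)$per_frame_normalized,
               cumulative_traffic(st, line)$per_frame_normalized,
               tolerance = 1e-12)
})

test_that("zero-signal lines trigger the degenerate-normalization guard", {
  st <- image_stack(array(0, c(20, 16, 16)), 0:19, 0.2)
  expect_error(cumulative_traffic(st, rbind(c(4, 8), c(12, 8))),
               "degenerate normalization")
  expect_error(cumulative_traffic(
    image_stack(array(1, c(8, 16, 16)), 0:7, 0.2),
    rbind(c(4, 8), c(12, 8))), "more frames")
})

test_that("denser traffic yields strictly larger cumulative flux", {
  cum_for <- function(n) {
    mc <- movie_config(
      punctum_speeds_um_s = rep(1.5, n),
      punctum_starts_um = seq(0, 18, length.out = n),
      noise_sd = 0, bouton_positions_um = numeric(0), seed = 5)
    mv <- render_axon_timelapse(mc)
    cross <- path_cross_line <- rbind(c(32 - 5, 150), c(32 + 5, 150))
    cumulative_traffic(mv$stack, cross)$cumulative
  }
  v <- c(cum_for(2), cum_for(5), cum_for(9))
  expect_true(all(diff(v) > 0))
})
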