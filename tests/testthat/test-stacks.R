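test_that("sum projection equals the per-pixel z sum", {
  # k identical planes of value v
  sub <- list(array(3, c(4, 8, 8)), array(3, c(4, 8, 8)))
  st <- sum_project(sub, c(0, 30), 0.2)
  expect_true(all(st$data == 12))
  # single plane is the identity
  plane <- matrix(runif(64), 8, 8)
  st1 <- sum_project(list(array(plane, c(1, 8, 8))), 0, 0.2)
  expect_equal(st1$data[1, , ], plane)
  # random 3-plane stack vs elementwise oracle
  set.seed(5)
  z <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  st3 <- sum_project(list(z), 0, 0.2)
  expect_equal(st3$data[1, , ], z[1, , ] + z[2, , ] + z[3, , ])
  expect_error(sum_project(list(array(0, c(2, 4, 4)),
                                array(0, c(2, 5, 5))), c(0, 1), 0.2),
               "shape")
})

test_that("image stack validates calibration metadata", {
  expect_error(image_stack(array(0, c(2, 4, 4)), c(1, 1), 0.2),
               "strictly increasing")
  expect_error(image_stack(array(0, c(2, 4, 4)), c(0, 1), 0),
               "pixel_size")
  expect_error(image_stack(array(0, c(2, 4, 4)), 0, 0.2), "one timestamp")
})

test_that("registration is null on a drift-free stack", {
  cfg <- frap_sim_config(noise_sd = 0, n_boutons = 3, seed = 2)
  rs <- render_frap_stack(cfg)
  reg <- register_stack(rs$stack)
  expect_lt(max(abs(reg$drift)), 0.05)
})

test_that("registration recovers injected constant drift within 0.25 px", {
  cfg <- frap_sim_config(noise_sd = 0, n_boutons = 3, seed = 2)
  rs <- render_frap_stack(cfg, frap_geometry(drift_per_frame = c(0.23, -0.17)))
  reg <- register_stack(rs$stack)
  expect_lt(max(abs(reg$drift - rs$drift)), 0.25)
})

test_that("registration increases mean frame-to-reference correlation", {
  cfg <- frap_sim_config(noise_sd = 0.02, n_boutons = 3, seed = 3)
  rs <- render_frap_stack(cfg, frap_geometry(drift_per_frame = c(0.3, 0.2)))
  reg <- register_stack(rs$stack)
  mean_cor <- function(s) {
    mean(vapply(2:dim(s$data)[1], function(f) {
      stats::cor(as.vector(s$data[f, , ]), as.vector(s$data[1, , ]))
    }, numeric(1)))
  }
  expect_gt(mean_cor(reg$stack), mean_cor(rs$stack))
})

test_that("all-zero frames trigger a degenerate-registration warning", {
  st <- image_stack(array(0, c(3, 16, 16)), c(0, 1, 2), 0.2)
  expect_warning(reg <- register_stack(st), "degenerate")
  expect_true(all(reg$drift == 0))
})

test_that("ROI extraction integrates intensities and flags empty masks", {
  data <- array(7, c(3, 20, 20))
  data[, 1:5, 1:5] <- 0
  st <- image_stack(data, c(0, 1, 2), 0.2)
  rois <- roi_set(list(roi_circle(c(12, 12), 3)),
                  list(roi_circle(c(12, 12), 5)),
                  roi_polygon(rbind(c(1, 1), c(1, 5), c(5, 5), c(5, 1))))
  ex <- extract_roi_traces(st, rois)
  a <- sum(roi_mask(rois$bouton_rois[[1]], c(20, 20)))
  expect_equal(ex$bouton[, 1], rep(7 * a, 3))         # uniform frame: v * area
  expect_equal(ex$background_mean, rep(0, 3))         # zero-valued region
  expect_error(
    extract_roi_traces(st, roi_set(list(roi_circle(c(-10, -10), 0.1)),
                                   rois$cell_rois, rois$background_roi)),
    "empty ROI")
})

test_that("ROI trace extraction is linear in the stack", {
  set.seed(11)
  a <- array(runif(3 * 16 * 16), c(3, 16, 16))
  b <- array(runif(3 * 16 * 16), c(3, 16, 16))
  rois <- roi_set(list(roi_circle(c(8, 8), 4)), list(roi_circle(c(8, 8), 6)),
                  roi_circle(c(3, 13), 2))
  tr <- function(x) extract_roi_traces(image_stack(x, 0:2, 1), rois)$bouton
  expect_equal(tr(a + b), tr(a) + tr(b), tolerance = 1e-12)
})

test_that("registration then extraction recovers the drift-free trace", {
  cfg <- frap_sim_config(noise_sd = 0, n_boutons = 2, seed = 4)
  rs <- render_frap_stack(cfg, frap_geometry(drift_per_frame = c(0.2, -0.15)))
  reg <- register_stack(rs$stack)
  ex <- extract_roi_traces(reg$stack, rs$rois)
  truth <- rs$sim$traces[[1]]$bouton_raw - cfg$background_level
  meas <- ex$bouton[, 1] - ex$background_mean * ex$bouton_areas[1]
  expect_lt(max(abs(meas - truth) / abs(truth)), 0.02)
})

test_that("bouton morphometry recovers disk area and intensity ratios", {
  img <- make_disk(c(64, 64), 32, 32, 8, 100)
  mb <- measure_boutons(img, pixel_size = 0.2)
  expect_equal(nrow(mb), 1)
  expect_lt(abs(mb$area_um2 / (pi * 8^2 * 0.2^2) - 1), 0.1)
  # blank image yields nothing
  expect_equal(nrow(measure_boutons(matrix(0, 32, 32))), 0)
  # 2:1 intensity ratio preserved within 5%
  img2 <- make_disk(c(64, 128), 32, 32, 8, 100) +
    make_disk(c(64, 128), 32, 96, 8, 50)
  mb2 <- measure_boutons(img2, 0.2)
  expect_equal(nrow(mb2), 2)
  r <- max(mb2$integrated_intensity) / min(mb2$integrated_intensity)
  expect_lt(abs(r - 2), 0.1)
})

test_that("bouton intensities are invariant to a global additive offset", {
  img <- make_disk(c(64, 64), 32, 32, 8, 100)
  m0 <- measure_boutons(img, 0.2)
  m1 <- measure_boutons(img + 37, 0.2)
  expect_equal(m1$integrated_intensity, m0$integrated_intensity,
               tolerance = 1e-9)
})

test_that("normalized bouton intensity uses the reference-group mean", {
  img <- make_disk(c(64, 64), 32, 32, 8, 100)
  m <- measure_boutons(img, 0.2, reference_mean = 1000)
  expect_equal(m$normalized_intensity, m$integrated_intensity / 1000)
})

test_that("puncta density reflects punctate signal level", {
  two <- make_disk(c(64, 64), 20, 20, 4, 50) +
    make_disk(c(64, 64), 45, 45, 4, 50)
  p <- puncta_density(two)
  expect_equal(p$mean_density, 50, tolerance = 50 * 0.3)
  expect_false(p$flagged)
  # uniform field: empty mask, density 0, flagged
  pu <- puncta_density(matrix(7, 32, 32))
  expect_equal(pu$mean_density, 0)
  expect_true(pu$flagged)
  # doubling intensity doubles density
  p2 <- puncta_density(2 * two)
  expect_equal(p2$mean_density / p$mean_density, 2, tolerance = 1e-9)
  # list input averages fields
  pl <- puncta_density(list(two, 2 * two))
  expect_equal(pl$n_fields, 2)
  expect_equal(pl$mean_density, (p$mean_density + p2$mean_density) / 2)
})

test_that("stack TIFF round-trip preserves data and calibration", {
  cfg <- frap_sim_config(noise_sd = 0.05, n_boutons = 1, seed = 6)
  rs <- render_frap_stack(cfg, frap_geometry(dim = c(48, 48)))
  path <- file.path(tempdir(), "stack_roundtrip.tif")
  write_stack_tiff(rs$stack, path)
  back <- read_stack_tiff(path)
  expect_equal(back$timestamps, rs$stack$timestamps)
  expect_equal(back$pixel_size, rs$stack$pixel_size)
  expect_equal(back$data, rs$stack$data, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})

test_that("trace CSV round-trip preserves every series and the areas", {
  cfg <- frap_sim_config(noise_sd = 0.02, n_boutons = 3, seed = 7)
  traces <- simulate_frap_trace(cfg)$traces
  path <- file.path(tempdir(), "traces_roundtrip.csv")
  write_frap_traces_csv(traces, path)
  back <- read_frap_traces_csv(path)
  expect_length(back, 3)
  expect_equal(back[[1]]$bouton_raw, traces[[1]]$bouton_raw)
  expect_equal(back[[2]]$cell_reference_raw, traces[[2]]$cell_reference_raw)
  expect_equal(back[[3]]$bleach_index, traces[[3]]$bleach_index)
  unlink(path)
})
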