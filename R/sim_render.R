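# separable 2-D Gaussian spot added onto a canvas; mass = integrated intensity
add_gaussian_spot <- function(canvas, center_row, center_col, sd, mass) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  amp <- mass / (2 * pi * sd^2)
  er <- exp(-((seq_len(nr) - center_row)^2) / (2 * sd^2))
  ec <- exp(-((seq_len(nc) - center_col)^2) / (2 * sd^2))
  canvas + amp * (er %o% ec)
}

#' Geometry of a rendered synthetic FRAP field
#'
#' @param dim Frame dimensions `c(nrow, ncol)` in pixels.
#' @param bouton_centers n x 2 matrix of bouton centers (row, col); default
#'   places `n_boutons` evenly along a horizontal line.
#' @param spot_sd Gaussian spot sd, pixels.
#' @param cell_center,cell_sd Center and sd of the diffuse whole-cell blob.
#' @param drift_per_frame Global (drow, dcol) drift applied per frame, px.
#' @param camera_noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param camera_noise_sd Gaussian camera noise sd (AU), when gaussian.
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `frap_geometry`.
#' @export
frap_geometry <- function(dim = c(96, 96), bouton_centers = NULL,
                          spot_sd = 2, cell_center = NULL, cell_sd = 6,
                          drift_per_frame = c(0, 0),
                          camera_noise = c("none", "gaussian", "poisson"),
                          camera_noise_sd = 0, pixel_size = 0.2) {
  camera_noise <- match.arg(camera_noise)
  if (!(spot_sd > 0)) stop("spot sd must be > 0", call. = FALSE)
  if (is.null(cell_center)) cell_center <- c(dim[1] * 0.25, dim[2] / 2)
  structure(list(dim = dim, bouton_centers = bouton_centers,
                 spot_sd = spot_sd, cell_center = cell_center,
                 cell_sd = cell_sd, drift_per_frame = drift_per_frame,
                 camera_noise = camera_noise,
                 camera_noise_sd = camera_noise_sd, pixel_size = pixel_size),
            class = "frap_geometry")
}

#' Render a synthetic FRAP image stack with ground truth
#'
#' Renders each bouton as an isotropic 2-D Gaussian spot whose integrated
#' intensity follows a trace from [simulate_frap_trace()], plus a broad
#' whole-cell reference blob carrying the same acquisition-photobleach
#' factor, a constant per-pixel background, optional global per-frame
#' drift, and optional camera noise. Ground-truth ROIs (boutons, cell,
#' background) and the injected drift are returned alongside.
#'
#' @param config A [frap_sim_config()].
#' @param geometry A [frap_geometry()].
#' @return List with `stack` ([image_stack()]), `rois` ([roi_set()],
#'   positioned on the undrifted frame), `drift` (frames x 2 matrix of
#'   injected drift), `sim` (the [simulate_frap_trace()] output used) and
#'   `geometry`.
#' @export
render_frap_stack <- function(config, geometry = frap_geometry()) {
  stopifnot(inherits(config, "frap_sim_config"),
            inherits(geometry, "frap_geometry"))
  nb <- config$n_boutons
  dimv <- geometry$dim
  centers <- geometry$bouton_centers
  if (is.null(centers)) {
    cols <- seq(dimv[2] * 0.15, dimv[2] * 0.85, length.out = nb)
    centers <- cbind(rep(dimv[1] * 0.7, nb), cols)
  }
  if (nrow(centers) != nb) {
    stop("need one bouton center per simulated bouton", call. = FALSE)
  }
  margin <- 3 * geometry$spot_sd
  if (any(centers[, 1] < margin | centers[, 1] > dimv[1] - margin |
          centers[, 2] < margin | centers[, 2] > dimv[2] - margin)) {
    stop("bouton centers must lie inside the frame", call. = FALSE)
  }
  sim <- simulate_frap_trace(config)
  nf <- length(sim$traces[[1]]$timestamps)
  bg_level <- config$background_level
  cell_mass <- config$cell_level * sim$bleach_factors
  set.seed(config$seed + 1L)
  data <- array(0, c(nf, dimv))
  for (f in seq_len(nf)) {
    off <- geometry$drift_per_frame * (f - 1)
    canvas <- matrix(bg_level, dimv[1], dimv[2])
    canvas <- add_gaussian_spot(canvas,
                                geometry$cell_center[1] + off[1],
                                geometry$cell_center[2] + off[2],
                                geometry$cell_sd, cell_mass[f])
    for (i in seq_len(nb)) {
      mass <- sim$traces[[i]]$bouton_raw[f] - bg_level  # pure bouton signal
      canvas <- add_gaussian_spot(canvas, centers[i, 1] + off[1],
                                  centers[i, 2] + off[2],
                                  geometry$spot_sd, mass)
    }
    if (geometry$camera_noise == "gaussian" && geometry$camera_noise_sd > 0) {
      canvas <- canvas + stats::rnorm(length(canvas), 0,
                                      geometry$camera_noise_sd)
    } else if (geometry$camera_noise == "poisson") {
      canvas <- matrix(stats::rpois(length(canvas), pmax(canvas, 0)),
                       dimv[1], dimv[2])
    }
    data[f, , ] <- canvas
  }
  t_abs <- sim$traces[[1]]$timestamps
  bouton_rois <- lapply(seq_len(nb), function(i) {
    roi_circle(centers[i, ], 3.5 * geometry$spot_sd)
  })
  rois <- roi_set(bouton_rois,
                  list(roi_circle(geometry$cell_center, 3 * geometry$cell_sd)),
                  roi_circle(c(dimv[1] * 0.9, dimv[2] * 0.08),
                             max(3, 2 * geometry$spot_sd)))
  drift <- cbind(geometry$drift_per_frame[1] * (seq_len(nf) - 1),
                 geometry$drift_per_frame[2] * (seq_len(nf) - 1))
  list(stack = image_stack(data, t_abs, geometry$pixel_size), rois = rois,
       drift = drift, sim = sim, geometry = geometry)
}

#' Configuration of the synthetic axonal time-lapse generator
#'
#' Defaults follow the transport imaging protocol: 5 frames/s for 30 s,
#' giving 151 frames, with vesicle clusters moving along the axon at
#' 0.5-2.5 um/s past stationary, brighter boutons.
#'
#' @param frame_rate Frames per second.
#' @param duration Sequence duration, seconds; the frame count is
#'   `round(frame_rate * duration) + 1`.
#' @param pixel_size Micrometres per pixel.
#' @param dim Frame dimensions `c(nrow, ncol)`, pixels.
#' @param axon_path Polyline (n x 2, (row, col)) of the axon; default a
#'   horizontal line through the field.
#' @param bouton_positions_um Path offsets (um) of stationary boutons.
#' @param punctum_speeds_um_s Signed speeds of moving puncta (um/s;
#'   positive = increasing path offset).
#' @param punctum_starts_um Path offset of each punctum at t = 0 (um).
#' @param punctum_amplitudes Integrated intensity of each punctum (AU).
#' @param bouton_amplitude Integrated intensity of stationary boutons (AU).
#' @param baseline_level Constant background level (AU).
#' @param noise_sd Gaussian camera noise sd (AU).
#' @param drift_per_frame Global (drow, dcol) drift per frame, px.
#' @param spot_sd Gaussian spot sd, px.
#' @param seed Integer seed.
#' @return An object of class `movie_config`.
#' @export
movie_config <- function(frame_rate = 5, duration = 30, pixel_size = 0.2,
                         dim = c(64, 256), axon_path = NULL,
                         bouton_positions_um = c(10, 25, 40),
                         punctum_speeds_um_s = c(1.5, -1.0),
                         punctum_starts_um = NULL,
                         punctum_amplitudes = NULL,
                         bouton_amplitude = 800,
                         baseline_level = 10, noise_sd = 0,
                         drift_per_frame = c(0, 0), spot_sd = 1.5,
                         seed = 1L) {
  if (!(frame_rate > 0) || !(duration > 0)) {
    stop("frame_rate and duration must be positive", call. = FALSE)
  }
  if (is.null(axon_path)) {
    axon_path <- cbind(c(dim[1] / 2, dim[1] / 2), c(6, dim[2] - 5))
  }
  axon_path <- as.matrix(axon_path)
  if (nrow(axon_path) < 2) stop("axon path needs >= 2 vertices", call. = FALSE)
  seg <- sqrt(rowSums(diff(axon_path)^2))
  if (sum(seg) <= 0) stop("axon path length must be > 0", call. = FALSE)
  np <- length(punctum_speeds_um_s)
  if (any(!is.finite(punctum_speeds_um_s))) {
    stop("punctum speeds must be finite", call. = FALSE)
  }
  path_len_um <- sum(seg) * pixel_size
  if (is.null(punctum_starts_um)) {
    punctum_starts_um <- if (np > 0) {
      seq(0.1, 0.6, length.out = np) * path_len_um
    } else numeric(0)
  }
  if (is.null(punctum_amplitudes)) punctum_amplitudes <- rep(200, np)
  structure(list(frame_rate = frame_rate, duration = duration,
                 pixel_size = pixel_size, dim = dim, axon_path = axon_path,
                 bouton_positions_um = bouton_positions_um,
                 punctum_speeds_um_s = punctum_speeds_um_s,
                 punctum_starts_um = punctum_starts_um,
                 punctum_amplitudes = punctum_amplitudes,
                 bouton_amplitude = bouton_amplitude,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 drift_per_frame = drift_per_frame, spot_sd = spot_sd,
                 path_len_um = path_len_um, seed = as.integer(seed)),
            class = "movie_config")
}

# cumulative arc length (px) and point at a given offset (um) on a polyline
path_point <- function(path, offset_um, pixel_size) {
  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  s_px <- offset_um / pixel_size
  s_px <- pmin(pmax(s_px, 0), cum[length(cum)])
  i <- findInterval(s_px, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  frac <- (s_px - cum[i]) / seg[i]
  path[i, , drop = FALSE] + frac * (path[i + 1, , drop = FALSE] -
                                      path[i, , drop = FALSE])
}

#' Render a synthetic axonal time-lapse movie with ground truth
#'
#' Stationary boutons and moving puncta are drawn as Gaussian spots along
#' the axon path; each punctum's path offset advances `speed * dt` per
#' frame and the punctum is drawn only while it remains on the path.
#'
#' @param config A [movie_config()].
#' @return List with `stack` ([image_stack()]), `config`, and `puncta`
#'   (data frame of ground-truth punctum kinematics: id, start offset um,
#'   speed um/s, amplitude). Crossing times at any path position are given
#'   by [transit_times()].
#' @export
render_axon_timelapse <- function(config) {
  stopifnot(inherits(config, "movie_config"))
  nf <- round(config$frame_rate * config$duration) + 1
  ts <- (seq_len(nf) - 1) / config$frame_rate
  dimv <- config$dim
  set.seed(config$seed)
  data <- array(0, c(nf, dimv))
  bcenters <- if (length(config$bouton_positions_um)) {
    path_point(config$axon_path, config$bouton_positions_um,
               config$pixel_size)
  } else matrix(0, 0, 2)
  np <- length(config$punctum_speeds_um_s)
  for (f in seq_len(nf)) {
    off <- config$drift_per_frame * (f - 1)
    canvas <- matrix(config$baseline_level, dimv[1], dimv[2])
    for (b in seq_len(nrow(bcenters))) {
      canvas <- add_gaussian_spot(canvas, bcenters[b, 1] + off[1],
                                  bcenters[b, 2] + off[2],
                                  config$spot_sd, config$bouton_amplitude)
    }
    for (p in seq_len(np)) {
      s <- config$punctum_starts_um[p] +
        config$punctum_speeds_um_s[p] * ts[f]
      if (s < 0 || s > config$path_len_um) next
      ctr <- path_point(config$axon_path, s, config$pixel_size)
      canvas <- add_gaussian_spot(canvas, ctr[1] + off[1], ctr[2] + off[2],
                                  config$spot_sd, config$punctum_amplitudes[p])
    }
    if (config$noise_sd > 0) {
      canvas <- canvas + stats::rnorm(length(canvas), 0, config$noise_sd)
    }
    data[f, , ] <- canvas
  }
  puncta <- data.frame(id = seq_len(np),
                       start_um = config$punctum_starts_um,
                       speed_um_s = config$punctum_speeds_um_s,
                       amplitude = config$punctum_amplitudes)
  list(stack = image_stack(data, ts, config$pixel_size), config = config,
       puncta = puncta)
}

#' Ground-truth crossing times of puncta at a path position
#'
#' @param movie Output of [render_axon_timelapse()].
#' @param position_um Path offset (um) of the queried cross-section.
#' @return Data frame (id, time_s) of puncta crossing that position within
#'   the recorded sequence.
#' @export
transit_times <- function(movie, position_um) {
  p <- movie$puncta
  t_cross <- (position_um - p$start_um) / p$speed_um_s
  ok <- is.finite(t_cross) & t_cross >= 0 & t_cross <= movie$config$duration
  data.frame(id = p$id[ok], time_s = t_cross[ok])
}
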