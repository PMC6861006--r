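# vectorized bilinear sampling of a matrix at fractional (row, col) points
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  if (any(r < 1 | r > nr | c < 1 | c > nc)) {
    stop("sampling point outside frame", call. = FALSE)
  }
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  wr <- r - r0; wc <- c - c0
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1)
  i10 <- cbind(r0 + 1, c0); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - wr) * (1 - wc) + m[i01] * (1 - wr) * wc +
    m[i10] * wr * (1 - wc) + m[i11] * wr * wc
}

# resample a polyline at 1-px arc-length steps; returns points, tangents
# and unit normals
resample_path <- function(path, step_px = 1) {
  path <- as.matrix(path)
  if (nrow(path) < 2) stop("path needs >= 2 vertices", call. = FALSE)
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  if (total <= 0) stop("path length must be > 0", call. = FALSE)
  s <- seq(0, total, by = step_px)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (s - cum[i]) / len[i]
  pts <- path[i, , drop = FALSE] + frac * seg[i, , drop = FALSE]
  tang <- seg[i, , drop = FALSE] / len[i]
  normal <- cbind(-tang[, 2], tang[, 1])
  list(points = pts, normals = normal, arc_px = s)
}

#' Build a kymograph from a time-lapse stack along an axon path
#'
#' The path is resampled at one-pixel arc-length steps; at every frame and
#' path position, intensity is read over a `width_px`-wide segment normal
#' to the path (bilinear interpolation) and reduced by maximum (default,
#' which preserves dim moving puncta next to saturated boutons) or mean.
#'
#' @param stack An [image_stack()].
#' @param path Polyline, n x 2 matrix of (row, col) pixel coordinates.
#' @param width_px Width of the normal averaging segment, pixels (>= 1).
#' @param reduce `"max"` or `"mean"`.
#' @return An object of class `kymograph`: `data` (frames x positions),
#'   `pixel_size` (um/px along the path), `frame_interval` (s), `path`.
#' @export
build_kymograph <- function(stack, path, width_px = 1,
                            reduce = c("max", "mean")) {
  stopifnot(inherits(stack, "image_stack"))
  reduce <- match.arg(reduce)
  if (width_px < 1) stop("width_px must be >= 1", call. = FALSE)
  rp <- resample_path(path)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  nf <- dim(stack$data)[1]
  npos <- nrow(rp$points)
  ky <- matrix(0, nf, npos)
  rows <- outer(rp$points[, 1], offs, function(p, o) p) +
    outer(rp$normals[, 1], offs)
  cols <- outer(rp$points[, 2], offs, function(p, o) p) +
    outer(rp$normals[, 2], offs)
  for (f in seq_len(nf)) {
    frame <- stack$data[f, , ]
    vals <- matrix(bilinear_sample(frame, as.vector(rows), as.vector(cols)),
                   npos, width_px)
    ky[f, ] <- if (reduce == "max") apply(vals, 1, max) else rowMeans(vals)
  }
  fi <- if (nf > 1) stats::median(diff(stack$timestamps)) else NA_real_
  structure(list(data = ky, pixel_size = stack$pixel_size,
                 frame_interval = fi, path = path),
            class = "kymograph")
}

#' A traced particle track on a kymograph
#'
#' @param times Vertex times, seconds (strictly increasing).
#' @param positions_um Path positions at the vertices, micrometres.
#' @return An object of class `track`.
#' @export
track <- function(times, positions_um) {
  if (length(times) < 2 || length(times) != length(positions_um)) {
    stop("a track needs >= 2 (time, position) vertices", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("invalid track: times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 positions_um = as.numeric(positions_um)),
            class = "track")
}

#' Mean speed of a track
#'
#' Segmental mean of `|dposition| / dtime` over consecutive vertex pairs;
#' pauses contribute zero-speed segments, and the result is unsigned.
#'
#' @param tr A [track()].
#' @return Mean speed, um/s.
#' @export
track_speed <- function(tr) {
  stopifnot(inherits(tr, "track"))
  dt <- diff(tr$times)
  if (any(dt <= 0)) stop("invalid track: zero time step", call. = FALSE)
  mean(abs(diff(tr$positions_um)) / dt)
}

#' Signed track velocity
#'
#' Least-squares slope of position over time; positive = motion toward
#' increasing path offset. Reported mean speeds are magnitudes
#' ([track_speed()]); the sign is kept separately for directionality.
#'
#' @param tr A [track()].
#' @return Velocity, um/s (signed).
#' @export
track_velocity <- function(tr) {
  stopifnot(inherits(tr, "track"))
  unname(stats::coef(stats::lm(tr$positions_um ~ tr$times))[2])
}

# subpixel peak position by parabolic interpolation around a local maximum
refine_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(i)
  i + 0.5 * (v[i - 1] - v[i + 1]) / denom
}

#' Automatically trace moving puncta on a kymograph
#'
#' Detects intensity ridges: per time row, local maxima above a threshold
#' are localized to subpixel precision (parabolic refinement, after
#' optional Gaussian smoothing along the position axis) and linked across
#' consecutive rows to the nearest existing track within the displacement
#' a punctum at `max_speed_um_s` could make per frame. Tracks shorter than
#' `min_frames` rows are dropped.
#'
#' @param kymo A [build_kymograph()] result.
#' @param min_frames Minimum track length in rows (default 5).
#' @param rel_threshold Peak threshold as a fraction of the kymograph's
#'   intensity range above its lower decile.
#' @param max_speed_um_s Largest linkable speed, um/s.
#' @param smooth_sd Gaussian smoothing sd along position, px (0 = none).
#' @return List of [track()] objects.
#' @export
detect_tracks <- function(kymo, min_frames = 5, rel_threshold = 0.25,
                          max_speed_um_s = 3, smooth_sd = 0) {
  stopifnot(inherits(kymo, "kymograph"))
  ky <- kymo$data
  if (length(ky) == 0 || all(ky == ky[1])) return(list())
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd)
    kern <- stats::dnorm(-half:half, sd = smooth_sd)
    kern <- kern / sum(kern)
    ky <- t(apply(ky, 1, function(row) {
      stats::filter(c(rep(row[1], half), row, rep(row[length(row)], half)),
                    kern, sides = 2)[(half + 1):(half + length(row))]
    }))
  }
  lo <- stats::quantile(ky, 0.1)
  thr <- lo + rel_threshold * (max(ky) - lo)
  if (max(ky) <= thr) return(list())
  max_step <- max_speed_um_s * kymo$frame_interval / kymo$pixel_size + 1
  nf <- nrow(ky)
  active <- list()   # each: list(rows, pos)
  done <- list()
  for (f in seq_len(nf)) {
    row <- ky[f, ]
    n <- length(row)
    is_peak <- row > thr &
      row >= c(-Inf, row[-n]) & row >= c(row[-1], -Inf)
    peaks <- vapply(which(is_peak), function(i) refine_peak(row, i),
                    numeric(1))
    used <- rep(FALSE, length(peaks))
    if (length(active)) {
      keep <- logical(length(active))
      for (a in seq_along(active)) {
        last_pos <- utils::tail(active[[a]]$pos, 1)
        if (length(peaks)) {
          d <- abs(peaks - last_pos)
          j <- which.min(ifelse(used, Inf, d))
          if (length(j) && !used[j] && d[j] <= max_step) {
            active[[a]]$rows <- c(active[[a]]$rows, f)
            active[[a]]$pos <- c(active[[a]]$pos, peaks[j])
            used[j] <- TRUE
            keep[a] <- TRUE
            next
          }
        }
        done <- c(done, active[a])
      }
      active <- active[keep]
    }
    for (j in which(!used)) {
      active <- c(active, list(list(rows = f, pos = peaks[j])))
    }
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$rows) >= max(min_frames, 2), done)
  lapply(done, function(tr) {
    track((tr$rows - 1) * kymo$frame_interval,
          (tr$pos - 1) * kymo$pixel_size)
  })
}

#' Cumulative cross-section traffic through an axonal line ROI
#'
#' Quantifies total material moving through a cross-section of the axon:
#' per frame, the integrated density along a line ROI drawn perpendicular
#' to the axon (bilinear sampling, averaged across `width_px`) minus the
#' per-pixel background; every frame's value is then divided by the mean
#' of the 10 lowest values of the sequence (normalizing away
#' between-experiment intensity differences), and the normalized values
#' are summed over all frames.
#'
#' @param stack An [image_stack()] (>= 11 frames).
#' @param line 2 x 2 matrix: endpoints of the cross-section, (row, col).
#' @param background Per-pixel background: a scalar, a per-frame vector,
#'   or an ROI (`roi_circle()`/`roi_polygon()`) whose per-frame mean is
#'   used. Default 0.
#' @param width_px Line width, pixels (default 1).
#' @param n_lowest Number of lowest frames defining the baseline
#'   (default 10).
#' @return An object of class `traffic_measure`: `per_frame_normalized`,
#'   `cumulative` (their sum), `per_frame_raw`, `line`.
#' @export
cumulative_traffic <- function(stack, line, background = 0, width_px = 1,
                               n_lowest = 10) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$data)[1]
  if (nf < n_lowest + 1) {
    stop("need more frames than the baseline pool", call. = FALSE)
  }
  rp <- resample_path(line)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  rows <- outer(rp$points[, 1], offs, function(p, o) p) +
    outer(rp$normals[, 1], offs)
  cols <- outer(rp$points[, 2], offs, function(p, o) p) +
    outer(rp$normals[, 2], offs)
  npts <- nrow(rp$points)
  bg <- if (inherits(background, "roi")) {
    m <- roi_mask(background, dim(stack$data)[2:3])
    idx <- which(m)
    vapply(seq_len(nf), function(f) mean(stack$data[f, , ][idx]), numeric(1))
  } else {
    rep_len(as.numeric(background), nf)
  }
  v <- vapply(seq_len(nf), function(f) {
    vals <- matrix(bilinear_sample(stack$data[f, , ], as.vector(rows),
                                   as.vector(cols)), npts, width_px)
    sum(rowMeans(vals)) - bg[f] * npts
  }, numeric(1))
  baseline <- mean(sort(v)[seq_len(n_lowest)])
  if (!(baseline > 1e-9 * max(abs(v)))) {
    stop("degenerate normalization: baseline (mean of ", n_lowest,
         " lowest frames) is not positive", call. = FALSE)
  }
  norm <- v / baseline
  structure(list(per_frame_normalized = norm, cumulative = sum(norm),
                 per_frame_raw = v, line = line),
            class = "traffic_measure")
}
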