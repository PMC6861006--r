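#' Calibrated time-lapse image stack
#'
#' @param data 3-D numeric array indexed `[frame, row, col]` (stored as
#'   32-bit float when written to TIFF).
#' @param timestamps Acquisition time of each frame, seconds; strictly
#'   increasing, one per frame.
#' @param pixel_size Pixel size, micrometres per pixel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, timestamps, pixel_size) {
  if (length(dim(data)) != 3) stop("data must be a 3-D array", call. = FALSE)
  if (length(timestamps) != dim(data)[1]) {
    stop("one timestamp per frame required", call. = FALSE)
  }
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!(pixel_size > 0)) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(data = data, timestamps = as.numeric(timestamps),
                 pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frames of %d x %d px (%.3g um/px), %.4g-%.4g s\n",
              d[1], d[2], d[3], x$pixel_size,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Region-of-interest set for a FRAP field
#'
#' Holds the bleached-bouton ROIs, whole-cell reference ROI(s), one
#' background region, and optional axon polylines. ROIs are circles
#' (`roi_circle()`) or polygons (`roi_polygon()`) in 0-free 1-based
#' (row, col) pixel coordinates; a pixel belongs to an ROI when its
#' center falls inside.
#'
#' @param bouton_rois List of ROIs over the bleached boutons.
#' @param cell_rois List of ROIs over the cells in the field.
#' @param background_roi One ROI over a cell-free region.
#' @param axon_paths Optional list of polylines (n x 2 matrices, (row, col)).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(bouton_rois, cell_rois, background_roi,
                    axon_paths = list()) {
  structure(list(bouton_rois = bouton_rois, cell_rois = cell_rois,
                 background_roi = background_roi, axon_paths = axon_paths),
            class = "roi_set")
}

#' @rdname roi_set
#' @param center Circle center, `c(row, col)`.
#' @param radius Radius in pixels.
#' @export
roi_circle <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(type = "circle", center = as.numeric(center),
                 radius = radius), class = "roi")
}

#' @rdname roi_set
#' @param vertices n x 2 matrix of polygon vertices, (row, col).
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  structure(list(type = "polygon", vertices = vertices), class = "roi")
}

#' Rasterize an ROI to a logical pixel mask
#'
#' @param roi A `roi_circle()` or `roi_polygon()`.
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @return Logical matrix; `TRUE` where the pixel center lies inside.
#' @export
roi_mask <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (roi$type == "circle") {
    m <- (rows - roi$center[1])^2 + (cols - roi$center[2])^2 <= roi$radius^2
  } else {
    m <- matrix(point_in_polygon(as.vector(rows), as.vector(cols),
                                 roi$vertices), nr, nc)
  }
  m
}

# even-odd ray-crossing point-in-polygon, vectorized over query points
point_in_polygon <- function(py, px, vertices) {
  vy <- vertices[, 1]; vx <- vertices[, 2]
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Sum-project per-timepoint z-stacks into a time-lapse stack
#'
#' Each acquisition timepoint of a FRAP experiment is a short z-stack;
#' analysis proceeds on its per-pixel sum projection.
#'
#' @param substacks List of 3-D arrays `[z, row, col]`, one per timepoint,
#'   all sharing x-y shape.
#' @param timestamps Timepoint times, seconds.
#' @param pixel_size Micrometres per pixel.
#' @return An [image_stack()] with one frame per timepoint.
#' @export
sum_project <- function(substacks, timestamps, pixel_size) {
  if (length(substacks) == 0) stop("no substacks given", call. = FALSE)
  shp <- dim(substacks[[1]])[2:3]
  planes <- lapply(substacks, function(s) {
    if (length(dim(s)) != 3 || any(dim(s)[2:3] != shp)) {
      stop("substacks must be 3-D and share x-y shape", call. = FALSE)
    }
    apply(s, c(2, 3), sum)
  })
  data <- array(0, c(length(planes), shp))
  for (i in seq_along(planes)) data[i, , ] <- planes[[i]]
  image_stack(data, timestamps, pixel_size)
}

# correlation surface of two equally-sized frames evaluated by
# matrix-multiply inverse DFT at arbitrary fractional shifts
cross_power <- function(ref, img) {
  fr <- stats::fft(ref); fi <- stats::fft(img)
  cp <- fr * Conj(fi)
  mag <- Mod(cp)
  cp / (mag + 1e-12 * max(mag))
}

dft_upsampled <- function(cp, shifts_r, shifts_c) {
  nr <- nrow(cp); nc <- ncol(cp)
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  er <- exp(2i * pi * outer(shifts_r, fr))         # |shifts_r| x nr
  ec <- exp(2i * pi * outer(fc, shifts_c))         # nc x |shifts_c|
  Re(er %*% cp %*% ec)
}

# estimate the (dr, dc) translation of img content relative to ref:
# img(x) ~ ref(x - d); the correlation of ref against img peaks at -d
estimate_shift <- function(ref, img, upsample = 10) {
  nr <- nrow(ref); nc <- ncol(ref)
  cp <- cross_power(ref, img)
  cc <- Re(stats::fft(cp, inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  dr <- peak[1] - 1; dc <- peak[2] - 1
  if (dr > nr / 2) dr <- dr - nr
  if (dc > nc / 2) dc <- dc - nc
  if (upsample > 1) {
    step <- 1 / upsample
    sr <- dr + seq(-1, 1, by = step)
    sc <- dc + seq(-1, 1, by = step)
    surf <- dft_upsampled(cp, sr, sc)
    pk <- arrayInd(which.max(surf), dim(surf))
    dr <- sr[pk[1]]; dc <- sc[pk[2]]
  }
  c(-dr, -dc)
}

# bilinear shift of a matrix by (dr, dc); out-of-range samples replicate edges
shift_frame <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  c <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  r0 <- floor(r); r1 <- pmin(r0 + 1, nr); wr <- r - r0
  c0 <- floor(c); c1 <- pmin(c0 + 1, nc); wc <- c - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  d <- m[r1, c0, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  top <- a * (1 - rep(wc, each = nr)) + b * rep(wc, each = nr)
  bot <- d * (1 - rep(wc, each = nr)) + e * rep(wc, each = nr)
  top * (1 - wr) + bot * wr
}

#' Realign a drifting time-lapse stack by cross-correlation
#'
#' Estimates the x-y translation of every frame against a reference frame
#' by phase cross-correlation with subpixel refinement (the correlation
#' surface is re-evaluated on an upsampled grid around the integer peak),
#' then resamples each frame onto the reference grid.
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @param reference_frame Index of the reference frame (default 1).
#' @param upsample Subpixel refinement factor (default 10, i.e. 0.1 px
#'   steps).
#' @return A list with `stack` (the realigned [image_stack()]) and
#'   `drift` (frames x 2 matrix of estimated per-frame (row, col)
#'   displacement relative to the reference).
#' @export
register_stack <- function(stack, reference_frame = 1, upsample = 10) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$data)[1]
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  ref <- stack$data[reference_frame, , ]
  drift <- matrix(0, nf, 2, dimnames = list(NULL, c("drow", "dcol")))
  out <- stack$data
  degenerate <- FALSE
  for (f in seq_len(nf)) {
    frame <- stack$data[f, , ]
    if (all(frame == 0) || all(ref == 0)) {
      degenerate <- TRUE
      next
    }
    if (f == reference_frame) next
    d <- estimate_shift(ref, frame, upsample)
    drift[f, ] <- d
    out[f, , ] <- shift_frame(frame, d[1], d[2])
  }
  if (degenerate) {
    warning("degenerate registration: all-zero frame(s); zero shift kept")
  }
  list(stack = image_stack(out, stack$timestamps, stack$pixel_size),
       drift = drift)
}

#' Extract integrated-intensity traces from ROIs
#'
#' For every bouton and cell ROI, sums pixel intensities inside the mask
#' per frame (integrated density); the background ROI is reduced to its
#' per-pixel mean per frame so it can be rescaled to any ROI area.
#'
#' @param stack An [image_stack()].
#' @param rois A [roi_set()].
#' @return List with `bouton` (frames x n_bouton matrix), `cell`
#'   (frames x n_cell), `background_mean` (vector), `bouton_areas`,
#'   `cell_areas` (pixel counts) and `timestamps`.
#' @export
extract_roi_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"), inherits(rois, "roi_set"))
  d <- dim(stack$data)[2:3]
  sum_trace <- function(roi) {
    m <- roi_mask(roi, d)
    if (!any(m)) stop("empty ROI mask", call. = FALSE)
    idx <- which(m)
    nf <- dim(stack$data)[1]
    v <- vapply(seq_len(nf),
                function(f) sum(stack$data[f, , ][idx]), numeric(1))
    list(trace = v, area = length(idx))
  }
  b <- lapply(rois$bouton_rois, sum_trace)
  cl <- lapply(rois$cell_rois, sum_trace)
  bg <- sum_trace(rois$background_roi)
  list(bouton = sapply(b, `[[`, "trace"),
       cell = sapply(cl, `[[`, "trace"),
       background_mean = bg$trace / bg$area,
       bouton_areas = vapply(b, `[[`, numeric(1), "area"),
       cell_areas = vapply(cl, `[[`, numeric(1), "area"),
       timestamps = stack$timestamps)
}

#' Assemble per-bouton FRAP traces from extracted ROI series
#'
#' Pairs each bouton trace with the summed whole-cell reference and the
#' per-pixel background, carrying the ROI areas so background subtraction
#' is correctly scaled.
#'
#' @param extracted Output of [extract_roi_traces()].
#' @param bleach_index 1-based index of the first post-bleach frame.
#' @return List of [frap_trace()], one per bouton ROI.
#' @export
frap_traces_from_rois <- function(extracted, bleach_index) {
  cellsum <- if (is.matrix(extracted$cell)) rowSums(extracted$cell)
             else extracted$cell
  cellarea <- sum(extracted$cell_areas)
  b <- as.matrix(extracted$bouton)
  lapply(seq_len(ncol(b)), function(i) {
    frap_trace(extracted$timestamps, b[, i], cellsum,
               extracted$background_mean, bleach_index,
               bouton_area = extracted$bouton_areas[i],
               cell_area = cellarea)
  })
}

ebi <- function(m) EBImage::Image(t(m))          # matrix -> EBImage (x, y)
unebi <- function(img) t(EBImage::imageData(img))

#' Segment and measure presynaptic boutons in a single image
#'
#' Reproduces an edge-based bouton morphometry recipe: Sobel gradient
#' magnitude, threshold (Otsu on the edge image by default), morphological
#' closing and hole filling to turn edge rings into solid masks, connected
#' components, then per-bouton area and background-subtracted integrated
#' intensity. Background is the mean intensity outside the dilated masks.
#'
#' @param image 2-D numeric matrix.
#' @param pixel_size Micrometres per pixel.
#' @param threshold `"otsu"` or a fixed numeric threshold on the gradient
#'   magnitude.
#' @param min_size Minimum component size in pixels (default 4).
#' @param close_radius Radius of the closing brush, px.
#' @param reference_mean Optional reference-group mean integrated
#'   intensity; when given, `normalized_intensity` is reported relative to
#'   it.
#' @return Data frame with one row per bouton: `label`, `area_px`,
#'   `area_um2`, `integrated_intensity`, `normalized_intensity`.
#' @export
measure_boutons <- function(image, pixel_size = 1, threshold = "otsu",
                            min_size = 4, close_radius = 2,
                            reference_mean = NULL) {
  stopifnot(is.matrix(image))
  empty <- data.frame(label = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0),
                      integrated_intensity = numeric(0),
                      normalized_intensity = numeric(0))
  img <- ebi(image)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  ky <- t(kx)
  gx <- EBImage::filter2(img, kx, boundary = "replicate")
  gy <- EBImage::filter2(img, ky, boundary = "replicate")
  gm <- sqrt(gx^2 + gy^2)
  gmax <- max(gm)
  if (gmax <= 0) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(gm / gmax) * gmax
  } else {
    as.numeric(threshold)
  }
  bw <- gm > thr
  brush <- EBImage::makeBrush(2 * close_radius + 1, "disc")
  solid <- EBImage::fillHull(EBImage::closing(bw, brush))
  # the thresholded gradient ring straddles the true boundary; the filled
  # mask is kept (generous) for intensity integration while the area is
  # read off the mask eroded back to the ridge
  core <- unebi(EBImage::erode(solid, EBImage::makeBrush(3, "diamond"))) > 0
  lab <- unebi(EBImage::bwlabel(solid))
  core_sizes <- tabulate(lab[lab > 0 & core], nbins = max(lab))
  keep <- which(core_sizes >= min_size)
  if (length(keep) == 0) return(empty)
  dil <- unebi(EBImage::dilate(solid, EBImage::makeBrush(5, "disc"))) > 0
  bg <- if (all(dil)) 0 else mean(image[!dil])
  rows <- lapply(seq_along(keep), function(i) {
    idx <- lab == keep[i]
    a <- core_sizes[keep[i]]
    data.frame(label = i, area_px = a, area_um2 = a * pixel_size^2,
               integrated_intensity = sum(image[idx]) - bg * sum(idx),
               normalized_intensity = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference_mean)) {
    out$normalized_intensity <- out$integrated_intensity / reference_mean
  }
  out
}

#' Mean punctate-signal density of an immunostained field
#'
#' Applies a mean filter, subtracts the field background (median of the
#' filtered image), thresholds the remainder to build a selection mask
#' over the punctate signal, and reports the mean background-subtracted
#' intensity within the mask. A list of images is treated as replicate
#' fields and densities are averaged.
#'
#' @param image 2-D numeric matrix, or a list of such matrices (fields).
#' @param mean_radius Mean-filter radius in pixels (default 2).
#' @param threshold `"otsu"` or a fixed numeric value applied to the
#'   background-subtracted filtered image.
#' @return List with `mean_density`, `n_fields` and `flagged` (`TRUE` when
#'   any field produced an empty mask, whose density counts as 0).
#' @export
puncta_density <- function(image, mean_radius = 2, threshold = "otsu") {
  if (is.list(image)) {
    per <- lapply(image, puncta_density,
                  mean_radius = mean_radius, threshold = threshold)
    return(list(mean_density = mean(vapply(per, `[[`, numeric(1),
                                           "mean_density")),
                n_fields = length(per),
                flagged = any(vapply(per, `[[`, logical(1), "flagged"))))
  }
  stopifnot(is.matrix(image))
  img <- ebi(image)
  brush <- EBImage::makeBrush(2 * mean_radius + 1, "disc")
  brush <- brush / sum(brush)
  filt <- unebi(EBImage::filter2(img, brush, boundary = "replicate"))
  bg <- stats::median(filt)
  sub <- pmax(filt - bg, 0)
  smax <- max(sub)
  if (smax <= 0) {
    return(list(mean_density = 0, n_fields = 1L, flagged = TRUE))
  }
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(ebi(sub / smax)) * smax
  } else {
    as.numeric(threshold)
  }
  mask <- sub > thr
  if (!any(mask)) {
    return(list(mean_density = 0, n_fields = 1L, flagged = TRUE))
  }
  list(mean_density = mean(image[mask] - bg), n_fields = 1L,
       flagged = FALSE)
}
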