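#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' The TIFF stores 32-bit float pages rescaled to `[0, 1]`; the sidecar
#' (`<path>.json`) records the rescaling factor, per-frame timestamps and
#' the pixel size, so `read_stack_tiff()` restores the calibrated stack.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(stack$data, 1e-12)
  nf <- dim(stack$data)[1]
  pages <- lapply(seq_len(nf), function(f) stack$data[f, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(scale = scale, timestamps = stack$timestamps,
                            pixel_size = stack$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(0, c(length(pages), dim(pages[[1]])))
  for (f in seq_along(pages)) data[f, , ] <- pages[[f]] * meta$scale
  image_stack(data, meta$timestamps, meta$pixel_size)
}

#' Write / read per-ROI traces as tidy CSV
#'
#' Long format with columns `frame`, `time_s`, `roi_id`, `series`
#' (`bouton` / `cell` / `background`), `value`.
#'
#' @param traces A list of [frap_trace()] objects.
#' @param path CSV path.
#' @return `path` invisibly; `read_frap_traces_csv()` returns the list of
#'   [frap_trace()] objects (areas restored from the attributes columns).
#' @export
write_frap_traces_csv <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    nf <- length(tr$timestamps)
    data.frame(frame = rep(seq_len(nf), 3),
               time_s = rep(tr$timestamps, 3),
               roi_id = i,
               series = rep(c("bouton", "cell", "background"), each = nf),
               value = c(tr$bouton_raw, tr$cell_reference_raw,
                         tr$background_raw),
               bleach_index = tr$bleach_index,
               bouton_area = tr$bouton_area, cell_area = tr$cell_area)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_traces_csv
#' @export
read_frap_traces_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$roi_id), function(g) {
    b <- g[g$series == "bouton", ]
    frap_trace(b$time_s, b$value, g$value[g$series == "cell"],
               g$value[g$series == "background"], b$bleach_index[1],
               bouton_area = b$bouton_area[1], cell_area = b$cell_area[1])
  })
}

#' Serialize a double-exponential fit or F-test result to JSON
#'
#' @param x A `double_exp_fit` or `f_test_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  to_list <- function(fit) {
    list(plateau = fit$plateau, fast_fraction = fit$fast_fraction,
         half_fast_s = fit$half_fast, half_slow_s = fit$half_slow,
         residual_ss = fit$residual_ss, n_points = fit$n_points,
         n_params = fit$n_params, mode = fit$mode,
         flags = as.list(fit$flags))
  }
  obj <- if (inherits(x, "double_exp_fit")) {
    to_list(x)
  } else if (inherits(x, "f_test_result")) {
    list(f_ratio = x$f_ratio, df_num = x$df_num, df_den = x$df_den,
         p_value = x$p_value, ss_shared = x$ss_shared,
         ss_separate = x$ss_separate, verdict = x$verdict,
         alpha = x$alpha, shared_fit = to_list(x$shared_fit),
         group_fits = lapply(x$group_fits, to_list))
  } else {
    stop("unsupported object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write detected miniature events as CSV
#'
#' @param events Data frame from [detect_events()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
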