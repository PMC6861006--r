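#' Run a configuration-driven analysis pipeline
#'
#' Executes the stages of a YAML-described run in order, threading a
#' single seed through every stochastic stage and writing each output
#' file with a JSON provenance record (configuration hash, seed, package
#' and R versions), so that identical configuration + seed reproduce
#' identical outputs byte for byte.
#'
#' Supported stages:
#' * `frap_sim` - simulate FRAP trace groups (`groups:` list of
#'   `name`/`plateau`/`fast_fraction`/`half_fast`/`half_slow`, plus
#'   `n_traces`, `noise_sd`); writes one traces CSV per group.
#' * `frap_normalize` - normalize and QC the simulated (or loaded) traces.
#' * `load_traces` - read trace CSVs (`files:` named list).
#' * `extract_traces` - extract traces from a stack TIFF
#'   (`stack:`, `rois:` a JSON of circle ROIs, `bleach_index:`).
#' * `frap_fit` - per-group double-exponential fits (`mode:`).
#' * `frap_ftest` - extra sum-of-squares F test across all groups
#'   (`alpha:`).
#' * `timepoint` - group comparison at a fixed time (`query_time:`,
#'   `test:`).
#' * `report` - figures and group tables via [make_report()].
#'
#' @param config Path to a YAML file, or an equivalent list, with fields
#'   `seed`, `out_dir` (optional, overridden by `out_dir` argument) and
#'   `stages` (list of stage blocks, each with a `stage` name).
#' @param out_dir Output directory (created if missing).
#' @return A run report: list with `outputs` (paths written), `state`
#'   (in-memory stage products) and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg_file <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov <- list(config_hash = unname(tools::md5sum(cfg_file)), seed = seed,
               svpool_version = as.character(utils::packageVersion("svpool")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  outputs <- character(0)
  emit <- function(path) {
    jsonlite::write_json(c(prov, list(file = basename(path))),
                         paste0(path, ".prov.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }
  state <- list()
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    name <- st$stage
    res <- tryCatch(switch(name,
      frap_sim = {
        traces <- list()
        for (gi in seq_along(st$groups)) {
          g <- st$groups[[gi]]
          cfg <- frap_sim_config(
            recovery_model = recovery_model(
              g$plateau %||% 0.7, g$fast_fraction %||% 0.4,
              g$half_fast %||% 60, g$half_slow %||% 1200),
            noise_sd = st$noise_sd %||% 0.05,
            n_boutons = st$n_traces %||% 20,
            seed = seed + gi)
          sim <- simulate_frap_trace(cfg)
          traces[[g$name %||% paste0("group", gi)]] <- sim$traces
          emit(write_frap_traces_csv(
            sim$traces,
            file.path(out_dir, paste0("traces_", g$name %||% gi, ".csv"))))
        }
        state$raw_traces <- traces
        NULL
      },
      load_traces = {
        if (is.null(st$files)) stop("no trace files listed")
        tr <- lapply(st$files, function(f) {
          if (!file.exists(f)) stop("missing traces file: ", f)
          read_frap_traces_csv(f)
        })
        state$raw_traces <- tr
        NULL
      },
      extract_traces = {
        if (is.null(st$stack) || !file.exists(st$stack)) {
          stop("missing stack: ", st$stack %||% "<unset>")
        }
        stack <- read_stack_tiff(st$stack)
        rois_js <- jsonlite::read_json(st$rois, simplifyVector = FALSE)
        mk <- function(r) roi_circle(c(r$row, r$col), r$radius)
        rois <- roi_set(lapply(rois_js$boutons, mk),
                        list(mk(rois_js$cell)), mk(rois_js$background))
        ex <- extract_roi_traces(stack, rois)
        state$raw_traces <- list(
          extracted = frap_traces_from_rois(ex, st$bleach_index))
        NULL
      },
      frap_normalize = {
        if (is.null(state$raw_traces)) stop("no traces to normalize")
        state$norm_traces <- lapply(state$raw_traces, function(g) {
          lapply(g, normalize_trace)
        })
        NULL
      },
      frap_fit = {
        if (is.null(state$norm_traces)) stop("no normalized traces")
        fits <- lapply(state$norm_traces, fit_double_exponential,
                       mode = st$mode %||% "pooled")
        state$fits <- fits
        for (nm in names(fits)) {
          emit(write_fit_json(fits[[nm]],
                              file.path(out_dir,
                                        paste0("fit_", nm, ".json"))))
        }
        NULL
      },
      frap_ftest = {
        if (is.null(state$norm_traces)) stop("no normalized traces")
        ft <- extra_ss_f_test(state$norm_traces,
                              mode = st$mode %||% "pooled",
                              alpha = st$alpha %||% 0.05)
        state$ftest <- ft
        emit(write_fit_json(ft, file.path(out_dir, "ftest.json")))
        NULL
      },
      timepoint = {
        if (is.null(state$norm_traces)) stop("no normalized traces")
        tp <- recovery_at_timepoint(state$norm_traces,
                                    query_time = st$query_time %||% 4080,
                                    test = st$test %||% "t")
        state$timepoint <- tp
        df <- tp$summary
        if (!is.null(tp$p_value)) df$p_value <- tp$p_value
        emit({
          utils::write.csv(df, file.path(out_dir, "timepoint.csv"),
                           row.names = FALSE)
          file.path(out_dir, "timepoint.csv")
        })
        NULL
      },
      report = {
        rep <- make_report(state, out_dir,
                           n_cultures = st$n_cultures %||% NA)
        outputs <- c(outputs, rep$outputs)
        NULL
      },
      stop("unknown stage: ", name)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
  }
  list(outputs = outputs, state = state, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render figures and group tables from pipeline products
#'
#' Writes a recovery-curve figure (group mean traces with the fitted
#' double-exponential models overlaid) and a group-comparison table with
#' mean +/- SEM, n (traces / cells) and N (independent cultures, when
#' supplied), mirroring the standard presentation of FRAP group
#' comparisons.
#'
#' @param state Pipeline state (list with `norm_traces`, `fits`, and
#'   optionally `ftest` / `timepoint`), e.g. `run_pipeline(...)$state`.
#' @param out_dir Output directory.
#' @param n_cultures Optional named vector/list: independent replicates
#'   per group for the N column.
#' @return List with `outputs` (paths written); empty (with a warning)
#'   when there is nothing to report.
#' @export
make_report <- function(state, out_dir, n_cultures = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(state$norm_traces) || length(state$norm_traces) == 0) {
    warning("nothing to report: no normalized traces in state")
    return(list(outputs = character(0)))
  }
  outputs <- character(0)
  groups <- state$norm_traces
  mean_df <- do.call(rbind, lapply(names(groups), function(nm) {
    pts <- pool_points(groups[[nm]], "averaged")
    data.frame(group = nm, t = pts$t, value = pts$v)
  }))
  fig <- ggplot2::ggplot(mean_df,
                         ggplot2::aes(x = t / 60, y = value,
                                      colour = group)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "time after bleach (min)",
                  y = "normalized fluorescence recovery") +
    ggplot2::theme_classic()
  if (!is.null(state$fits)) {
    tmax <- max(mean_df$t)
    curve_df <- do.call(rbind, lapply(names(state$fits), function(nm) {
      tt <- seq(0, tmax, length.out = 200)
      data.frame(group = nm, t = tt,
                 value = predict_double_exp(state$fits[[nm]], tt))
    }))
    fig <- fig + ggplot2::geom_line(data = curve_df)
  }
  fig_path <- file.path(out_dir, "recovery_curves.pdf")
  suppressMessages(ggplot2::ggsave(fig_path, fig, width = 6, height = 4))
  outputs <- c(outputs, fig_path)

  tab <- do.call(rbind, lapply(names(groups), function(nm) {
    last <- vapply(groups[[nm]], function(x) {
      utils::tail(x$values, 1)
    }, numeric(1))
    nn <- if (!is.null(names(n_cultures))) n_cultures[[nm]] %||% NA
          else NA
    data.frame(group = nm, n = length(last),
               N = if (length(n_cultures) == 1 && is.na(n_cultures)) NA
                   else nn,
               mean_final_recovery = mean(last),
               sem = stats::sd(last) / sqrt(length(last)))
  }))
  if (!is.null(state$ftest)) {
    tab$test <- "extra-SS F"
    tab$statistic <- state$ftest$f_ratio
    tab$p_value <- state$ftest$p_value
  }
  tab_path <- file.path(out_dir, "group_table.csv")
  utils::write.csv(tab, tab_path, row.names = FALSE)
  outputs <- c(outputs, tab_path)
  list(outputs = outputs)
}
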