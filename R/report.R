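#' Experiment configuration
#'
#' Bundles everything one full analysis needs: which observer to build and
#' with what parameters, the GA settings, the measure settings and the
#' master seed. Round-trips losslessly through YAML with
#' [write_experiment_config()] / [read_experiment_config()].
#'
#' @param observer_kind One of `"bouma_pooling"`, `"popcode"`,
#'   `"grouping_two_stage"`.
#' @param observer_params Named list overriding the observer constructor's
#'   defaults. For the grouping observer, `stage_kind` (default
#'   `"bouma_pooling"`) and `stage_params` select the interference stage.
#' @param ga A [ga_config()].
#' @param alpha Significance level of the selection measure.
#' @param distances,proportions,n_runs Settings of the sparse and
#'   proportion measures.
#' @param target_accuracy,p_vertical Calibration settings.
#' @param seed Master integer seed.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(observer_kind = "grouping_two_stage",
                              observer_params = list(),
                              ga = ga_config(), alpha = 0.05,
                              distances = seq(0.75, 4.5, by = 0.75),
                              proportions = seq(0, 1, by = 0.2),
                              n_runs = 100, target_accuracy = 0.67,
                              p_vertical = 0.3, seed = 1L, out_dir = NULL) {
  observer_kind <- match.arg(observer_kind,
                             c("bouma_pooling", "popcode",
                               "grouping_two_stage"))
  stopifnot(inherits(ga, "ga_config"), alpha > 0, alpha < 1, n_runs >= 1)
  structure(list(observer_kind = observer_kind,
                 observer_params = observer_params, ga = ga,
                 alpha = as.numeric(alpha),
                 distances = as.numeric(distances),
                 proportions = as.numeric(proportions),
                 n_runs = as.integer(n_runs),
                 target_accuracy = as.numeric(target_accuracy),
                 p_vertical = as.numeric(p_vertical),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  obj <- unclass(config)
  obj$ga <- unclass(obj$ga)
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  ga <- do.call(ga_config, obj$ga)
  obj$ga <- NULL
  obj$observer_params <- as.list(obj$observer_params)
  do.call(experiment_config, c(obj, list(ga = ga)))
}

#' Build an observer from a config
#'
#' @param config An `experiment_config` (or observer kind string).
#' @param params Parameter overrides when `config` is a kind string.
#' @return A `crowding_observer`.
#' @export
build_observer <- function(config, params = list()) {
  if (inherits(config, "experiment_config")) {
    params <- config$observer_params
    kind <- config$observer_kind
  } else kind <- config
  if (kind == "bouma_pooling")
    return(do.call(bouma_pooling_observer, params))
  if (kind == "popcode")
    return(do.call(popcode_observer, params))
  stage_kind <- params$stage_kind %||% "bouma_pooling"
  stage_params <- params$stage_params %||% list()
  params$stage_kind <- NULL
  params$stage_params <- NULL
  params$stage <- build_observer(stage_kind, stage_params)
  do.call(grouping_observer, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the configured observer and write the result
#'
#' Runs [calibrate_noise()] under the config's seed and writes the
#' calibrated parameters, the achieved accuracy and the seed to a YAML
#' file. Re-running with the same config is byte-identical. On calibration
#' failure (target above the observer's ceiling) no file is written.
#'
#' @param config An [experiment_config()].
#' @param path Output YAML path.
#' @return The calibrated observer, invisibly.
#' @export
calibrate_to_file <- function(config, path) {
  observer <- build_observer(config)
  set.seed(subseed(config$seed, 101L))
  observer <- calibrate_noise(observer, p_vertical = config$p_vertical,
                              target_accuracy = config$target_accuracy)
  cal <- attr(observer, "calibration")
  yaml::write_yaml(list(
    observer_kind = config$observer_kind,
    observer_params = config$observer_params,
    noise_sd = observer$noise_sd,
    achieved_accuracy = cal$achieved_accuracy,
    p_vertical = cal$p_vertical,
    target_accuracy = cal$target_accuracy,
    seed = config$seed), path, precision = 12)
  invisible(observer)
}

#' Run the complete analysis for one observer
#'
#' Calibrates the configured observer, runs the fitness-driven GA and the
#' matched neutral condition (`n_subjects x n_sessions` sessions each),
#' computes all four measures and a summary report with the qualitative
#' pass/fail flags: `performance_pass` (generation 1 to 6 improvement of at
#' least 10 accuracy points) and `selection_local_pass` (every significant
#' slot of the selection map within 1.1 deg of the target; when it fails
#' the offending slots are listed). If `config$out_dir` is set, all
#' artifacts (config, calibration, measure CSVs, summary JSON) are written
#' there.
#'
#' Note that with the map's uncorrected per-slot alpha of 0.05, around 5%
#' of causally irrelevant slots are expected to be flagged by chance, so
#' `selection_local_pass` is a demanding criterion; the `effect` column
#' separates strong systematic slots from alpha-rate scatter.
#'
#' @param config An [experiment_config()].
#' @return A list of class `crowding_experiment` with elements `observer`,
#'   `ga`, `neutral`, `performance`, `selection`, `sparse`, `proportion`,
#'   `summary` and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$ga$n_subjects < 1)
    stop("config requires at least one subject", call. = FALSE)
  observer <- build_observer(config)
  set.seed(subseed(config$seed, 101L))
  observer <- calibrate_noise(observer, p_vertical = config$p_vertical,
                              target_accuracy = config$target_accuracy)

  cfg_fit <- config$ga
  cfg_fit$selection_mode <- "fitness"
  cfg_neu <- config$ga
  cfg_neu$selection_mode <- "neutral"
  ga <- run_condition(observer, cfg_fit, seed = subseed(config$seed, 1L))
  neutral <- run_condition(observer, cfg_neu, seed = subseed(config$seed, 2L))

  performance <- performance_measure(ga)
  selection <- selection_measure(ga, neutral, alpha = config$alpha)
  set.seed(subseed(config$seed, 3L))
  sparse <- sparse_measure(observer, distances = config$distances,
                           n_runs = config$n_runs)
  set.seed(subseed(config$seed, 4L))
  proportion <- proportion_measure(observer, proportions = config$proportions,
                                   n_runs = config$n_runs)

  improvement <- performance$mean_accuracy[nrow(performance)] -
    performance$mean_accuracy[1]
  offending <- selection[selection$significant & selection$dist_deg > 1.1, ]
  summary <- list(
    observer_kind = config$observer_kind,
    calibrated_noise_sd = observer$noise_sd,
    calibrated_accuracy = attr(observer, "calibration")$achieved_accuracy,
    improvement_points = 100 * improvement,
    performance_pass = improvement >= 0.10,
    n_significant_slots = sum(selection$significant),
    max_significant_dist_deg =
      if (any(selection$significant)) max(selection$dist_deg[selection$significant]) else 0,
    selection_local_pass = nrow(offending) == 0,
    offending_slots = offending[, c("row", "col", "dist_deg", "p", "effect")],
    seed = config$seed)

  result <- structure(list(observer = observer, ga = ga, neutral = neutral,
                           performance = performance, selection = selection,
                           sparse = sparse, proportion = proportion,
                           summary = summary, config = config),
                      class = "crowding_experiment")
  if (!is.null(config$out_dir)) write_experiment_files(result)
  result
}

write_experiment_files <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(result$config$out_dir, f)
  write_experiment_config(result$config, p("config.yaml"))
  write_measure_csv(result$performance, p("performance.csv"))
  write_measure_csv(result$selection, p("selection_map.csv"))
  write_measure_csv(result$sparse, p("sparse.csv"))
  write_measure_csv(result$proportion, p("proportion.csv"))
  utils::write.csv(ga_summary(result$ga), p("ga_summary.csv"),
                   row.names = FALSE)
  summ <- result$summary
  summ$offending_slots <- as.data.frame(summ$offending_slots)
  jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(result$config$out_dir)
}

#' @export
print.crowding_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<crowding_experiment> %s observer (noise_sd %.4g, calibrated %.3f)\n",
              s$observer_kind, s$calibrated_noise_sd, s$calibrated_accuracy))
  cat(sprintf("  performance: %+.1f points gen 1 -> %d [%s]\n",
              s$improvement_points, x$config$ga$n_generations,
              if (s$performance_pass) "pass" else "fail"))
  cat(sprintf("  selection radius <= 1.1 deg: %d significant slots, max dist %.2f deg [%s]\n",
              s$n_significant_slots, s$max_significant_dist_deg,
              if (s$selection_local_pass) "pass" else "fail"))
  invisible(x)
}

## ---- rendering ------------------------------------------------------------

#' Plot a selection map as a red/blue heatmap
#'
#' Red marks slots where the GA favoured horizontal flankers (effect < 0),
#' blue where it favoured vertical; intensity is the effect size. By
#' default only significant slots are coloured (non-significant slots stay
#' white), mirroring the thresholded map; `threshold = FALSE` gives the
#' fine-grained unthresholded variant. The target slot is marked with a
#' cross.
#'
#' @param map A `selection_map`.
#' @param threshold Colour only significant slots?
#' @return A ggplot object.
#' @export
plot_selection_map <- function(map, threshold = TRUE) {
  stopifnot(inherits(map, "selection_map"))
  g <- attr(map, "geometry")
  df <- as.data.frame(map)
  df$shown <- if (threshold) ifelse(df$significant, df$effect, 0) else df$effect
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = shown)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#c0392b", mid = "white",
                                  high = "#2980b9", midpoint = 0,
                                  name = "effect\n(GA - neutral)") +
    ggplot2::annotate("point", x = g$target_col, y = g$target_row,
                      shape = 4, size = 3) +
    ggplot2::scale_y_reverse(breaks = seq_len(g$n_rows)) +
    ggplot2::scale_x_continuous(breaks = seq_len(g$n_cols)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot a measure curve with its dispersion band
#'
#' @param curve A `measure_curve`.
#' @return A ggplot object.
#' @export
plot_measure_curve <- function(curve) {
  stopifnot(inherits(curve, "measure_curve"))
  df <- as.data.frame(curve)
  has_class <- "flanker_class" %in% names(df)
  aes <- if (has_class)
    ggplot2::aes(x = abscissa, y = mean_accuracy,
                 colour = flanker_class, fill = flanker_class)
  else
    ggplot2::aes(x = abscissa, y = mean_accuracy)
  pl <- ggplot2::ggplot(df, aes) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_accuracy - sd,
                                      ymax = mean_accuracy + sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = attr(curve, "abscissa") %||% "abscissa",
                  y = "proportion correct") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  unf <- attr(curve, "unflanked")
  if (!is.null(unf))
    pl <- pl + ggplot2::geom_hline(yintercept = unf[["mean"]],
                                   linetype = "dotted")
  pl
}

#' Render a measure CSV file to a PNG figure
#'
#' Detects the file type from its columns (a selection map has `effect`,
#' curves have `mean_accuracy`) and writes the corresponding figure.
#'
#' @param csv_path Input CSV produced by [write_measure_csv()].
#' @param out_path Output PNG path.
#' @param width,height,dpi Figure size.
#' @return `out_path`, invisibly.
#' @export
render_file <- function(csv_path, out_path, width = 7, height = 5, dpi = 150) {
  df <- tryCatch(utils::read.csv(csv_path),
                 error = function(e) stop("cannot parse ", csv_path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (all(c("row", "col", "effect", "p") %in% names(df))) {
    map <- tibble::as_tibble(df)
    class(map) <- c("selection_map", class(map))
    attr(map, "geometry") <- grid_geometry(n_rows = max(df$row),
                                           n_cols = max(df$col))
    pl <- plot_selection_map(map)
  } else if (all(c("abscissa", "mean_accuracy", "sd") %in% names(df))) {
    curve <- tibble::as_tibble(df)
    class(curve) <- c("measure_curve", class(curve))
    pl <- plot_measure_curve(curve)
  } else {
    stop("unrecognised measure file (line 1: unexpected columns): ",
         csv_path, call. = FALSE)
  }
  ggplot2::ggsave(out_path, pl, width = width, height = height, dpi = dpi)
  invisible(out_path)
}
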