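#' Welch's unequal-variance t-test for two samples of proportions
#'
#' Thin wrapper around [stats::t.test()] (Welch-Satterthwaite degrees of
#' freedom) with explicit conventions for degenerate zero-variance input,
#' which arises routinely for slot proportions after GA fixation: if both
#' samples are constant and equal the result is `t = 0, p = 1`; if both are
#' constant but unequal the difference is treated as certain (`p = 0`,
#' `t = +/-Inf`).
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @return List with elements `t`, `p` (two-sided) and `df`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t needs at least 2 observations per sample", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

# Column-wise Welch test: A (n1 x S) vs B (n2 x S), same conventions as
# welch_t() applied independently per column.
welch_t_cols <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  both0 <- v1 == 0 & v2 == 0
  eq <- both0 & m1 == m2
  ne <- both0 & m1 != m2
  t[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
  t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0; df[ne] <- NA_real_
  list(t = t, p = p, df = df, mean_a = m1, mean_b = m2)
}

#' Performance measure: mean accuracy per generation
#'
#' For each generation, display fitness is averaged over displays and
#' sessions within each subject, then over subjects; the dispersion column
#' is the between-subject standard deviation.
#'
#' @param experiment A `ga_experiment` (all runs share one config).
#' @return A tibble of class `measure_curve` with columns `abscissa`
#'   (generation), `mean_accuracy`, `sd`, `n_runs`.
#' @export
performance_measure <- function(experiment) {
  stopifnot(inherits(experiment, "ga_experiment"))
  cfgs <- lapply(experiment$runs, function(r) unclass(r$config))
  if (!all(vapply(cfgs, identical, TRUE, cfgs[[1]])))
    stop("runs have mismatched configs", call. = FALSE)
  n_gen <- experiment$config$n_generations
  subjects <- sort(unique(vapply(experiment$runs, `[[`, 0L, "subject_id")))
  per_subject <- vapply(subjects, function(s) {
    runs <- Filter(function(r) r$subject_id == s, experiment$runs)
    vapply(seq_len(n_gen), function(g)
      mean(unlist(lapply(runs, function(r) r$generations[[g]]$fitness))), 0)
  }, numeric(n_gen))  # n_gen x n_subjects
  if (is.null(dim(per_subject)))
    per_subject <- matrix(per_subject, nrow = n_gen)
  out <- tibble::tibble(
    abscissa = seq_len(n_gen),
    mean_accuracy = rowMeans(per_subject),
    sd = apply(per_subject, 1, stats::sd),
    n_runs = length(subjects))
  structure(out, class = c("measure_curve", class(out)),
            measure = "performance", abscissa = "generation")
}

#' Selection measure: per-slot significance map of GA vs neutral
#'
#' For every flanker slot, the per-subject mean vertical proportion over
#' the final-generation displays (pooled across that subject's sessions)
#' under the fitness-driven GA is compared to the matched neutral
#' (random-selection) condition with a two-tailed Welch t-test at `alpha`,
#' uncorrected for multiple comparisons. The signed effect is the
#' difference of mean proportions (GA - neutral): negative values mean the
#' GA favoured horizontal flankers at that slot, positive values vertical.
#' The unthresholded `effect` column is the fine-grained variant of the
#' map; `significant` applies the `p < alpha` threshold.
#'
#' @param ga_experiment,neutral_experiment `ga_experiment`s with identical
#'   subject counts, run in `"fitness"` and `"neutral"` selection mode.
#' @param alpha Significance level (0.05, uncorrected).
#' @return A tibble of class `selection_map` with one row per flanker slot:
#'   `row`, `col`, `x_deg`, `y_deg`, `dist_deg`, `prop_ga`, `prop_neutral`,
#'   `t`, `p`, `significant`, `effect`.
#' @export
selection_measure <- function(ga_experiment, neutral_experiment,
                              alpha = 0.05) {
  stopifnot(inherits(ga_experiment, "ga_experiment"),
            inherits(neutral_experiment, "ga_experiment"))
  if (ga_experiment$config$n_subjects != neutral_experiment$config$n_subjects)
    stop("subject counts differ between conditions", call. = FALSE)
  geometry <- ga_experiment$runs[[1]]$generations[[1]]$displays[[1]]$geometry
  A <- subject_slot_proportions(ga_experiment)       # n_subjects x slots
  B <- subject_slot_proportions(neutral_experiment)
  tab <- slot_table(geometry)
  flank <- !tab$is_target
  wt <- welch_t_cols(A[, flank, drop = FALSE], B[, flank, drop = FALSE])
  out <- tibble::tibble(
    row = tab$row[flank], col = tab$col[flank],
    x_deg = tab$x_deg[flank], y_deg = tab$y_deg[flank],
    dist_deg = tab$dist_deg[flank],
    prop_ga = wt$mean_a, prop_neutral = wt$mean_b,
    t = wt$t, p = wt$p,
    significant = wt$p < alpha,
    effect = wt$mean_a - wt$mean_b)
  structure(out, class = c("selection_map", class(out)),
            alpha = alpha, geometry = geometry)
}

# n_subjects x (n_rows * n_cols) matrix of per-subject mean vertical
# proportions in the final generation, sessions pooled. Column order
# matches slot_table() (column-major over the grid).
subject_slot_proportions <- function(experiment) {
  subjects <- sort(unique(vapply(experiment$runs, `[[`, 0L, "subject_id")))
  t(vapply(subjects, function(s) {
    runs <- Filter(function(r) r$subject_id == s, experiment$runs)
    displays <- unlist(lapply(runs, function(r) {
      r$generations[[length(r$generations)]]$displays
    }), recursive = FALSE)
    acc <- Reduce(`+`, lapply(displays, function(d) {
      v <- d$vertical; v[is.na(v)] <- 0; v + 0
    }))
    as.vector(acc) / length(displays)
  }, numeric(experiment$runs[[1]]$generations[[1]]$displays[[1]]$geometry$n_rows *
               experiment$runs[[1]]$generations[[1]]$displays[[1]]$geometry$n_cols)))
}

#' Sparse-display measure: accuracy vs target-flanker distance
#'
#' The Bouma's-law probe: accuracy of the observer on sparse displays
#' (four same-class flankers at the cardinal offsets) as a function of
#' centre-to-centre distance, for vertical and horizontal flanker classes,
#' plus the unflanked baseline. Each of the `n_runs` runs scores every
#' condition with `n_trials` fresh trials.
#'
#' @param observer A calibrated `crowding_observer`.
#' @param distances Target-flanker distances in degrees.
#' @param n_runs Number of independent runs (100 by default).
#' @param n_trials Trials per condition per run.
#' @param geometry A [grid_geometry()].
#' @return A tibble of class `measure_curve` with columns `abscissa`
#'   (distance), `flanker_class`, `mean_accuracy`, `sd`, `n_runs`;
#'   attribute `"unflanked"` holds the baseline mean and sd.
#' @export
sparse_measure <- function(observer, distances = seq(0.75, 4.5, by = 0.75),
                           n_runs = 100, n_trials = 12,
                           geometry = grid_geometry()) {
  stopifnot(n_runs >= 1, all(distances > 0))
  distances <- sort(distances)
  classes <- c("vertical", "horizontal")
  acc <- array(NA_real_, c(n_runs, length(distances), length(classes)))
  base <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    for (ci in seq_along(classes)) {
      for (di in seq_along(distances)) {
        d <- make_sparse_display(distances[di], classes[ci],
                                 geometry = geometry)
        acc[r, di, ci] <- display_fitness(observer, d, n_trials)
      }
    }
    base[r] <- display_fitness(observer, make_unflanked_display(geometry = geometry),
                               n_trials)
  }
  m <- apply(acc, c(2, 3), mean)
  s <- apply(acc, c(2, 3), stats::sd)
  out <- tibble::tibble(
    abscissa = rep(distances, times = length(classes)),
    flanker_class = rep(classes, each = length(distances)),
    mean_accuracy = c(m[, 1], m[, 2]),
    sd = c(s[, 1], s[, 2]),
    n_runs = n_runs)
  structure(out, class = c("measure_curve", class(out)),
            measure = "sparse", abscissa = "distance_deg",
            unflanked = c(mean = mean(base), sd = stats::sd(base)))
}

#' Proportion measure: accuracy vs vertical-flanker proportion
#'
#' Accuracy on fresh random dense displays whose vertical-flanker
#' proportion steps through `proportions` (0 to 1 by 0.2 by default). Each
#' run draws a new display per proportion and scores it with `n_trials`
#' trials.
#'
#' @inheritParams sparse_measure
#' @param proportions Vertical-flanker proportions to probe.
#' @return A tibble of class `measure_curve` with columns `abscissa`
#'   (proportion), `mean_accuracy`, `sd`, `n_runs`.
#' @export
proportion_measure <- function(observer, proportions = seq(0, 1, by = 0.2),
                               n_runs = 100, n_trials = 12,
                               geometry = grid_geometry()) {
  stopifnot(n_runs >= 1, all(proportions >= 0 & proportions <= 1))
  proportions <- sort(proportions)
  acc <- matrix(NA_real_, n_runs, length(proportions))
  for (r in seq_len(n_runs)) {
    for (pi in seq_along(proportions)) {
      d <- make_dense_display(proportions[pi], geometry = geometry)
      acc[r, pi] <- display_fitness(observer, d, n_trials)
    }
  }
  out <- tibble::tibble(abscissa = proportions,
                        mean_accuracy = colMeans(acc),
                        sd = apply(acc, 2, stats::sd),
                        n_runs = n_runs)
  structure(out, class = c("measure_curve", class(out)),
            measure = "proportion", abscissa = "p_vertical")
}

#' Write a selection map or measure curve to CSV
#'
#' @param x A `selection_map` or `measure_curve`.
#' @param path Output path.
#' @export
write_measure_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
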