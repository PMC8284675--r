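#' Configuration of the genetic algorithm over dense displays
#'
#' Defaults mirror the standard procedure: 20 random displays at 30%
#' vertical flankers in generation 1; the 4 best displays (by proportion
#' correct over 12 trials) become parents; the 6 unordered parent pairs
#' each produce 2 children by uniform crossover (each flanker slot comes
#' from the first parent with probability `crossover_p`) followed by
#' mutation (each slot reassigned uniformly to vertical/horizontal with
#' probability `mutation_rate`); the 12 children constitute the next
#' generation, for 6 generations in total; the whole GA is repeated for 4
#' sessions in each of 10 simulated subjects.
#'
#' @param pop_size_gen1 Displays in generation 1.
#' @param n_parents Parents selected per generation.
#' @param n_children Children per generation (generations 2+ contain
#'   exactly these, unless `elitism` is set).
#' @param crossover_p Probability a child slot comes from the first parent.
#' @param mutation_rate Per-slot probability of uniform reassignment (the
#'   effective flip probability is `mutation_rate / 2`).
#' @param n_generations Number of generations (including the first).
#' @param n_trials_per_display Trials used to score each display.
#' @param n_sessions GA repetitions per subject.
#' @param n_subjects Simulated subjects.
#' @param p_vertical_init Vertical-flanker proportion of generation 1.
#' @param selection_mode `"fitness"` (select the best) or `"neutral"`
#'   (select parents uniformly at random - the drift-only control).
#' @param elitism If `TRUE`, parents are carried into the next generation
#'   alongside the children. Off by default: the children alone constitute
#'   the next generation.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size_gen1 = 20, n_parents = 4, n_children = 12,
                      crossover_p = 0.5, mutation_rate = 0.04,
                      n_generations = 6, n_trials_per_display = 12,
                      n_sessions = 4, n_subjects = 10,
                      p_vertical_init = 0.3,
                      selection_mode = c("fitness", "neutral"),
                      elitism = FALSE) {
  selection_mode <- match.arg(selection_mode)
  if (!(n_parents >= 2)) stop("n_parents must be >= 2", call. = FALSE)
  if (!(n_children >= n_parents))
    stop("n_children must be >= n_parents", call. = FALSE)
  stopifnot(pop_size_gen1 >= n_parents, crossover_p >= 0, crossover_p <= 1,
            mutation_rate >= 0, mutation_rate <= 1, n_generations >= 1,
            n_trials_per_display >= 1, n_sessions >= 1, n_subjects >= 1,
            p_vertical_init >= 0, p_vertical_init <= 1)
  structure(list(pop_size_gen1 = as.integer(pop_size_gen1),
                 n_parents = as.integer(n_parents),
                 n_children = as.integer(n_children),
                 crossover_p = crossover_p, mutation_rate = mutation_rate,
                 n_generations = as.integer(n_generations),
                 n_trials_per_display = as.integer(n_trials_per_display),
                 n_sessions = as.integer(n_sessions),
                 n_subjects = as.integer(n_subjects),
                 p_vertical_init = p_vertical_init,
                 selection_mode = selection_mode, elitism = elitism),
            class = "ga_config")
}

#' Score one display: proportion correct over n trials
#'
#' Each trial draws a fresh fair-coin target sign and fresh observer noise;
#' the flanker genome is fixed. The value lies on the lattice
#' `{0, 1/n, ..., 1}`.
#'
#' @param observer A calibrated `crowding_observer`.
#' @param display A display object.
#' @param n_trials Number of trials (12 by default).
#' @return Proportion of correct responses.
#' @export
display_fitness <- function(observer, display, n_trials = 12) {
  stopifnot(n_trials >= 1)
  mean(simulate_trials(observer, display, n_trials))
}

#' Select parent displays from a generation
#'
#' In `"fitness"` mode the `n_parents` highest-fitness displays are chosen,
#' ties broken uniformly at random; in `"neutral"` mode parents are drawn
#' uniformly without replacement, ignoring fitness entirely.
#'
#' @param displays List of displays.
#' @param fitness Numeric fitness values, one per display.
#' @param mode `"fitness"` or `"neutral"`.
#' @param n_parents Number of parents.
#' @return Integer indices of the selected parents.
#' @export
select_parents <- function(displays, fitness, mode = c("fitness", "neutral"),
                           n_parents = 4) {
  mode <- match.arg(mode)
  if (length(displays) < n_parents)
    stop("fewer displays than parents requested", call. = FALSE)
  if (mode == "neutral")
    return(sample.int(length(displays), n_parents))
  stopifnot(length(fitness) == length(displays))
  # random tie-breaking: secondary sort key drawn from the stream
  order(-fitness, stats::runif(length(fitness)))[seq_len(n_parents)]
}

#' Uniform crossover of two dense-display genomes
#'
#' Each of the 284 flanker slots is copied independently from `parent_a`
#' with probability `crossover_p`, otherwise from `parent_b`. The target
#' slot is untouched; the child inherits `parent_a`'s target sign.
#'
#' @param parent_a,parent_b `dense_display`s sharing a geometry.
#' @param crossover_p Probability a slot comes from `parent_a`.
#' @return A child `dense_display`.
#' @export
crossover <- function(parent_a, parent_b, crossover_p = 0.5) {
  stopifnot(inherits(parent_a, "dense_display"),
            inherits(parent_b, "dense_display"))
  if (!identical(unclass(parent_a$geometry), unclass(parent_b$geometry)))
    stop("parents have mismatched geometries", call. = FALSE)
  g <- parent_a$geometry
  from_a <- matrix(stats::runif(g$n_rows * g$n_cols) < crossover_p,
                   g$n_rows, g$n_cols)
  v <- ifelse(from_a, parent_a$vertical, parent_b$vertical)
  v[g$target_row, g$target_col] <- NA
  new_dense_display(g, v, parent_a$target_sign)
}

#' Mutate a dense-display genome
#'
#' Each flanker slot is, with probability `rate`, re-assigned uniformly at
#' random to vertical or horizontal (so the probability that a slot
#' actually flips is `rate / 2`).
#'
#' @param display A `dense_display`.
#' @param rate Per-slot reassignment probability.
#' @return The mutated display.
#' @export
mutate_display <- function(display, rate = 0.04) {
  stopifnot(inherits(display, "dense_display"), rate >= 0, rate <= 1)
  g <- display$geometry
  n <- g$n_rows * g$n_cols
  hit <- matrix(stats::runif(n) < rate, g$n_rows, g$n_cols)
  new_val <- matrix(stats::runif(n) < 0.5, g$n_rows, g$n_cols)
  v <- ifelse(hit, new_val, display$vertical)
  v[g$target_row, g$target_col] <- NA
  new_dense_display(g, v, display$target_sign)
}

#' Produce the next generation from the selected parents
#'
#' The `choose(n_parents, 2)` unordered parent pairs each contribute
#' `n_children / choose(n_parents, 2)` children (2 with the defaults):
#' uniform crossover followed by mutation. Pairing is deterministic in
#' structure; all stochasticity is in the crossover/mutation draws.
#'
#' @param parents List of parent `dense_display`s.
#' @param config A [ga_config()].
#' @return List of `n_children` child displays.
#' @export
next_generation <- function(parents, config) {
  np <- length(parents)
  pairs <- utils::combn(np, 2)
  per_pair <- config$n_children / ncol(pairs)
  if (per_pair != round(per_pair))
    stop("n_children must be a multiple of the number of parent pairs",
         call. = FALSE)
  children <- vector("list", config$n_children)
  k <- 0
  for (p in seq_len(ncol(pairs))) {
    for (j in seq_len(per_pair)) {
      k <- k + 1
      child <- crossover(parents[[pairs[1, p]]], parents[[pairs[2, p]]],
                         config$crossover_p)
      children[[k]] <- mutate_display(child, config$mutation_rate)
    }
  }
  children
}

#' Run one GA session
#'
#' Generation 1 is `pop_size_gen1` random displays at `p_vertical_init`;
#' each subsequent generation selects parents (by fitness or neutrally per
#' `config$selection_mode`), breeds children and scores them. Every display
#' is scored with `n_trials_per_display` fresh trials.
#'
#' @param observer A calibrated `crowding_observer`.
#' @param config A [ga_config()].
#' @param seed Optional integer seed; if given, the run is bit-reproducible.
#' @param subject_id,session_id Identifiers recorded in the result.
#' @param geometry A [grid_geometry()].
#' @return An object of class `ga_run`: list with `generations` (each a
#'   list of `displays` and `fitness`), `config`, ids and the seed record.
#' @export
run_ga <- function(observer, config = ga_config(), seed = NULL,
                   subject_id = 1L, session_id = 1L,
                   geometry = grid_geometry()) {
  stopifnot(inherits(config, "ga_config"))
  if (!is.null(seed)) set.seed(seed)
  score <- function(displays)
    vapply(displays, function(d)
      display_fitness(observer, d, config$n_trials_per_display), 0)

  displays <- replicate(config$pop_size_gen1,
                        make_dense_display(config$p_vertical_init,
                                           geometry = geometry),
                        simplify = FALSE)
  fitness <- score(displays)
  generations <- list(list(displays = displays, fitness = fitness))

  for (g in seq_len(config$n_generations - 1)) {
    idx <- select_parents(displays, fitness, config$selection_mode,
                          config$n_parents)
    parents <- displays[idx]
    children <- next_generation(parents, config)
    if (config$elitism) children <- c(parents, children)
    displays <- children
    fitness <- score(displays)
    generations[[g + 1]] <- list(displays = displays, fitness = fitness)
  }
  structure(list(generations = generations, config = config,
                 subject_id = as.integer(subject_id),
                 session_id = as.integer(session_id),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  means <- vapply(x$generations, function(g) mean(g$fitness), 0)
  cat(sprintf("<ga_run> subject %d session %d (%s selection): mean fitness %s\n",
              x$subject_id, x$session_id, x$config$selection_mode,
              paste(sprintf("%.2f", means), collapse = " -> ")))
  invisible(x)
}

#' Run the full multi-subject, multi-session GA condition
#'
#' Repeats [run_ga()] for `n_subjects x n_sessions` independent sessions.
#' Session seeds are derived deterministically from `seed` (see
#' [subseed()]), so the whole condition is bit-reproducible and any single
#' session can be replayed in isolation.
#'
#' @inheritParams run_ga
#' @param seed Master integer seed for the condition.
#' @return An object of class `ga_experiment`: list of `ga_run`s plus the
#'   config and master seed.
#' @export
run_condition <- function(observer, config = ga_config(), seed = 1L,
                          geometry = grid_geometry()) {
  runs <- list()
  for (subject in seq_len(config$n_subjects)) {
    for (session in seq_len(config$n_sessions)) {
      runs[[length(runs) + 1]] <-
        run_ga(observer, config,
               seed = subseed(seed, subject, session),
               subject_id = subject, session_id = session,
               geometry = geometry)
    }
  }
  structure(list(runs = runs, config = config, seed = as.integer(seed)),
            class = "ga_experiment")
}

#' @export
print.ga_experiment <- function(x, ...) {
  cat(sprintf("<ga_experiment> %d runs (%d subjects x %d sessions), %s selection, seed %d\n",
              length(x$runs), x$config$n_subjects, x$config$n_sessions,
              x$config$selection_mode, x$seed))
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing (multiplicative congruential steps modulo
#' 2^31 - 1) of a master seed with any number of integer keys, used to give
#' every subject x session its own replayable stream.
#'
#' @param master Master integer seed.
#' @param ... Integer keys (e.g. subject, session).
#' @return A positive integer seed below 2^31 - 1.
#' @export
subseed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (k in c(...)) {
    h <- (h * 48271 + (as.numeric(k) + 1) * 1299721) %% m
  }
  as.integer(h) + 1L
}

#' Per-run fitness summary table
#'
#' @param experiment A `ga_experiment`.
#' @return Tibble with one row per subject x session x generation: mean and
#'   best fitness.
#' @export
ga_summary <- function(experiment) {
  stopifnot(inherits(experiment, "ga_experiment"))
  rows <- lapply(experiment$runs, function(run) {
    tibble::tibble(
      subject = run$subject_id, session = run$session_id,
      generation = seq_along(run$generations),
      mean_fitness = vapply(run$generations, function(g) mean(g$fitness), 0),
      best_fitness = vapply(run$generations, function(g) max(g$fitness), 0))
  })
  do.call(rbind, rows)
}

#' Serialize a GA run (or experiment) to JSON
#'
#' Records the config, ids, seed, per-generation genomes (as the V/H/T text
#' format) and fitness vectors.
#'
#' @param run A `ga_run` or `ga_experiment`.
#' @param path Output path.
#' @export
write_ga_json <- function(run, path) {
  jsonlite::write_json(ga_to_list(run), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

ga_to_list <- function(run) {
  if (inherits(run, "ga_experiment")) {
    return(list(type = "ga_experiment", seed = run$seed,
                config = unclass(run$config),
                runs = lapply(run$runs, ga_to_list)))
  }
  list(type = "ga_run", subject_id = run$subject_id,
       session_id = run$session_id, seed = run$seed,
       config = unclass(run$config),
       generations = lapply(run$generations, function(g) {
         list(fitness = g$fitness,
              displays = lapply(g$displays, format_display))
       }))
}
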