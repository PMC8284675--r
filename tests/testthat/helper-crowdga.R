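# Displays with a fully specified genome
uniform_display <- function(p, sign = 1L) {
  make_dense_display(p, target_sign = sign)
}
all_vertical <- function(sign = 1L) make_dense_display(1, target_sign = sign)
all_horizontal <- function(sign = 1L) make_dense_display(0, target_sign = sign)

# Flip one flanker slot of a dense display
flip_slot <- function(display, row, col) {
  display$vertical[row, col] <- !display$vertical[row, col]
  display
}

# Minimal hand-built GA experiment whose final generation is produced by
# `display_fn(subject, session, i)`; used to probe the measures directly.
fake_experiment <- function(display_fn, n_subjects = 4, n_sessions = 2,
                            n_displays = 6, mode = "fitness") {
  cfg <- ga_config(pop_size_gen1 = max(4L, n_displays), n_generations = 1,
                   n_subjects = n_subjects, n_sessions = n_sessions,
                   selection_mode = mode)
  runs <- list()
  for (subject in seq_len(n_subjects)) {
    for (session in seq_len(n_sessions)) {
      displays <- lapply(seq_len(n_displays),
                         function(i) display_fn(subject, session, i))
      runs[[length(runs) + 1]] <- structure(
        list(generations = list(list(displays = displays,
                                     fitness = rep(0.5, n_displays))),
             config = cfg, subject_id = subject, session_id = session,
             seed = NA_integer_),
        class = "ga_run")
    }
  }
  structure(list(runs = runs, config = cfg, seed = 0L),
            class = "ga_experiment")
}

# Small GA config for fast unit tests
tiny_cfg <- function(...) {
  ga_config(pop_size_gen1 = 8, n_generations = 3, n_trials_per_display = 4,
            n_sessions = 1, n_subjects = 2, ...)
}
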