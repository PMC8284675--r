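test_that("display fitness lies on the k/n lattice", {
  obs <- bouma_pooling_observer(noise_sd = 1)  # near-chance observer
  set.seed(40)
  d <- make_dense_display(0.3)
  f <- replicate(50, display_fitness(obs, d, 12))
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(abs(f * 12 - round(f * 12)) < 1e-12))
  expect_lt(abs(mean(f) - 0.5), 0.1)
  expect_error(display_fitness(obs, d, 0))
})

test_that("parent selection takes the best four, ties broken uniformly", {
  set.seed(41)
  displays <- replicate(6, make_dense_display(0.3), simplify = FALSE)
  fit <- c(1.0, 0.9, 0.8, 0.7, 0.1, 0.05)
  expect_setequal(select_parents(displays, fit, "fitness"), 1:4)
  expect_error(select_parents(displays[1:3], fit[1:3], "fitness"),
               "fewer displays")

  # all fitness equal: every display equally likely to be picked
  displays <- replicate(10, make_dense_display(0.3), simplify = FALSE)
  hits <- integer(10)
  for (i in 1:2000) {
    idx <- select_parents(displays, rep(0.5, 10), "fitness")
    hits[idx] <- hits[idx] + 1
  }
  # each slot has expectation 2000 * 4/10 = 800, binomial se ~ 21.9
  expect_true(all(abs(hits - 800) < 5 * sqrt(2000 * 0.4 * 0.6)))
})

test_that("neutral selection ignores fitness entirely", {
  displays <- replicate(8, make_dense_display(0.3), simplify = FALSE)
  fit <- seq(0, 1, length.out = 8)
  set.seed(42); a <- select_parents(displays, fit, "neutral")
  set.seed(42); b <- select_parents(displays, rev(fit), "neutral")
  expect_identical(a, b)
})

test_that("crossover copies each slot from one of the two parents", {
  set.seed(43)
  pa <- make_dense_display(0.5, target_sign = 1)
  pb <- make_dense_display(0.5, target_sign = 1)

  expect_identical(crossover(pa, pa, 0.5)$vertical, pa$vertical)
  expect_identical(crossover(pa, pb, 1)$vertical, pa$vertical)
  expect_identical(crossover(pa, pb, 0)$vertical, pb$vertical)

  child <- crossover(pa, pb, 0.5)
  mix <- child$vertical == pa$vertical | child$vertical == pb$vertical
  expect_true(all(mix, na.rm = TRUE))

  # complementary parents: child vertical count ~ Binomial(284, 1/2)
  va <- all_vertical(); vb <- all_horizontal()
  counts <- replicate(300, vertical_count(crossover(va, vb, 0.5)))
  se <- sqrt(284 * 0.25 / 300)
  expect_lt(abs(mean(counts) - 142), 4 * se)

  g2 <- grid_geometry(spacing = 0.5)
  expect_error(crossover(pa, make_dense_display(0.5, geometry = g2)),
               "mismatched geometries")
})

test_that("mutation reassigns slots uniformly at the stated rate", {
  set.seed(44)
  d <- all_vertical()
  expect_identical(mutate_display(d, 0)$vertical, d$vertical)

  # full reassignment: half the slots stay vertical in expectation
  p1 <- mean(replicate(50, vertical_count(mutate_display(d, 1)) / 284))
  expect_lt(abs(p1 - 0.5), 0.02)

  # default 4% rate: expected vertical proportion 1 - 0.04/2 = 0.98
  p04 <- mean(replicate(200, vertical_count(mutate_display(d, 0.04)) / 284))
  expect_lt(abs(p04 - 0.98), 0.005)
})

test_that("next_generation breeds 12 children from the 6 parent pairs", {
  set.seed(45)
  cfg <- ga_config()
  parents <- replicate(4, make_dense_display(0.3, target_sign = 1),
                       simplify = FALSE)
  children <- next_generation(parents, cfg)
  expect_length(children, 12)

  # without mutation, every child slot value occurs in some parent
  cfg0 <- ga_config(mutation_rate = 0)
  children <- next_generation(parents, cfg0)
  pstack <- sapply(parents, function(p) as.vector(p$vertical))
  for (ch in children) {
    v <- as.vector(ch$vertical)
    ok <- vapply(seq_along(v), function(i)
      is.na(v[i]) || v[i] %in% pstack[i, ], TRUE)
    expect_true(all(ok))
  }

  # four identical parents, no mutation: twelve identical children
  same <- replicate(4, list(parents[[1]]))
  children <- next_generation(same, cfg0)
  for (ch in children) expect_identical(ch$vertical, parents[[1]]$vertical)
})

test_that("run_ga produces the configured lineage and is seed-reproducible", {
  obs <- bouma_pooling_observer(noise_sd = 0.01)
  cfg <- tiny_cfg()
  run <- run_ga(obs, cfg, seed = 99)
  expect_s3_class(run, "ga_run")
  expect_length(run$generations, 3)
  expect_length(run$generations[[1]]$displays, 8)
  expect_length(run$generations[[2]]$displays, 12)
  expect_true(all(vapply(run$generations, function(g)
    all(vapply(g$displays, n_flanker_slots, 0L) == 284L), TRUE)))

  run2 <- run_ga(obs, cfg, seed = 99)
  expect_identical(run, run2)

  # elitism keeps the parents alongside the children
  runE <- run_ga(obs, tiny_cfg(elitism = TRUE), seed = 99)
  expect_length(runE$generations[[2]]$displays, 16)
})

test_that("run_condition derives independent replayable session seeds", {
  obs <- bouma_pooling_observer(noise_sd = 0.01)
  cfg <- tiny_cfg()
  exp1 <- run_condition(obs, cfg, seed = 7)
  expect_length(exp1$runs, 2)
  expect_identical(run_condition(obs, cfg, seed = 7), exp1)
  # any single session can be replayed in isolation from its seed record
  r <- exp1$runs[[2]]
  replay <- run_ga(obs, cfg, seed = subseed(7, r$subject_id, r$session_id),
                   subject_id = r$subject_id, session_id = r$session_id)
  expect_identical(replay, r)
  expect_false(identical(exp1$runs[[1]]$generations,
                         exp1$runs[[2]]$generations))
})

test_that("GA runs serialize to JSON with genomes and fitness", {
  obs <- bouma_pooling_observer(noise_sd = 0.01)
  run <- run_ga(obs, tiny_cfg(), seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_ga_json(run, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(obj$type, "ga_run")
  expect_length(obj$generations, 3)
  g1 <- obj$generations[[1]]
  expect_length(g1$fitness, 8)
  expect_identical(parse_display(unlist(g1$displays[[1]])),
                   run$generations[[1]]$displays[[1]])
})
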