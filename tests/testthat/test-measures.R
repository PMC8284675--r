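test_that("welch_t matches an independent hand computation", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  b <- c(0.5, 0.6, 0.7, 0.8)
  res <- welch_t(a, b)
  # Welch formula computed from first principles
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
})

test_that("welch_t applies the zero-variance conventions", {
  expect_equal(welch_t(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))[c("t", "p")],
               list(t = 0, p = 1))
  res <- welch_t(c(0.2, 0.2, 0.2), c(0.8, 0.8, 0.8))
  expect_equal(res$p, 0)
  expect_equal(res$t, -Inf)
  expect_error(welch_t(0.5, c(0.1, 0.2)), "at least 2")
})

test_that("column-wise Welch agrees with the scalar test", {
  set.seed(50)
  A <- matrix(runif(10 * 6), 10, 6)
  B <- matrix(runif(8 * 6), 8, 6)
  A[, 6] <- 0.3; B[, 6] <- 0.3      # constant-equal column
  A[, 5] <- 0.1; B[, 5] <- 0.9      # constant-unequal column
  res <- crowdga:::welch_t_cols(A, B)
  for (j in 1:6) {
    ref <- welch_t(A[, j], B[, j])
    expect_equal(res$t[j], ref$t, tolerance = 1e-12)
    expect_equal(res$p[j], ref$p, tolerance = 1e-12)
  }
})

test_that("performance_measure averages within then across subjects", {
  # two subjects with constant, known per-run fitness
  exp <- fake_experiment(function(s, sess, i) make_dense_display(0.3),
                         n_subjects = 2, n_sessions = 2, n_displays = 3)
  exp$runs <- lapply(exp$runs, function(r) {
    r$generations[[1]]$fitness <- rep(ifelse(r$subject_id == 1, 0.4, 0.8), 3)
    r
  })
  curve <- performance_measure(exp)
  expect_s3_class(curve, "measure_curve")
  expect_equal(curve$mean_accuracy, 0.6)
  expect_equal(curve$sd, sd(c(0.4, 0.8)))
  expect_equal(curve$n_runs, 2)

  bad <- exp
  bad$runs[[1]]$config$n_trials_per_display <- 99L
  expect_error(performance_measure(bad), "mismatched configs")
})

test_that("selection_measure flags slots that diverge between conditions", {
  set.seed(51)
  # GA condition: slot (8,9) always horizontal, slot (2,2) always vertical
  ga <- fake_experiment(function(s, sess, i) {
    d <- make_dense_display(0.34)
    d$vertical[8, 9] <- FALSE
    d$vertical[2, 2] <- TRUE
    d
  }, n_subjects = 6, n_sessions = 2, n_displays = 8)
  ne <- fake_experiment(function(s, sess, i) make_dense_display(0.34),
                        n_subjects = 6, n_sessions = 2, n_displays = 8,
                        mode = "neutral")
  map <- selection_measure(ga, ne, alpha = 0.05)
  expect_s3_class(map, "selection_map")
  expect_equal(nrow(map), 284)
  expect_false(any(map$row == 8 & map$col == 8))
  expect_true(all(map$prop_ga >= 0 & map$prop_ga <= 1))
  expect_true(all(map$significant == (map$p < 0.05), na.rm = TRUE))

  horiz <- map[map$row == 8 & map$col == 9, ]
  expect_true(horiz$significant)
  expect_lt(horiz$effect, 0)   # horizontal favoured
  expect_equal(horiz$prop_ga, 0)
  vert <- map[map$row == 2 & map$col == 2, ]
  expect_true(vert$significant)
  expect_gt(vert$effect, 0)    # vertical favoured

  # t/p agree with the scalar welch_t applied to the same observations
  A <- crowdga:::subject_slot_proportions(ga)
  B <- crowdga:::subject_slot_proportions(ne)
  j <- which(slot_table(grid_geometry())$row == 8 &
               slot_table(grid_geometry())$col == 9)
  ref <- welch_t(A[, j], B[, j])
  expect_equal(horiz$t, ref$t, tolerance = 1e-12)
  expect_equal(horiz$p, ref$p, tolerance = 1e-12)

  # constant-and-equal slots are never significant
  ga2 <- ga
  ga2$runs <- lapply(ga2$runs, function(r) {
    r$generations[[1]]$displays <- lapply(r$generations[[1]]$displays,
                                          function(d) { d$vertical[1, 1] <- TRUE; d })
    r
  })
  ne2 <- ne
  ne2$runs <- lapply(ne2$runs, function(r) {
    r$generations[[1]]$displays <- lapply(r$generations[[1]]$displays,
                                          function(d) { d$vertical[1, 1] <- TRUE; d })
    r
  })
  map2 <- selection_measure(ga2, ne2)
  expect_false(map2$significant[map2$row == 1 & map2$col == 1])

  small <- fake_experiment(function(s, sess, i) make_dense_display(0.3),
                           n_subjects = 3)
  expect_error(selection_measure(ga, small), "subject counts")
})

test_that("sparse_measure traces accuracy against flanker distance", {
  obs <- bouma_pooling_observer(noise_sd = 0)
  set.seed(52)
  curve <- sparse_measure(obs, n_runs = 3)
  expect_equal(unique(curve$abscissa), seq(0.75, 4.5, by = 0.75))
  expect_setequal(unique(curve$flanker_class), c("vertical", "horizontal"))
  # noise-free pooling observer is always correct regardless of dilution
  expect_true(all(curve$mean_accuracy == 1))
  unf <- attr(curve, "unflanked")
  expect_equal(unname(unf["mean"]), 1)
  expect_true(all(diff(curve$abscissa[curve$flanker_class == "vertical"]) > 0))
})

test_that("proportion_measure probes the stated vertical proportions", {
  obs <- bouma_pooling_observer(noise_sd = 0.004)
  set.seed(53)
  curve <- proportion_measure(obs, n_runs = 40)
  expect_equal(curve$abscissa, seq(0, 1, by = 0.2))
  expect_equal(nrow(curve), 6)
  expect_true(all(curve$mean_accuracy >= 0 & curve$mean_accuracy <= 1))
  # all-horizontal displays are easier than all-vertical ones
  expect_gte(curve$mean_accuracy[1], curve$mean_accuracy[6])
})

test_that("measure tables export to CSV", {
  obs <- bouma_pooling_observer(noise_sd = 0)
  set.seed(54)
  curve <- proportion_measure(obs, n_runs = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measure_csv(curve, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$mean_accuracy, curve$mean_accuracy)
})
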