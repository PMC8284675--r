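test_that("noise-free pooling observer always follows an undiluted target", {
  obs <- bouma_pooling_observer(noise_sd = 0)
  right <- make_unflanked_display(target_sign = 1)
  left <- make_unflanked_display(target_sign = -1)
  set.seed(20)
  expect_true(all(respond(obs, right, 50) == "right"))
  expect_true(all(respond(obs, left, 50) == "left"))
  expect_equal(display_fitness(obs, right, 12), 1.0)

  # pooled estimate is the undiluted tilt signal
  expect_equal(pooled_tilt_estimate(obs, right), sin(10 * pi / 180))
})

test_that("vertical (target-like) flankers crowd at least as much as horizontal", {
  obs <- bouma_pooling_observer(noise_sd = 0.004)
  dv <- all_vertical(); dh <- all_horizontal()
  set.seed(21); acc_h <- display_fitness(obs, dh, 4000)
  set.seed(21); acc_v <- display_fitness(obs, dv, 4000)  # common random numbers
  expect_gte(acc_h, acc_v)

  # sparse displays at matched distance, common random numbers
  sv <- make_sparse_display(0.75, "vertical")
  sh <- make_sparse_display(0.75, "horizontal")
  set.seed(22); acc_sv <- display_fitness(obs, sv, 4000)
  set.seed(22); acc_sh <- display_fitness(obs, sh, 4000)
  expect_gte(acc_sh, acc_sv)
})

test_that("pooling interference vanishes beyond the 3 deg window", {
  obs <- bouma_pooling_observer(noise_sd = 0.1)
  far <- make_sparse_display(3.75, "vertical", target_sign = 1)
  base <- make_unflanked_display(target_sign = 1)
  # identical draws => bit-identical behaviour, not just statistical equality
  set.seed(23); f_far <- display_fitness(obs, far, 500)
  set.seed(23); f_base <- display_fitness(obs, base, 500)
  expect_identical(f_far, f_base)
})

test_that("population-code decoding recovers the target tilt", {
  obs <- popcode_observer(noise_sd = 0)
  alone <- make_unflanked_display(target_sign = 1)
  set.seed(24)
  # read-out band truncation biases the decoded tilt slightly toward 0
  est <- crowdga:::decision_values(obs, alone, 1)
  expect_gt(est, 4.7)
  expect_lt(est, 5.001)
  expect_true(all(respond(obs, alone, 20) == "right"))

  # narrow tuning: the population vector converges on the true tilt
  sharp <- popcode_observer(tuning_sd = 0.5, noise_sd = 0)
  expect_equal(crowdga:::decision_values(sharp, alone, 1), 5, tolerance = 1e-6)

  # vertical flankers attract the decoded tilt toward 0 but cannot flip it
  sv <- make_sparse_display(0.75, "vertical", target_sign = 1)
  est_v <- crowdga:::decision_values(obs, sv, 1)
  expect_gt(est_v, 0)
  expect_lt(est_v, est)

  # horizontal flankers barely enter the +/-45 deg read-out band
  sh <- make_sparse_display(0.75, "horizontal", target_sign = 1)
  est_h <- crowdga:::decision_values(obs, sh, 1)
  expect_lt(abs(est_h - 5), 0.5)
})

test_that("accuracy degrades to chance as noise grows", {
  set.seed(25)
  d <- make_dense_display(0.3)
  for (obs in list(bouma_pooling_observer(noise_sd = 1e6),
                   popcode_observer(noise_sd = 1e6))) {
    acc <- display_fitness(obs, d, 4000)
    expect_lt(abs(acc - 0.5), 0.03)
  }
})

test_that("noise calibration hits the target accuracy and is monotone", {
  set.seed(26)
  obs <- calibrate_noise(bouma_pooling_observer(), p_vertical = 0.3,
                         target_accuracy = 0.67)
  cal <- attr(obs, "calibration")
  expect_equal(cal$achieved_accuracy, 0.67, tolerance = 0.011)
  expect_gt(obs$noise_sd, 0)

  # independent evaluation set
  set.seed(27)
  expect_equal(evaluate_accuracy(obs, n_displays = 800), 0.67,
               tolerance = 0.02)

  # doubling the calibrated noise lowers accuracy (common random numbers)
  set.seed(28); a1 <- evaluate_accuracy(obs, n_displays = 400)
  set.seed(28); a2 <- evaluate_accuracy(set_noise(obs, 2 * obs$noise_sd),
                                        n_displays = 400)
  expect_lt(a2, a1)
})

test_that("unreachable calibration targets fail cleanly", {
  expect_error(calibrate_noise(bouma_pooling_observer(), target_accuracy = 0.5),
               "strictly above chance")
  expect_error(calibrate_noise(bouma_pooling_observer(), target_accuracy = 1),
               "strictly below 1")
  set.seed(29)
  expect_error(calibrate_noise(bouma_pooling_observer(),
                               target_accuracy = 0.9999),
               "ceiling")
})
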