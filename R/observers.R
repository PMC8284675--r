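#' Observer models for the tilt-discrimination task
#'
#' All observers implement the same two-alternative forced-choice contract:
#' given a display they report whether the target bar is tilted left or
#' right of vertical. Stochasticity enters only through the decision /
#' channel noise `noise_sd`; with `noise_sd = 0` every observer is
#' deterministic, and as `noise_sd` grows accuracy falls to chance (0.5).
#'
#' * `bouma_pooling_observer()` - a linear pooling observer. The target's
#'   tilt signal `target_weight * sin(2 * tilt)` is diluted by every flanker
#'   inside the pooling window (radius 3 deg = half the 6 deg target
#'   eccentricity, i.e. Bouma's window). Each flanker contributes
#'   `weight_fn(d) * s_class`, where `weight_fn` is a truncated Gaussian of
#'   the distance to the target and `s_class` is 1 for vertical
#'   (target-like) flankers and `sim_horizontal` < 1 for horizontal ones:
#'   similar flankers crowd more.
#' * `popcode_observer()` - a population-code observer. Bars within the
#'   spatial kernel excite orientation channels tiling \[-90, 90) deg;
#'   channel activity is read out by a doubled-angle population vector
#'   restricted to a band of `readout_halfwidth` deg around vertical, and
#'   the decoded tilt sign is the response.
#' * `grouping_observer()` - a two-stage observer: displays are first
#'   parsed into perceptual groups ([group_components()]); flankers outside
#'   the target's group have their interference weight multiplied by
#'   `out_group_gain` (0 = complete segmentation) before the chosen
#'   interference stage (pooling or popcode) runs.
#'
#' @param window_radius Pooling / kernel truncation radius in degrees.
#'   Defaults to 3, half the 6 deg target eccentricity.
#' @param weight_sd Width (deg) of the Gaussian interference weight profile.
#' @param weight_scale Amplitude of the interference weight profile relative
#'   to `target_weight`. Controls how strongly a nearest-neighbour flanker
#'   dilutes the target signal; the default gives the calibrated observers a
#'   wide dynamic range between crowded and uncrowded displays.
#' @param sim_horizontal Interference multiplier for horizontal flankers
#'   (vertical flankers have multiplier 1); must be < 1.
#' @param target_weight Weight of the target's own signal.
#' @param noise_sd Standard deviation of the decision noise (pooling) or of
#'   the additive channel noise (popcode). Usually set by
#'   [calibrate_noise()].
#' @return An object of class `crowding_observer`.
#' @examples
#' obs <- bouma_pooling_observer(noise_sd = 0.2)
#' d <- make_sparse_display(0.75, "vertical", target_sign = 1)
#' set.seed(1); respond(obs, d)
#' @name observers
NULL

#' @rdname observers
#' @export
bouma_pooling_observer <- function(window_radius = 3, weight_sd = 1,
                                   weight_scale = 20, sim_horizontal = 0.3,
                                   target_weight = 1, noise_sd = 0) {
  stopifnot(window_radius > 0, weight_sd > 0, weight_scale > 0,
            sim_horizontal >= 0, sim_horizontal < 1, target_weight > 0,
            noise_sd >= 0)
  structure(list(kind = "bouma_pooling", window_radius = window_radius,
                 weight_sd = weight_sd, weight_scale = weight_scale,
                 sim_horizontal = sim_horizontal,
                 target_weight = target_weight, noise_sd = noise_sd),
            class = c("bouma_pooling_observer", "crowding_observer"))
}

#' @rdname observers
#' @param tuning_sd Orientation tuning width of the channels, in degrees.
#' @param spatial_sd Width (deg) of the Gaussian spatial interference
#'   kernel, truncated at `window_radius` so the population pools over
#'   (roughly) Bouma's window at 6 deg eccentricity.
#' @param n_channels Number of orientation channels tiling \[-90, 90).
#' @param readout_halfwidth Half-width (deg) of the read-out band around
#'   vertical used by the population-vector decoder.
#' @export
popcode_observer <- function(tuning_sd = 15, spatial_sd = 1.5,
                             window_radius = 3, n_channels = 180,
                             readout_halfwidth = 45, noise_sd = 0) {
  stopifnot(tuning_sd > 0, spatial_sd > 0, window_radius > 0,
            n_channels >= 8, readout_halfwidth > 0, readout_halfwidth <= 90,
            noise_sd >= 0)
  phi <- seq(-90, 90 - 180 / n_channels, length.out = n_channels)
  band <- abs(phi) <= readout_halfwidth
  structure(list(kind = "popcode", tuning_sd = tuning_sd,
                 spatial_sd = spatial_sd, window_radius = window_radius,
                 n_channels = as.integer(n_channels),
                 readout_halfwidth = readout_halfwidth, noise_sd = noise_sd,
                 phi = phi[band],
                 cos2 = cos(2 * phi[band] * pi / 180),
                 sin2 = sin(2 * phi[band] * pi / 180)),
            class = c("popcode_observer", "crowding_observer"))
}

#' @rdname observers
#' @param stage Interference-stage observer: a `bouma_pooling_observer` or
#'   `popcode_observer` whose parameters define the within-group
#'   interference (its own `noise_sd` is ignored; the grouping observer's
#'   `noise_sd` is used).
#' @param out_group_gain Interference multiplier in `[0, 1]` applied to
#'   flankers outside the target's perceptual group (0 = complete
#'   segmentation, the default; 1 collapses the observer onto its bare
#'   interference stage).
#' @export
grouping_observer <- function(stage = bouma_pooling_observer(),
                              out_group_gain = 0, noise_sd = stage$noise_sd) {
  stopifnot(inherits(stage, "crowding_observer"),
            !inherits(stage, "grouping_observer"),
            out_group_gain >= 0, out_group_gain <= 1, noise_sd >= 0)
  structure(list(kind = "grouping_two_stage", stage = stage,
                 out_group_gain = out_group_gain, noise_sd = noise_sd),
            class = c("grouping_observer", "crowding_observer"))
}

#' @export
print.crowding_observer <- function(x, ...) {
  cat(sprintf("<%s observer> noise_sd = %.4g\n", x$kind, x$noise_sd))
  if (inherits(x, "grouping_observer"))
    cat(sprintf("  interference stage: %s, out_group_gain = %g\n",
                x$stage$kind, x$out_group_gain))
  cal <- attr(x, "calibration")
  if (!is.null(cal))
    cat(sprintf("  calibrated: accuracy %.3f at p_vertical = %g\n",
                cal$achieved_accuracy, cal$p_vertical))
  invisible(x)
}

#' Replace an observer's noise level
#' @param observer A `crowding_observer`.
#' @param noise_sd New non-negative noise standard deviation.
#' @export
set_noise <- function(observer, noise_sd) {
  stopifnot(inherits(observer, "crowding_observer"), noise_sd >= 0)
  observer$noise_sd <- noise_sd
  observer
}

## ---- interference computations ------------------------------------------

# Gaussian interference weight, truncated at the window radius; zero at d=0.
pool_weight <- function(d, p) {
  ifelse(d > 0 & d <= p$window_radius,
         p$weight_scale * exp(-d^2 / (2 * p$weight_sd^2)), 0)
}

# Pooling denominator: target_weight + sum of flanker weights x similarity
# x (optional per-flanker gain from the grouping stage).
pooling_denominator <- function(display, p, gains = NULL) {
  if (inherits(display, "unflanked_display")) return(p$target_weight)
  if (inherits(display, "dense_display")) {
    dm <- distance_matrix(display$geometry)
    w <- pool_weight(dm, p)
    s <- ifelse(display$vertical, 1, p$sim_horizontal)
    s[is.na(s)] <- 0
    if (!is.null(gains)) w <- w * gains
    return(p$target_weight + sum(w * s))
  }
  # sparse: 4 flankers of one class at one distance
  w <- pool_weight(rep(display$distance, 4), p)
  s <- if (display$flanker_class == "vertical") 1 else p$sim_horizontal
  if (!is.null(gains)) w <- w * gains
  p$target_weight + sum(w * s)
}

# Noise-free pooled signal magnitude for the display's tilt amplitude.
pooling_mu <- function(display, p, gains = NULL) {
  D <- pooling_denominator(display, p, gains)
  p$target_weight *
    sin(2 * display$geometry$tilt_magnitude * pi / 180) / D
}

# Summed spatial-kernel weight of vertical / horizontal flankers within the
# window (popcode stage). Kernel amplitude 1, target weight 1.
popcode_weights <- function(display, p, gains = NULL) {
  kern <- function(d) ifelse(d > 0 & d <= p$window_radius,
                             exp(-d^2 / (2 * p$spatial_sd^2)), 0)
  if (inherits(display, "unflanked_display"))
    return(c(wv = 0, wh = 0))
  if (inherits(display, "dense_display")) {
    w <- kern(distance_matrix(display$geometry))
    if (!is.null(gains)) w <- w * gains
    v <- display$vertical
    return(c(wv = sum(w[which(v)]), wh = sum(w[which(!v)])))
  }
  w <- kern(rep(display$distance, 4))
  if (!is.null(gains)) w <- w * gains
  if (display$flanker_class == "vertical") c(wv = sum(w), wh = 0)
  else c(wv = 0, wh = sum(w))
}

angdist <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  d
}

# Complex population-vector contribution of a unit-weight bar at
# orientation theta, over the read-out band.
popcode_profile <- function(obs, theta) {
  g <- exp(-angdist(obs$phi, theta)^2 / (2 * obs$tuning_sd^2))
  complex(real = sum(g * obs$cos2), imaginary = sum(g * obs$sin2))
}

# Noise-free population vector z0 for a display with a given target sign.
popcode_z0 <- function(display, obs, sign, gains = NULL) {
  w <- popcode_weights(display, obs, gains)
  tilt <- sign * display$geometry$tilt_magnitude
  popcode_profile(obs, tilt) +
    w[["wv"]] * popcode_profile(obs, 0) +
    w[["wh"]] * popcode_profile(obs, 90)
}

# Decode tilt (deg) from complex population vectors; zero-magnitude vectors
# fall back to a fair coin from the stream.
popcode_decode <- function(z) {
  tilt <- Arg(z) * 90 / pi
  zero <- Mod(z) == 0
  if (any(zero))
    tilt[zero] <- ifelse(stats::runif(sum(zero)) < 0.5, 1, -1) *
      .Machine$double.eps
  tilt
}

## ---- trial summaries ------------------------------------------------------

# Deterministic per-display summary consumed by the trial simulators:
# pooling-family -> list(type = "linear", mu); popcode-family ->
# list(type = "popcode", z0_pos, z0_neg, obs).
trial_summary <- function(observer, display) {
  UseMethod("trial_summary")
}

#' @export
trial_summary.bouma_pooling_observer <- function(observer, display) {
  list(type = "linear", mu = pooling_mu(display, observer))
}

#' @export
trial_summary.popcode_observer <- function(observer, display) {
  list(type = "popcode",
       z0_pos = popcode_z0(display, observer, 1L),
       z0_neg = popcode_z0(display, observer, -1L))
}

#' @export
trial_summary.grouping_observer <- function(observer, display) {
  gains <- group_gains(display, observer$out_group_gain)
  if (inherits(observer$stage, "popcode_observer")) {
    list(type = "popcode",
         z0_pos = popcode_z0(display, observer$stage, 1L, gains),
         z0_neg = popcode_z0(display, observer$stage, -1L, gains))
  } else {
    list(type = "linear", mu = pooling_mu(display, observer$stage, gains))
  }
}

popcode_noise_projection <- function(obs, n) {
  eps <- matrix(stats::rnorm(length(obs$phi) * n), length(obs$phi), n)
  complex(real = drop(obs$cos2 %*% eps), imaginary = drop(obs$sin2 %*% eps))
}

# n signed perceived-tilt estimates for the display's own target sign
decision_values <- function(observer, display, n = 1) {
  ts <- trial_summary(observer, display)
  s <- display$target_sign
  if (ts$type == "linear") {
    s * ts$mu + observer$noise_sd * stats::rnorm(n)
  } else {
    obs <- if (inherits(observer, "grouping_observer")) observer$stage else observer
    z0 <- if (s > 0) ts$z0_pos else ts$z0_neg
    popcode_decode(z0 + observer$noise_sd * popcode_noise_projection(obs, n))
  }
}

#' Simulate responses of an observer to a display
#'
#' `respond()` returns `"left"` or `"right"` for each of `n` independent
#' trials on the display as given (its `target_sign` fixed).
#' `pooled_tilt_estimate()` exposes the pooling observer's signed internal
#' estimate before thresholding. `popcode_respond()` and
#' `two_stage_respond()` are aliases of `respond()` restricted to the
#' matching observer kind.
#'
#' @param observer A `crowding_observer`.
#' @param display A display object.
#' @param n Number of independent trials.
#' @return `respond()`: character vector in `{"left", "right"}`.
#' @export
respond <- function(observer, display, n = 1) {
  stopifnot(inherits(observer, "crowding_observer"))
  dv <- decision_values(observer, display, n)
  zero <- dv == 0
  if (any(zero))
    dv[zero] <- ifelse(stats::runif(sum(zero)) < 0.5, 1, -1)
  ifelse(dv > 0, "right", "left")
}

#' @rdname respond
#' @export
pooled_tilt_estimate <- function(observer, display, n = 1) {
  stopifnot(inherits(observer, "bouma_pooling_observer") ||
              (inherits(observer, "grouping_observer") &&
                 inherits(observer$stage, "bouma_pooling_observer")))
  decision_values(observer, display, n)
}

#' @rdname respond
#' @export
popcode_respond <- function(observer, display, n = 1) {
  stopifnot(inherits(observer, "popcode_observer"))
  respond(observer, display, n)
}

#' @rdname respond
#' @export
two_stage_respond <- function(observer, display, n = 1) {
  stopifnot(inherits(observer, "grouping_observer"))
  respond(observer, display, n)
}

# n trials with a fresh fair-coin target sign per trial; returns logical
# correctness vector. The genome is fixed; only sign and noise vary.
simulate_trials <- function(observer, display, n) {
  ts <- trial_summary(observer, display)
  s <- ifelse(stats::runif(n) < 0.5, 1L, -1L)
  if (ts$type == "linear") {
    dv <- s * ts$mu + observer$noise_sd * stats::rnorm(n)
  } else {
    obs <- if (inherits(observer, "grouping_observer")) observer$stage else observer
    z0 <- ifelse(s > 0, ts$z0_pos, ts$z0_neg)
    dv <- popcode_decode(z0 + observer$noise_sd * popcode_noise_projection(obs, n))
  }
  zero <- dv == 0
  if (any(zero))
    dv[zero] <- ifelse(stats::runif(sum(zero)) < 0.5, 1, -1)
  (dv > 0) == (s > 0)
}

## ---- calibration ----------------------------------------------------------

#' Calibrate an observer's noise to a target accuracy
#'
#' Bisects on `noise_sd` until the observer's mean accuracy on a fixed set
#' of `n_displays` fresh random dense displays (flankers vertical with
#' probability `p_vertical`, `n_trials` trials each, fresh target sign per
#' trial) matches `target_accuracy`. Common random numbers are used across
#' bisection steps, making the evaluated accuracy a deterministic
#' non-increasing function of the noise level, so the bisection converges
#' to the Monte-Carlo lattice resolution.
#'
#' @param observer A `crowding_observer`.
#' @param p_vertical Vertical-flanker proportion of the calibration
#'   displays (0.30 for the standard first-generation condition).
#' @param target_accuracy Desired proportion correct; must be strictly
#'   above 0.5 and below the observer's noise-free ceiling.
#' @param n_displays,n_trials Size of the calibration set.
#' @param tol Acceptable deviation of the achieved accuracy.
#' @param geometry A [grid_geometry()].
#' @return The observer with `noise_sd` set; attribute `"calibration"`
#'   records the achieved accuracy and settings.
#' @export
calibrate_noise <- function(observer, p_vertical = 0.3,
                            target_accuracy = 0.67, n_displays = 300,
                            n_trials = 12, tol = 0.01,
                            geometry = grid_geometry()) {
  stopifnot(inherits(observer, "crowding_observer"), n_displays >= 200,
            n_trials >= 1)
  if (!(target_accuracy > 0.5))
    stop("target_accuracy must be strictly above chance (0.5)", call. = FALSE)
  if (target_accuracy >= 1)
    stop("target_accuracy must be strictly below 1", call. = FALSE)

  displays <- replicate(n_displays,
                        make_dense_display(p_vertical, geometry = geometry),
                        simplify = FALSE)
  acc <- calibration_accuracy_fn(observer, displays, n_trials)

  ceiling_acc <- acc(0)
  if (ceiling_acc < target_accuracy + tol)
    stop(sprintf(
      "calibration target %.3f unreachable: noise-free ceiling is %.3f",
      target_accuracy, ceiling_acc), call. = FALSE)

  hi <- 1
  while (acc(hi) > target_accuracy && hi < 2^20) hi <- hi * 2
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (acc(mid) > target_accuracy) lo <- mid else hi <- mid
  }
  sd_star <- (lo + hi) / 2
  achieved <- acc(sd_star)
  observer <- set_noise(observer, sd_star)
  attr(observer, "calibration") <- list(
    p_vertical = p_vertical, target_accuracy = target_accuracy,
    achieved_accuracy = achieved, n_displays = n_displays,
    n_trials = n_trials)
  observer
}

# Closure: accuracy on a frozen display set as a function of noise_sd,
# using noise draws frozen across calls (common random numbers).
calibration_accuracy_fn <- function(observer, displays, n_trials) {
  n <- length(displays)
  summaries <- lapply(displays, function(d) trial_summary(observer, d))
  signs <- matrix(ifelse(stats::runif(n * n_trials) < 0.5, 1, -1), n, n_trials)
  if (summaries[[1]]$type == "linear") {
    mu <- matrix(vapply(summaries, `[[`, 0, "mu"), n, n_trials)
    eps <- matrix(stats::rnorm(n * n_trials), n, n_trials)
    # correct iff mu + sd * (sign * eps) > 0; sign*eps is symmetric noise
    e2 <- signs * eps
    function(noise_sd) mean(mu + noise_sd * e2 > 0)
  } else {
    obs <- if (inherits(observer, "grouping_observer")) observer$stage else observer
    z0p <- vapply(summaries, `[[`, complex(1), "z0_pos")
    z0m <- vapply(summaries, `[[`, complex(1), "z0_neg")
    z0 <- matrix(ifelse(signs > 0, z0p, z0m), n, n_trials)
    eta <- matrix(popcode_noise_projection(obs, n * n_trials), n, n_trials)
    coin <- matrix(stats::runif(n * n_trials) < 0.5, n, n_trials)
    function(noise_sd) {
      z <- z0 + noise_sd * eta
      dv <- Arg(z)
      ok <- (dv > 0) == (signs > 0)
      degenerate <- Mod(z) == 0 | dv == 0
      ok[degenerate] <- coin[degenerate]
      mean(ok)
    }
  }
}

#' Mean accuracy of an observer on fresh random dense displays
#'
#' @inheritParams calibrate_noise
#' @param n_displays Number of independent displays.
#' @return Mean proportion correct.
#' @export
evaluate_accuracy <- function(observer, n_displays = 500, p_vertical = 0.3,
                              n_trials = 12, geometry = grid_geometry()) {
  mean(vapply(seq_len(n_displays), function(i) {
    d <- make_dense_display(p_vertical, geometry = geometry)
    mean(simulate_trials(observer, d, n_trials))
  }, 0))
}
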