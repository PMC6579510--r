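#' Motion-state parameter sets for synthetic trajectories
#'
#' `motion_params()` assembles the parameter list consumed by
#' [generate_state_trajectory()]. Each active state provides a speed sampler
#' and a duration sampler; stationary gaps have their own duration sampler.
#' Two presets are provided:
#'
#' * `motion_params_invivo()` mirrors the kinematics measured for axonal
#'   mitochondria at 25 degrees C: fast/slow directed states with Gaussian
#'   speeds (fast anterograde 0.62 +/- 0.09 um/s, slow anterograde
#'   0.36 +/- 0.08, fast retrograde 0.76 +/- 0.08, slow retrograde
#'   0.42 +/- 0.11) and state durations around 2.5 s (fast) and 0.45 s
#'   (slow); pauses decay with a ~2-3 s constant. Fast motion occurs in a
#'   single direction per trajectory, set by `direction`.
#' * `motion_params_uniform()` draws directed-phase speeds uniformly from
#'   `speed_range` (default 0.3-0.8 um/s) and durations uniformly from
#'   `active_dur` (0.4-3 s), with stationary gaps of `stationary_dur`
#'   (1-5 s) -- the regime used to validate the segmentation pipeline.
#'
#' @param states Named list of active states. Each element is a list with
#'   `speed` (function(n) -> um/s), `duration` (function(n) -> s) and
#'   `direction` (+1 anterograde, -1 retrograde).
#' @param transition Square matrix of transition probabilities between
#'   consecutive active states (rows sum to 1), row/col names matching
#'   `names(states)`.
#' @param stationary_duration function(n) -> s, duration of stationary gaps.
#' @param sigma Lateral localization noise s.d. (nm) added per coordinate.
#' @param sigma_z Axial localization noise s.d. (nm).
#' @param dt Sample interval (s); default 0.01 (100 Hz).
#' @param start Optional name of the first active state.
#' @param start_active Begin with an active phase (`TRUE`, default) or a
#'   stationary one.
#' @return A `motion_params` list.
#' @export
motion_params <- function(states, transition, stationary_duration,
                          sigma = 5, sigma_z = 30, dt = 0.01, start = NULL,
                          start_active = TRUE) {
  stopifnot(is.list(states), length(states) >= 1,
            nrow(transition) == length(states),
            all(abs(rowSums(transition) - 1) < 1e-8),
            sigma >= 0, sigma_z >= 0, dt > 0)
  structure(list(states = states, transition = transition,
                 stationary_duration = stationary_duration,
                 sigma = sigma, sigma_z = sigma_z, dt = dt,
                 start = start, start_active = isTRUE(start_active)),
            class = "motion_params")
}

rtruncnorm1 <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' @rdname motion_params
#' @param direction `"anterograde"` or `"retrograde"`: direction of the fast
#'   state for this trajectory.
#' @export
motion_params_invivo <- function(direction = c("anterograde", "retrograde"),
                                 sigma = 5, sigma_z = 30, dt = 0.01) {
  direction <- match.arg(direction)
  fwd <- if (direction == "anterograde") 1 else -1
  sp <- if (fwd == 1) {
    list(fast = c(0.62, 0.09), slow_fwd = c(0.36, 0.08), slow_rev = c(0.42, 0.11))
  } else {
    list(fast = c(0.76, 0.08), slow_fwd = c(0.42, 0.11), slow_rev = c(0.36, 0.08))
  }
  states <- list(
    fast = list(speed = function(n) rtruncnorm1(n, sp$fast[1], sp$fast[2], 0.05),
                duration = function(n) rtruncnorm1(n, 2.5, 1.2, 0.3),
                direction = fwd),
    slow_fwd = list(speed = function(n) rtruncnorm1(n, sp$slow_fwd[1], sp$slow_fwd[2], 0.05),
                    duration = function(n) rtruncnorm1(n, 0.46, 0.15, 0.2),
                    direction = fwd),
    slow_rev = list(speed = function(n) rtruncnorm1(n, sp$slow_rev[1], sp$slow_rev[2], 0.05),
                    duration = function(n) rtruncnorm1(n, 0.45, 0.15, 0.2),
                    direction = -fwd)
  )
  tr <- rbind(fast     = c(0.55, 0.25, 0.20),
              slow_fwd = c(0.50, 0.30, 0.20),
              slow_rev = c(0.50, 0.30, 0.20))
  colnames(tr) <- rownames(tr)
  motion_params(states, tr,
                stationary_duration = function(n) pmin(stats::rexp(n, 1 / 2.5) + 0.3, 20),
                sigma = sigma, sigma_z = sigma_z, dt = dt, start = "fast")
}

#' @rdname motion_params
#' @param speed_range,active_dur,stationary_dur Uniform ranges for directed
#'   speeds (um/s), directed durations (s) and stationary durations (s).
#' @param p_reverse Probability that a directed phase runs opposite to the
#'   previous one.
#' @export
motion_params_uniform <- function(speed_range = c(0.3, 0.8),
                                  active_dur = c(0.4, 3),
                                  stationary_dur = c(1, 5),
                                  p_reverse = 0.3,
                                  sigma = 5, sigma_z = 30, dt = 0.01) {
  mk <- function(dir) list(
    speed = function(n) stats::runif(n, speed_range[1], speed_range[2]),
    duration = function(n) stats::runif(n, active_dur[1], active_dur[2]),
    direction = dir)
  states <- list(fwd = mk(1), rev = mk(-1))
  tr <- rbind(fwd = c(1 - p_reverse, p_reverse),
              rev = c(p_reverse, 1 - p_reverse))
  colnames(tr) <- rownames(tr)
  motion_params(states, tr,
                stationary_duration = function(n)
                  stats::runif(n, stationary_dur[1], stationary_dur[2]),
                sigma = sigma, sigma_z = sigma_z, dt = dt, start = "fwd")
}

#' Generate a ground-truth motion-state trajectory
#'
#' Simulates the saltatory motion of an axonal organelle as alternating
#' directed phases and stationary gaps. Directed phases advance along the
#' axon axis (+x = anterograde) at a constant per-phase speed; stationary
#' phases hold a fixed point. Gaussian localization noise of s.d. `sigma`
#' (lateral) and `sigma_z` (axial) is added to the true positions to produce
#' the observed coordinates.
#'
#' @param params A [motion_params()] object.
#' @param duration Total trajectory duration (s).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `t_s`, `x_nm`, `y_nm`, `z_nm`
#'   (noisy observed positions), `true_x_nm`, `true_y_nm`, `true_z_nm`,
#'   `state` (per-sample 5-level label: `stationary`, `fast_antero`,
#'   `slow_antero`, `fast_retro`, `slow_retro`) and `active` (logical ground
#'   truth). The phase table used to build it is attached as
#'   `attr(, "phases")`.
#' @export
generate_state_trajectory <- function(params, duration = 60, seed = NULL) {
  stopifnot(inherits(params, "motion_params"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  nm <- names(params$states)
  cur <- params$start %||% nm[1]
  t_cum <- 0
  ph <- list()
  active_next <- params$start_active %||% TRUE
  while (t_cum < duration) {
    if (active_next) {
      st <- params$states[[cur]]
      dur <- st$duration(1)
      sp <- st$speed(1)
      if (dur <= 0 || sp < 0) stop("negative durations or speeds are invalid")
      ph[[length(ph) + 1]] <- data.frame(
        state = cur, active = TRUE, duration = dur,
        speed = sp * st$direction, stringsAsFactors = FALSE)
      cur <- sample(nm, 1, prob = params$transition[cur, ])
    } else {
      dur <- params$stationary_duration(1)
      if (dur <= 0) stop("negative durations or speeds are invalid")
      ph[[length(ph) + 1]] <- data.frame(
        state = "stationary", active = FALSE, duration = dur, speed = 0,
        stringsAsFactors = FALSE)
    }
    t_cum <- t_cum + dur
    active_next <- !active_next
  }
  phases <- do.call(rbind, ph)
  phases$t_start <- cumsum(c(0, phases$duration[-nrow(phases)]))

  n <- floor(duration / params$dt) + 1
  t <- (seq_len(n) - 1) * params$dt
  idx <- findInterval(t, phases$t_start)
  # true x: integrate the piecewise-constant velocity (nm/s)
  v <- phases$speed[idx] * 1000
  true_x <- cumsum(c(0, v[-1] * params$dt))
  true_y <- rep(0, n)
  true_z <- rep(0, n)
  state5 <- ifelse(phases$active[idx],
                   paste0(ifelse(abs(phases$speed[idx]) >= 0.49, "fast", "slow"),
                          ifelse(phases$speed[idx] > 0, "_antero", "_retro")),
                   "stationary")
  out <- data.frame(
    t_s = t,
    x_nm = true_x + stats::rnorm(n, 0, params$sigma),
    y_nm = true_y + stats::rnorm(n, 0, params$sigma),
    z_nm = true_z + stats::rnorm(n, 0, params$sigma_z),
    true_x_nm = true_x, true_y_nm = true_y, true_z_nm = true_z,
    state = state5, active = phases$active[idx],
    stringsAsFactors = FALSE)
  attr(out, "phases") <- phases
  attr(out, "params") <- params
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
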