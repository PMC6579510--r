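#' Extract motion phases from active/stationary labels
#'
#' Turns every contiguous active run into a motion phase with its direction
#' (sign of the net x displacement; anterograde = +x), duration, lateral
#' (xy) displacement, mean lateral velocity (displacement/duration) and the
#' per-orbit x displacement samples used for the orbit-displacement
#' histograms. Kinematics are computed on the 5-point smoothed positions.
#'
#' @param active Logical per-sample vector (e.g. `segment_trajectory()$active`).
#' @param traj Trajectory data.frame with `t_s`, `x_nm`, `y_nm`.
#' @param smooth Position smoothing window for kinematics (odd; 1 disables).
#' @return data.frame with one row per active phase: `t_start`, `t_end`,
#'   `duration_s`, `direction` ("antero"/"retro"), `dx_um`,
#'   `displacement_um`, `velocity_um_s`, `n_samples`, and a list column
#'   `orbit_dx_nm`.
#' @export
extract_phases <- function(active, traj, smooth = 5) {
  stopifnot(length(active) == nrow(traj))
  sx <- smooth_positions(traj$x_nm, smooth)
  sy <- smooth_positions(traj$y_nm, smooth)
  r <- rle(as.logical(active))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0), direction = character(0),
                      dx_um = numeric(0), displacement_um = numeric(0),
                      velocity_um_s = numeric(0), n_samples = integer(0)))
  rows <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- traj$t_s[i1] - traj$t_s[i0]
    dx <- (sx[i1] - sx[i0]) / 1000
    dy <- (sy[i1] - sy[i0]) / 1000
    disp <- sqrt(dx^2 + dy^2)
    data.frame(t_start = traj$t_s[i0], t_end = traj$t_s[i1],
               duration_s = dur,
               direction = if (dx >= 0) "antero" else "retro",
               dx_um = dx, displacement_um = disp,
               velocity_um_s = disp / dur, n_samples = i1 - i0 + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$orbit_dx_nm <- lapply(keep, function(k) diff(sx[starts[k]:ends[k]]))
  out
}

# log-likelihood of a two-component Gaussian mixture
mix2_loglik <- function(x, p) {
  sum(log(p$w * stats::dnorm(x, p$mu[1], p$sd[1]) +
            (1 - p$w) * stats::dnorm(x, p$mu[2], p$sd[2])))
}

#' Two-component Gaussian maximum-likelihood velocity fit
#'
#' Fits the phase-velocity histogram of the fast-motion direction with a
#' two-component Gaussian mixture by maximum likelihood (EM with k-means
#' initialisation and random restarts). The class boundary between slow and
#' fast transport is the mean of the two Gaussian centres.
#'
#' @param v Numeric vector of phase velocities (um/s), >= 10 values.
#' @param n_restarts EM restarts; the best log-likelihood is kept.
#' @param tol,max_iter EM convergence controls.
#' @param seed Optional integer seed.
#' @return List with `mu` (sorted ascending), `sd`, `w` (weight of the
#'   first component), `threshold` = mean(mu), `loglik`, `degenerate`
#'   (TRUE when the centres are closer than half the larger sigma, i.e.
#'   a single-mode fit), `n`.
#' @export
fit_velocity_mixture <- function(v, n_restarts = 10, tol = 1e-8,
                                 max_iter = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- v[is.finite(v)]
  if (length(v) < 10) {
    return(list(mu = rep(mean(v), 2), sd = rep(stats::sd(v), 2), w = 0.5,
                threshold = mean(v), loglik = NA_real_, degenerate = TRUE,
                n = length(v)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(v, 2, nstart = 1), error = function(e) NULL)
    if (is.null(km)) next
    ord <- order(km$centers)
    p <- list(mu = as.numeric(km$centers[ord]),
              sd = pmax(c(stats::sd(v[km$cluster == ord[1]]),
                          stats::sd(v[km$cluster == ord[2]])),
                        1e-4, na.rm = TRUE),
              w = mean(km$cluster == ord[1]))
    p$sd[!is.finite(p$sd)] <- stats::sd(v)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- p$w * stats::dnorm(v, p$mu[1], p$sd[1])
      d2 <- (1 - p$w) * stats::dnorm(v, p$mu[2], p$sd[2])
      g <- d1 / (d1 + d2)
      g[!is.finite(g)] <- 0.5
      p$w <- mean(g)
      p$mu <- c(sum(g * v) / sum(g), sum((1 - g) * v) / sum(1 - g))
      p$sd <- sqrt(c(sum(g * (v - p$mu[1])^2) / sum(g),
                     sum((1 - g) * (v - p$mu[2])^2) / sum(1 - g)))
      p$sd <- pmax(p$sd, 1e-4)
      ll <- mix2_loglik(v, p)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      ord <- order(p$mu)
      best <- list(mu = p$mu[ord], sd = p$sd[ord],
                   w = if (ord[1] == 1) p$w else 1 - p$w, loglik = ll)
    }
  }
  best$threshold <- mean(best$mu)
  # components are separate modes only when their centres are at least two
  # of the wider sigmas apart; otherwise the fit is a single velocity mode
  best$degenerate <- abs(diff(best$mu)) < 2 * max(best$sd)
  best$n <- length(v)
  best
}

#' Classify active phases into fast/slow antero/retrograde states
#'
#' Fast motion occurs in only one direction per trajectory, so the velocity
#' histogram of the dominant direction is fitted with the two-Gaussian
#' mixture and phases above the centre-mean threshold become `fast`; all
#' phases of the other direction, and phases below threshold, are `slow`.
#' When the mixture is degenerate (a single velocity mode) all phases are
#' assigned `slow` with a warning.
#'
#' @param phases Phase table from [extract_phases()].
#' @param fast_direction `"antero"`, `"retro"` or `"auto"` (direction whose
#'   phases reach the higher velocities).
#' @param seed Passed to [fit_velocity_mixture()].
#' @return `phases` with added columns `speed_class` ("fast"/"slow") and
#'   `state` (e.g. "fast_antero"); the mixture fit is attached as
#'   `attr(, "mixture")`.
#' @export
classify_phases <- function(phases, fast_direction = "auto", seed = NULL) {
  if (nrow(phases) == 0) {
    phases$speed_class <- character(0); phases$state <- character(0)
    return(phases)
  }
  if (fast_direction == "auto") {
    q <- tapply(phases$velocity_um_s, phases$direction,
                stats::quantile, probs = 0.9)
    fast_direction <- names(q)[which.max(q)]
  }
  vf <- phases$velocity_um_s[phases$direction == fast_direction]
  fit <- fit_velocity_mixture(vf, seed = seed)
  phases$speed_class <- "slow"
  if (fit$degenerate) {
    warning("velocity mixture is degenerate (single mode); all phases assigned slow")
  } else {
    sel <- phases$direction == fast_direction &
      phases$velocity_um_s > fit$threshold
    phases$speed_class[sel] <- "fast"
  }
  phases$state <- paste0(phases$speed_class, "_",
                         ifelse(phases$direction == "antero", "antero", "retro"))
  attr(phases, "mixture") <- fit
  phases
}

#' Per-sample 5-state labels from classified phases
#'
#' @param phases Classified phase table ([classify_phases()]).
#' @param traj Trajectory the phases belong to.
#' @return Character vector per sample: `stationary`, `fast_antero`,
#'   `slow_antero`, `fast_retro`, `slow_retro`.
#' @export
state_labels <- function(phases, traj) {
  lab <- rep("stationary", nrow(traj))
  for (i in seq_len(nrow(phases))) {
    sel <- traj$t_s >= phases$t_start[i] & traj$t_s <= phases$t_end[i]
    lab[sel] <- phases$state[i]
  }
  lab
}

#' Exponential decay-constant fit (maximum likelihood)
#'
#' @param x Positive data (s or um).
#' @param floor Left truncation point subtracted before the fit.
#' @return The ML decay constant (mean of `x - floor`).
#' @export
fit_exp_decay <- function(x, floor = 0) mean(x - floor)

#' Subset-replicated fit summary
#'
#' Implements the replicate-statistics scheme: the data set is partitioned
#' at random into `n_subsets` equal-size subsets, the model (Gaussian
#' location or exponential decay) is fitted to each subset by maximum
#' likelihood, and the parameter is reported as mean +/- s.d. across
#' subsets. The subset parameter vectors also feed two-sided t-tests
#' between conditions ([state_ttest()]).
#'
#' @param x Numeric data.
#' @param model `"gaussian"` (fitted centre) or `"exponential"` (decay
#'   constant).
#' @param n_subsets Number of equal-size random subsets (default 10).
#' @param seed Optional integer seed for the partition.
#' @return List with `mean`, `sd`, `n`, `subset_fits` and `flag`
#'   (`"raw"` when fewer than 20 observations force a plain mean +/- s.d.).
#' @export
subset_fit_summary <- function(x, model = c("gaussian", "exponential"),
                               n_subsets = 10, seed = NULL) {
  model <- match.arg(model)
  x <- x[is.finite(x)]
  if (length(x) < 20) {
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x),
                subset_fits = NULL, flag = "raw"))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(rep(seq_len(n_subsets), length.out = length(x)))
  fits <- vapply(seq_len(n_subsets), function(k) {
    xk <- x[idx == k]
    if (model == "gaussian") mean(xk) else fit_exp_decay(xk)
  }, numeric(1))
  list(mean = mean(fits), sd = stats::sd(fits), n = length(x),
       subset_fits = fits, flag = "ok")
}

#' @rdname subset_fit_summary
#' @param s1,s2 Two results of [subset_fit_summary()].
#' @return p-value of a two-sided t-test between the subset parameter
#'   vectors.
#' @export
state_ttest <- function(s1, s2) {
  if (is.null(s1$subset_fits) || is.null(s2$subset_fits)) return(NA_real_)
  stats::t.test(s1$subset_fits, s2$subset_fits)$p.value
}

#' Per-state summary statistics of a classified trajectory
#'
#' Builds the per-state table of duration (exponential decay constant),
#' xy displacement (exponential), xy velocity (Gaussian centre) -- each via
#' the 10-subset replicate scheme -- and the x orbit-displacement Gaussian
#' (mean +/- s.d. fitted directly to all per-orbit steps of that state).
#'
#' @param phases Classified phase table.
#' @param traj Trajectory; used for the stationary orbit displacements.
#' @param active Logical active labels aligned to `traj`.
#' @param smooth Smoothing for the orbit displacements.
#' @param seed Partition seed for [subset_fit_summary()].
#' @return data.frame with one row per (state, quantity): `state`,
#'   `quantity`, `estimate`, `sd`, `n`, `flag`.
#' @export
state_statistics <- function(phases, traj, active, smooth = 5, seed = NULL) {
  sx <- smooth_positions(traj$x_nm, smooth)
  rows <- list()
  add <- function(state, quantity, s)
    rows[[length(rows) + 1]] <<- data.frame(
      state = state, quantity = quantity, estimate = s$mean, sd = s$sd,
      n = s$n, flag = s$flag, stringsAsFactors = FALSE)
  for (st in unique(phases$state)) {
    p <- phases[phases$state == st, ]
    add(st, "duration_s",
        subset_fit_summary(p$duration_s, "exponential", seed = seed))
    add(st, "xy_displacement_um",
        subset_fit_summary(p$displacement_um, "exponential", seed = seed))
    add(st, "xy_velocity_um_s",
        subset_fit_summary(p$velocity_um_s, "gaussian", seed = seed))
    dx <- unlist(p$orbit_dx_nm)
    rows[[length(rows) + 1]] <- data.frame(
      state = st, quantity = "x_orbit_displacement_nm",
      estimate = mean(dx), sd = stats::sd(dx), n = length(dx), flag = "ok",
      stringsAsFactors = FALSE)
  }
  stat_dx <- diff(sx)[!active[-length(active)]]
  rows[[length(rows) + 1]] <- data.frame(
    state = "stationary", quantity = "x_orbit_displacement_nm",
    estimate = mean(stat_dx), sd = stats::sd(stat_dx), n = length(stat_dx),
    flag = "ok", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Transition and pause analysis between motion phases
#'
#' Transitions are ordered pairs of consecutive active phases; the
#' stationary gap between them is the pause. Pauses are classed by their
#' flanking speed classes (fast-fast, fast-slow in either order,
#' slow-slow) and each class is fitted with a mono-exponential decay by
#' maximum likelihood. Direction-change probabilities are reported
#' separately for pauses shorter/longer than `long_pause`.
#'
#' @param phases Classified phase table (time-ordered).
#' @param long_pause Boundary between short and long pauses (s), default
#'   20.
#' @return List with `transitions` (data.frame per pair: states, pause
#'   duration, pause class, direction change), `counts` (transition count
#'   matrix), `pause_decay` (named decay constants per pause class),
#'   `direction_change` (probability and n for short/long pauses).
#' @export
transition_analysis <- function(phases, long_pause = 20) {
  if (nrow(phases) < 2)
    return(list(transitions = NULL, counts = NULL, pause_decay = NULL,
                direction_change = NULL))
  phases <- phases[order(phases$t_start), ]
  i <- seq_len(nrow(phases) - 1)
  tr <- data.frame(
    from = phases$state[i], to = phases$state[i + 1],
    pause_s = phases$t_start[i + 1] - phases$t_end[i],
    stringsAsFactors = FALSE)
  cls_from <- phases$speed_class[i]; cls_to <- phases$speed_class[i + 1]
  tr$pause_class <- ifelse(cls_from == "fast" & cls_to == "fast", "fast-fast",
                    ifelse(cls_from == "slow" & cls_to == "slow", "slow-slow",
                           "fast-slow"))
  tr$direction_change <- phases$direction[i] != phases$direction[i + 1]
  states <- sort(unique(phases$state))
  counts <- table(factor(tr$from, states), factor(tr$to, states))
  decay <- tapply(tr$pause_s, tr$pause_class, fit_exp_decay)
  short <- tr$pause_s < long_pause
  dc <- data.frame(
    pause = c("short", "long"),
    p_direction_change = c(mean(tr$direction_change[short]),
                           mean(tr$direction_change[!short])),
    n = c(sum(short), sum(!short)))
  list(transitions = tr, counts = counts, pause_decay = decay,
       direction_change = dc)
}
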