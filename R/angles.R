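#' Centered running-mean smoothing of trajectory positions
#'
#' 5-point (50 ms at 100 Hz) smoothing removes the high-frequency jitter of
#' the tracking feedback before the angle series is formed; windows shrink
#' symmetrically at the trajectory ends so the sample count is preserved.
#'
#' @param x Numeric vector or matrix (columns smoothed independently).
#' @param k Window size in samples (odd).
#' @return Smoothed object of the same shape.
#' @export
smooth_positions <- function(x, k = 5) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (is.matrix(x) || is.data.frame(x))
    return(apply(as.matrix(x), 2, smooth_positions, k = k))
  n <- length(x)
  h <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-step lateral displacement angles of a trajectory
#'
#' The lateral angle phi of each step with respect to the axon (x) axis,
#' `phi = atan2(dy, dx)` for consecutive positions. Steps with exactly zero
#' displacement inherit the previous step's angle and are flagged.
#'
#' @param traj data.frame with `x_nm`, `y_nm` (and `t_s`), or a 2-column
#'   matrix of lateral positions.
#' @return An `angle_series`: numeric vector of angles in (-pi, pi], length
#'   one less than the trajectory, with attributes `dt` (sample interval,
#'   if derivable) and `zero_steps` (indices that inherited an angle).
#' @export
displacement_angles <- function(traj) {
  if (is.data.frame(traj)) {
    xy <- cbind(traj$x_nm, traj$y_nm)
    dt <- if (!is.null(traj$t_s) && nrow(traj) > 1) stats::median(diff(traj$t_s)) else NA_real_
  } else {
    xy <- as.matrix(traj)
    dt <- NA_real_
  }
  if (nrow(xy) < 2) stop("at least 2 samples are required")
  if (!all(is.finite(xy))) stop("lateral coordinates must be finite")
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  zero <- which(dx == 0 & dy == 0)
  if (length(zero) == length(dx)) stop("degenerate trajectory: all displacements are zero")
  phi <- atan2(dy, dx)
  for (i in zero) phi[i] <- if (i == 1) phi[which(dx != 0 | dy != 0)[1]] else phi[i - 1]
  structure(phi, dt = dt, zero_steps = zero, class = "angle_series")
}

lags_from_interval <- function(tau_interval, dt) {
  lags <- seq(ceiling(tau_interval[1] / dt - 1e-9),
              floor(tau_interval[2] / dt + 1e-9))
  if (length(lags) < 1 || any(lags < 1))
    stop("tau interval is not representable at this sample interval")
  as.integer(lags)
}

#' Sliding-window autocorrelation of the angle series
#'
#' Correlates the step angles along the trajectory in a sliding window of
#' `window` points for each lag tau, producing a correlation carpet
#' Cor(t, tau) and its reduced series (mean over the lag interval
#' `tau_interval`, 0.03-0.06 s by default). Two functional forms are
#' available: `"cosine"` (default), Cor = mean of cos(phi_s - phi_(s-tau)),
#' which approaches 1 for directed motion and 0 for isotropic noise; and
#' `"raw"`, the plain product mean of the angles,
#' sum(phi_s * phi_(s-tau)) / (n - tau).
#'
#' @param angles An [displacement_angles()] series (or numeric vector with
#'   `dt` supplied).
#' @param window Sliding-window length in samples (default 64).
#' @param tau_interval Lag interval in seconds averaged into the reduced
#'   series.
#' @param dt Sample interval (s); taken from `angles` when available.
#' @param mode `"cosine"` or `"raw"`.
#' @return A `correlation_carpet`: list with `carpet` (one row per window
#'   start, one column per lag), `reduced`, `lags` (samples), `window`,
#'   `dt`, `mode`. Row t corresponds to the window over angle indices
#'   t..t+window-1, i.e. is centred on sample t + window/2.
#' @export
direction_correlation <- function(angles, window = 64,
                                  tau_interval = c(0.03, 0.06),
                                  dt = attr(angles, "dt"), mode = c("cosine", "raw")) {
  mode <- match.arg(mode)
  phi <- as.numeric(angles)
  if (is.null(dt) || is.na(dt)) stop("sample interval dt is required")
  M <- length(phi)
  if (M < window) stop("angle series shorter than the correlation window")
  lags <- lags_from_interval(tau_interval, dt)
  nt <- M - window + 1
  carpet <- matrix(NA_real_, nt, length(lags))
  for (j in seq_along(lags)) {
    tau <- lags[j]
    q <- if (mode == "cosine") cos(phi[(1 + tau):M] - phi[1:(M - tau)])
         else phi[(1 + tau):M] * phi[1:(M - tau)]
    w <- window - tau
    f <- as.numeric(stats::filter(q, rep(1 / w, w), sides = 1))
    carpet[, j] <- f[w:(w + nt - 1)]
  }
  structure(list(carpet = carpet, reduced = rowMeans(carpet), lags = lags,
                 window = window, dt = dt, mode = mode),
            class = "correlation_carpet")
}

#' Randomization threshold for active-transport detection
#'
#' Builds the null distribution of the reduced correlation for a trajectory
#' without directional persistence: the angle array is augmented with a
#' sign-reversed copy (so that trajectories with a preferred direction do
#' not bias the null), permuted uniformly, and passed through the same
#' correlation analysis. The threshold is the pooled mean plus five
#' standard deviations of the shuffled reduced series.
#'
#' @inheritParams direction_correlation
#' @param n_shuffles Number of random permutations pooled (default 10).
#' @param seed Optional integer seed (the threshold is deterministic given
#'   the seed).
#' @return Threshold (numeric scalar) with attributes `mean` and `sd` of
#'   the pooled null.
#' @export
randomized_threshold <- function(angles, window = 64,
                                 tau_interval = c(0.03, 0.06),
                                 dt = attr(angles, "dt"),
                                 n_shuffles = 10, seed = NULL,
                                 mode = c("cosine", "raw")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_shuffles >= 1)
  phi <- as.numeric(angles)
  if (length(phi) < window) stop("angle series shorter than the correlation window")
  aug <- c(phi, -phi)
  pooled <- unlist(lapply(seq_len(n_shuffles), function(i) {
    a <- sample(aug)
    direction_correlation(structure(a, dt = dt), window = window,
                          tau_interval = tau_interval, dt = dt,
                          mode = mode)$reduced
  }))
  structure(mean(pooled) + 5 * stats::sd(pooled),
            mean = mean(pooled), sd = stats::sd(pooled))
}

#' Active/stationary segmentation from the reduced correlation
#'
#' Thresholds the reduced correlation series, shifts the binary assignment
#' back by half the correlation window to undo the window-induced delay,
#' and relabels active runs shorter than `min_active` seconds (150 ms,
#' twice the duration of a recentering event) as stationary.
#'
#' @param carpet A [direction_correlation()] result (or its reduced
#'   vector).
#' @param threshold Numeric threshold, e.g. from [randomized_threshold()].
#' @param n_samples Trajectory length the labels should cover.
#' @param min_active Minimum active-phase duration in seconds.
#' @return Logical vector of length `n_samples`: `TRUE` = active.
#' @export
segment_active_stationary <- function(carpet, threshold, n_samples,
                                      min_active = 0.15) {
  if (inherits(carpet, "correlation_carpet")) {
    reduced <- carpet$reduced; window <- carpet$window; dt <- carpet$dt
  } else stop("carpet must be a correlation_carpet")
  act <- reduced > threshold
  half <- window %/% 2
  lab <- rep(NA, n_samples)
  idx <- seq_along(act) + half          # window start t labels sample t + w/2
  idx <- idx[idx <= n_samples]
  lab[idx] <- act[seq_along(idx)]
  first <- which(!is.na(lab))[1]
  lab[seq_len(first - 1)] <- lab[first]
  last <- max(which(!is.na(lab)))
  if (last < n_samples) lab[(last + 1):n_samples] <- lab[last]
  min_run <- ceiling(min_active / dt)
  r <- rle(lab)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

#' Full active/stationary segmentation of a trajectory
#'
#' Convenience pipeline: smooth positions (5 points, 50 ms), form the angle
#' series, compute the per-trajectory randomized threshold, correlate in a
#' 64-sample sliding window, threshold, shift by half a window and enforce
#' the 150 ms minimum active duration.
#'
#' @param traj Trajectory data.frame with `t_s`, `x_nm`, `y_nm`.
#' @param window,tau_interval,mode See [direction_correlation()].
#' @param smooth Position-smoothing window in samples before the angle
#'   series (odd; 1 disables).
#' @param n_shuffles,seed Passed to [randomized_threshold()].
#' @param threshold Override the randomized threshold with a fixed value.
#' @param min_active Minimum active-phase duration (s).
#' @return List with `active` (logical per sample), `threshold`, `carpet`,
#'   `angles`, `smoothed` (n x 2 matrix of smoothed lateral positions) and
#'   `dt`.
#' @export
segment_trajectory <- function(traj, window = 64,
                               tau_interval = c(0.03, 0.06), smooth = 5,
                               n_shuffles = 10, seed = NULL,
                               threshold = NULL, min_active = 0.15,
                               mode = "cosine") {
  stopifnot(all(c("t_s", "x_nm", "y_nm") %in% names(traj)))
  dt <- stats::median(diff(traj$t_s))
  sm <- cbind(smooth_positions(traj$x_nm, smooth),
              smooth_positions(traj$y_nm, smooth))
  ang <- displacement_angles(data.frame(x_nm = sm[, 1], y_nm = sm[, 2],
                                        t_s = traj$t_s))
  if (is.null(threshold))
    threshold <- randomized_threshold(ang, window = window,
                                      tau_interval = tau_interval, dt = dt,
                                      n_shuffles = n_shuffles, seed = seed,
                                      mode = mode)
  carpet <- direction_correlation(ang, window = window,
                                  tau_interval = tau_interval, dt = dt,
                                  mode = mode)
  active <- segment_active_stationary(carpet, threshold, nrow(traj),
                                      min_active = min_active)
  list(active = active, threshold = threshold, carpet = carpet,
       angles = ang, smoothed = sm, dt = dt)
}
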