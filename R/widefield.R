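#' Remove moving objects from a wide-field movie
#'
#' Per-pixel forward-difference background subtraction: brightness that
#' disappears within `lag` frames is subtracted from the current frame,
#'   dI(x,y,t) = I(x,y,t+lag) - I(x,y,t), kept only where negative,
#'   I_stationary = I + dI,
#' which removes objects that move away while leaving resting objects
#' untouched. The final `lag` frames have no forward difference and are
#' dropped from the returned stack.
#'
#' @param stack ny x nx x nt array (e.g. from [render_widefield_movie()]).
#' @param lag Forward-difference lag in frames (default 10, i.e. 5 s at
#'   2 Hz).
#' @return ny x nx x (nt - lag) array of the stationary-only movie; input
#'   attributes are preserved and recentering frame indices beyond the new
#'   length are trimmed.
#' @export
remove_moving <- function(stack, lag = 10) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  if (lag >= d[3]) stop("lag must be smaller than the stack length")
  keep <- seq_len(d[3] - lag)
  di <- stack[, , keep + lag, drop = FALSE] - stack[, , keep, drop = FALSE]
  di[di > 0] <- 0
  out <- stack[, , keep, drop = FALSE] + di
  for (a in c("pixel_size", "frame_interval", "origins"))
    attr(out, a) <- attr(stack, a)
  rf <- attr(stack, "recenter_frames")
  attr(out, "recenter_frames") <- rf[rf <= length(keep)]
  out
}

#' Mean images between long-range recentering events
#'
#' A movie with m recentering events has m + 1 stationary field-of-view
#' segments. The mean image of each segment is computed; the segment after
#' the last event is discarded (it usually contains a long terminal
#' stationary phase), except when there are no events at all, in which case
#' the single mean image is kept.
#'
#' @param stack ny x nx x nt array.
#' @param recenter_frames Strictly increasing frame indices at which the
#'   field of view jumped (first frame of each new segment); defaults to
#'   the stack attribute.
#' @return List of mean images (matrices), length m (or 1 when m = 0).
#' @export
mean_segments <- function(stack, recenter_frames = attr(stack, "recenter_frames")) {
  d <- dim(stack)
  recenter_frames <- sort(unique(recenter_frames))
  recenter_frames <- recenter_frames[recenter_frames > 1 & recenter_frames <= d[3]]
  bounds <- c(1, recenter_frames, d[3] + 1)
  m <- length(recenter_frames)
  n_seg <- if (m == 0) 1 else m
  lapply(seq_len(n_seg), function(i) {
    idx <- bounds[i]:(bounds[i + 1] - 1)
    apply(stack[, , idx, drop = FALSE], c(1, 2), mean)
  })
}

boxcar_smooth <- function(img, k = 5) {
  kern <- matrix(1 / k^2, k, k)
  EBImage::filter2(img, kern, boundary = "replicate")
}

# Binary corridor mask around the trajectory: rasterize the trajectory
# pixels and dilate by the corridor half-widths (separably in x and y).
corridor_mask <- function(dim_img, traj_px, corridor = c(51, 11)) {
  mask <- matrix(0, dim_img[1], dim_img[2])
  ix <- round(traj_px[, 1]) + 1
  iy <- round(traj_px[, 2]) + 1
  ok <- ix >= 1 & ix <= dim_img[2] & iy >= 1 & iy <= dim_img[1]
  mask[cbind(iy[ok], ix[ok])] <- 1
  if (!any(mask > 0)) return(mask)
  kx <- matrix(1, 1, corridor[1])
  ky <- matrix(1, corridor[2], 1)
  mask <- EBImage::filter2(mask, kx, boundary = 0)
  mask <- EBImage::filter2(mask, ky, boundary = 0)
  (mask > 1e-6) * 1
}

#' Detect stationary objects in a mean wide-field image
#'
#' Implements the stationary-mitochondrion extraction: the mean image is
#' smoothed with a 5 x 5 boxcar, binarized at mean + 5 s.d. of the full
#' smoothed frame, masked to a 51 x 11 px corridor around the trajectory
#' (dilated polyline with half-widths 25 and 5 px, the axon running along
#' x), and connected components are labelled. Each component yields an
#' intensity-weighted centroid and a length: the half-maximum span of the
#' component's intensity profile projected onto its principal axis, which
#' locates the object edges independently of the blur halo a raw binary
#' extent would include.
#'
#' @param mean_image Matrix (a [mean_segments()] element, typically after
#'   [remove_moving()]).
#' @param traj_px n x 2 matrix of the trajectory in camera pixel
#'   coordinates (0-based, x then y).
#' @param map A [fit_poly_map()]/[identity_poly_map()] mapping camera px to
#'   tracking nm.
#' @param smooth Boxcar width in px (default 5).
#' @param k_sigma Threshold in s.d. above the frame mean (default 5).
#' @param corridor Corridor size `c(nx, ny)` in px (default 51 x 11).
#' @param min_px Minimum component size in px.
#' @return data.frame with one row per object: `x_nm`, `y_nm` (centroid in
#'   tracking frame), `length_nm`, `n_px`, `x_px`, `y_px`.
#' @export
detect_stationary <- function(mean_image, traj_px, map = identity_poly_map(),
                              smooth = 5, k_sigma = 5, corridor = c(51, 11),
                              min_px = 3) {
  sm <- boxcar_smooth(mean_image, smooth)
  thr <- mean(sm) + k_sigma * stats::sd(sm)
  mask <- corridor_mask(dim(mean_image), traj_px, corridor)
  bin <- (sm > thr) * mask
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      length_nm = numeric(0), n_px = integer(0),
                      x_px = numeric(0), y_px = numeric(0))
  if (!any(bin > 0)) return(empty)
  lab <- EBImage::bwlabel(bin)
  px_nm <- sqrt(sum((apply_poly_map(map, rbind(c(1, 0))) -
                       apply_poly_map(map, rbind(c(0, 0))))^2))
  rows <- list()
  bg <- mean(sm)
  for (l in seq_len(max(lab))) {
    w <- which(lab == l, arr.ind = TRUE)
    if (nrow(w) < min_px) next
    # image rows are y, columns are x; convert to 0-based pixel coords
    pts <- cbind(x = w[, 2] - 1, y = w[, 1] - 1)
    wt <- pmax(sm[w] - bg, 0)
    if (sum(wt) <= 0) wt <- rep(1, nrow(pts))
    ctr <- colSums(pts * wt) / sum(wt)
    cen <- sweep(pts, 2, ctr)
    ev <- eigen(stats::cov.wt(cen, wt = wt / sum(wt))$cov,
                symmetric = TRUE)$vectors[, 1]
    proj <- as.numeric(cen %*% ev)
    # half-maximum span of the 1 px binned axial intensity profile
    br <- seq(floor(min(proj)) - 0.5, ceiling(max(proj)) + 0.5, by = 1)
    prof <- tapply(wt, cut(proj, br), mean)
    prof[is.na(prof)] <- 0
    above <- which(prof >= stats::quantile(prof, 0.9) / 2)
    len_px <- max(above) - min(above) + 0.5
    ctr_nm <- apply_poly_map(map, rbind(ctr))
    rows[[length(rows) + 1]] <- data.frame(
      x_nm = ctr_nm[1], y_nm = ctr_nm[2], length_nm = len_px * px_nm,
      n_px = nrow(pts), x_px = ctr[1], y_px = ctr[2])
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Motion-state occupancy split by local stationary-object presence
#'
#' Classifies every trajectory sample as `occupied` (the tracked position
#' lies within `capture` nm of the axonal extent of any stationary object)
#' or `free`, and reports the fraction of time spent in each motion state
#' under both conditions.
#'
#' @param labels Per-sample state labels ([state_labels()]).
#' @param traj Trajectory data.frame (`x_nm`).
#' @param objects Stationary-object table (`x_nm`, `length_nm`) in the same
#'   (tracking) frame.
#' @param capture Capture distance (nm) by which each object's extent along
#'   the axon is dilated; default 500.
#' @return data.frame: `condition`, `state`, `fraction`, `n_samples`; the
#'   per-sample occupancy flags are attached as `attr(, "occupied")`.
#' @export
occupancy_fractions <- function(labels, traj, objects, capture = 500) {
  occ <- rep(FALSE, nrow(traj))
  if (!is.null(objects) && nrow(objects) > 0) {
    for (i in seq_len(nrow(objects))) {
      lo <- objects$x_nm[i] - objects$length_nm[i] / 2 - capture
      hi <- objects$x_nm[i] + objects$length_nm[i] / 2 + capture
      occ <- occ | (traj$x_nm >= lo & traj$x_nm <= hi)
    }
  }
  out <- list()
  for (cond in c("free", "occupied")) {
    sel <- if (cond == "free") !occ else occ
    if (!any(sel)) next
    tab <- table(labels[sel])
    out[[cond]] <- data.frame(condition = cond, state = names(tab),
                              fraction = as.numeric(tab) / sum(tab),
                              n_samples = as.integer(tab),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "occupied") <- occ
  res
}

#' Crossing-time profile along the axon
#'
#' For each trajectory, the time spent in every 100 nm bin of the common
#' axon-axis coordinate is accumulated; bins a trajectory never visits are
#' missing (NA), not zero. On a coarser 1 um grid, a bin is flagged as a
#' slow focus for a trajectory when its summed crossing time exceeds
#' `slow_threshold` seconds; the profile reports the fraction of
#' trajectories flagged per coarse bin (both travel directions pooled).
#'
#' @param trajectories A trajectory data.frame or list of them (`t_s`,
#'   `x_nm`).
#' @param bin Fine bin width (nm), default 100.
#' @param coarse_bin Coarse bin width (nm), default 1000.
#' @param slow_threshold Crossing time (s) per coarse bin defining a slow
#'   focus, default 10.
#' @return List with `fine` (data.frame `x_nm`, per-trajectory crossing
#'   times `t_<i>_s`, `mean_s`) and `coarse` (data.frame `x_nm`,
#'   `fraction_slow`, `n_traj`).
#' @export
crossing_times <- function(trajectories, bin = 100, coarse_bin = 1000,
                           slow_threshold = 10) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  rng <- range(unlist(lapply(trajectories, function(tr) range(tr$x_nm))))
  breaks <- seq(floor(rng[1] / bin) * bin, ceiling(rng[2] / bin) * bin, by = bin)
  centers <- breaks[-1] - bin / 2
  fine <- matrix(NA_real_, length(centers), length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    dt <- stats::median(diff(tr$t_s))
    idx <- findInterval(tr$x_nm, breaks, rightmost.closed = TRUE)
    idx[idx < 1 | idx > length(centers)] <- NA
    tab <- tapply(rep(dt, length(idx)), idx, sum)
    fine[as.integer(names(tab)), i] <- as.numeric(tab)
  }
  cgrp <- floor(centers / coarse_bin)
  ugrp <- sort(unique(cgrp))
  frac <- vapply(ugrp, function(g) {
    sel <- cgrp == g
    per_traj <- colSums(fine[sel, , drop = FALSE], na.rm = TRUE)
    visited <- colSums(!is.na(fine[sel, , drop = FALSE])) > 0
    if (!any(visited)) return(NA_real_)
    mean(per_traj[visited] > slow_threshold)
  }, numeric(1))
  fine_df <- data.frame(x_nm = centers, fine)
  names(fine_df)[-1] <- paste0("t_", seq_along(trajectories), "_s")
  fine_df$mean_s <- rowMeans(fine, na.rm = TRUE)
  coarse_df <- data.frame(x_nm = ugrp * coarse_bin + coarse_bin / 2,
                          fraction_slow = frac,
                          n_traj = length(trajectories))
  list(fine = fine_df, coarse = coarse_df)
}
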