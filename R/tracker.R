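#' Orbit and feedback-loop configuration
#'
#' @param orbit_radius Orbit radius (nm), default 150.
#' @param n_sectors Number of angular sectors (even, >= 8), default 16.
#' @param orbit_period Duration of one orbit (s), default 0.005.
#' @param dark_orbit_factor Integer n >= 1: only one out of every n-th orbit
#'   is illuminated; n = 1 means no dark orbits. With a 5 ms orbit and
#'   n = 2 the effective sampling is 100 Hz.
#' @param count_threshold Photons per illuminated orbit (planes summed)
#'   below which the tracker enters search mode.
#' @param recenter_threshold Galvo offset (nm) triggering a long-range stage
#'   recentering, default 10000 (10 um), checked per lateral axis.
#' @param recenter_dead_time Named numeric `c(x=, y=)` dead time (s) of a
#'   recentering event per axis; defaults 0.063 (x) and 0.035 (y).
#' @param plane_sep Axial detection-plane separation (nm); must match the
#'   PSF used to build the look-up tables.
#' @param spiral_pitch Radial gain of the search spiral per turn (nm);
#'   default = orbit radius.
#' @param spiral_step Angular step of the search spiral per probe orbit
#'   (radians).
#' @param spiral_max_radius Search radius (nm) beyond which tracking is
#'   declared lost.
#' @return An `orbit_config` object.
#' @export
orbit_config <- function(orbit_radius = 150, n_sectors = 16,
                         orbit_period = 0.005, dark_orbit_factor = 2,
                         count_threshold = 20, recenter_threshold = 10000,
                         recenter_dead_time = c(x = 0.063, y = 0.035),
                         plane_sep = 1000,
                         spiral_pitch = orbit_radius,
                         spiral_step = 2 * pi / 16,
                         spiral_max_radius = 5000) {
  stopifnot(orbit_radius > 0, n_sectors >= 8, n_sectors %% 2 == 0,
            orbit_period > 0, dark_orbit_factor >= 1,
            recenter_threshold > 0, all(recenter_dead_time >= 0),
            plane_sep > 0, spiral_pitch > 0, spiral_max_radius > 0)
  structure(list(orbit_radius = orbit_radius, n_sectors = n_sectors,
                 orbit_period = orbit_period,
                 dark_orbit_factor = as.integer(dark_orbit_factor),
                 count_threshold = count_threshold,
                 recenter_threshold = recenter_threshold,
                 recenter_dead_time = recenter_dead_time,
                 plane_sep = plane_sep,
                 spiral_pitch = spiral_pitch, spiral_step = spiral_step,
                 spiral_max_radius = spiral_max_radius),
            class = "orbit_config")
}

#' Initialise the tracker state
#'
#' @param start Initial orbit centre (sample-fixed nm, length 3).
#' @return A `tracker_state` list: galvo offset, stage position, mode
#'   (`"track"` or `"search"`) and spiral bookkeeping.
#' @export
tracker_state <- function(start = c(0, 0, 0)) {
  structure(list(galvo = as.numeric(start), stage = c(0, 0, 0),
                 mode = "track", spiral_origin = NULL, spiral_k = 0L,
                 last_tracked = as.numeric(start)),
            class = "tracker_state")
}

#' One feedback iteration of the orbital tracker
#'
#' Applies the positioning algorithm to the counts of one illuminated
#' orbit. If the count rate (planes summed) reaches the threshold, the
#' particle displacement is estimated from the first-order Fourier
#' coefficients and the two look-up tables and the orbit centre is moved
#' onto the estimate (taking effect from the next orbit). Below threshold
#' the tracker switches to search mode and the next probe position comes
#' from [spiral_search()].
#'
#' @param state A `tracker_state`.
#' @param counts [sector_counts()] measured at the current orbit centre.
#' @param cfg [orbit_config()].
#' @param lut_xy,lut_z Look-up tables from [build_lut()].
#' @return List `state` (updated) and `record` (one-row data.frame:
#'   `t_s, x_nm, y_nm, z_nm, counts, tracked, recenter_axis`).
#' @export
feedback_step <- function(state, counts, cfg, lut_xy, lut_z) {
  total <- sum(counts$counts)
  center <- state$stage + state$galvo
  if (total >= cfg$count_threshold) {
    dxy <- localize_xy(counts, lut_xy, cfg)
    dz <- localize_z(counts, lut_z, cfg)
    est <- center + c(dxy[1], dxy[2], dz)
    state$galvo <- state$galvo + c(dxy[1], dxy[2], dz)
    state$mode <- "track"
    state$spiral_origin <- NULL
    state$spiral_k <- 0L
    state$last_tracked <- est
    rec <- data.frame(t_s = counts$timestamp, x_nm = est[1], y_nm = est[2],
                      z_nm = est[3], counts = total, tracked = TRUE,
                      recenter_axis = "", stringsAsFactors = FALSE)
  } else {
    if (state$mode != "search") {
      state$mode <- "search"
      state$spiral_origin <- state$galvo
      state$spiral_k <- 0L
    }
    rec <- data.frame(t_s = counts$timestamp, x_nm = NA_real_,
                      y_nm = NA_real_, z_nm = NA_real_, counts = total,
                      tracked = FALSE, recenter_axis = "",
                      stringsAsFactors = FALSE)
  }
  list(state = state, record = rec)
}

#' Next probe centre of the lateral search spiral
#'
#' When the count rate drops below threshold, the tracker probes successive
#' positions on an Archimedean spiral about the position where the particle
#' was lost, advancing `spiral_step` radians per orbit and gaining
#' `spiral_pitch` nm radius per turn.
#'
#' @param state A `tracker_state` in search mode.
#' @param cfg [orbit_config()].
#' @return List `state` (spiral counter advanced, galvo moved to the probe
#'   centre) and `lost` (`TRUE` once the spiral radius exceeds
#'   `spiral_max_radius`).
#' @export
spiral_search <- function(state, cfg) {
  stopifnot(state$mode == "search", !is.null(state$spiral_origin))
  state$spiral_k <- state$spiral_k + 1L
  theta <- state$spiral_k * cfg$spiral_step
  r <- cfg$spiral_pitch * theta / (2 * pi)
  if (r > cfg$spiral_max_radius) return(list(state = state, lost = TRUE))
  state$galvo <- state$spiral_origin +
    c(r * cos(theta), r * sin(theta), 0)
  list(state = state, lost = FALSE)
}

#' Long-range stage recentering
#'
#' Checks the lateral galvo offsets against the recentering threshold. When
#' an axis exceeds it, the sample stage absorbs that offset, the galvo
#' returns to rest on that axis and tracking pauses for the axis dead time.
#' Sample-fixed coordinates (stage + galvo) are continuous across the
#' event.
#'
#' @param state A `tracker_state`.
#' @param cfg [orbit_config()].
#' @param t Current time (s).
#' @return List `state`, `axis` (`""` if no event) and `dead_until` (time
#'   until which no localization records are produced; `-Inf` if none).
#' @export
long_range_recenter <- function(state, cfg, t = 0) {
  axis <- ""
  dead_until <- -Inf
  for (ax in 1:2) {
    if (abs(state$galvo[ax]) > cfg$recenter_threshold) {
      state$stage[ax] <- state$stage[ax] + state$galvo[ax]
      state$galvo[ax] <- 0
      nm <- c("x", "y")[ax]
      axis <- if (nzchar(axis)) paste0(axis, nm) else nm
      dead_until <- max(dead_until, t + cfg$recenter_dead_time[[nm]])
    }
  }
  list(state = state, axis = axis, dead_until = dead_until)
}

#' Closed-loop orbital tracking of a simulated emitter
#'
#' Runs the full feedback loop against the physical simulator: for every
#' orbit the emitter is placed at its ground-truth position, sector counts
#' are drawn, and the tracker updates the orbit centre (spiral search below
#' threshold, long-range recentering beyond the threshold offset, dark
#' orbits interleaved). Records are produced for illuminated orbits
#' outside recentering dead times.
#'
#' @param truth Ground-truth motion: either a data.frame with `t_s`,
#'   `true_x_nm`/`x_nm`, `true_y_nm`/`y_nm`, `true_z_nm`/`z_nm` (positions
#'   interpolated to orbit times) or a function `f(t)` returning a length-3
#'   position.
#' @param psf [psf_model()].
#' @param em [emitter()] template (its position field is overridden by the
#'   ground truth each orbit; brightness/length/bleaching are used).
#' @param cfg [orbit_config()].
#' @param duration Tracking duration (s); defaults to the truth extent.
#' @param lut_xy,lut_z Look-up tables; built from `psf`/`cfg` when missing.
#' @param noise Poisson photon noise on sector counts.
#' @param start Initial orbit centre; defaults to the true position at t=0.
#' @param seed Optional integer seed.
#' @return A `raw_trajectory`: data.frame `t_s, x_nm, y_nm, z_nm, counts,
#'   tracked, recenter_axis` with attributes `status` ("ok" or "lost"),
#'   `config`, and `luts`.
#' @export
run_tracking <- function(truth, psf, em, cfg = orbit_config(),
                         duration = NULL, lut_xy = NULL, lut_z = NULL,
                         noise = TRUE, start = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.function(truth)) {
    pos_fun <- truth
    stopifnot(!is.null(duration))
  } else {
    tx <- if ("true_x_nm" %in% names(truth)) truth$true_x_nm else truth$x_nm
    ty <- if ("true_y_nm" %in% names(truth)) truth$true_y_nm else truth$y_nm
    tz <- if ("true_z_nm" %in% names(truth)) truth$true_z_nm else truth$z_nm
    tt <- truth$t_s
    pos_fun <- function(t) c(stats::approx(tt, tx, t, rule = 2)$y,
                             stats::approx(tt, ty, t, rule = 2)$y,
                             stats::approx(tt, tz, t, rule = 2)$y)
    if (is.null(duration)) duration <- max(tt) - min(tt)
  }
  if (duration < 1) stop("ground truth duration must be >= 1 s")
  if (is.null(lut_xy)) lut_xy <- build_lut(psf, cfg, "lateral")
  if (is.null(lut_z)) lut_z <- build_lut(psf, cfg, "axial")
  if (is.null(start)) start <- pos_fun(0)
  state <- tracker_state(start)
  n_orbits <- floor(duration / cfg$orbit_period)
  nd <- cfg$dark_orbit_factor
  brightness <- em$brightness
  dead_until <- -Inf
  status <- "ok"
  recs <- vector("list", n_orbits)
  ri <- 0L
  prev_galvo <- state$galvo
  for (i in seq_len(n_orbits)) {
    t <- (i - 1) * cfg$orbit_period
    if ((i - 1) %% nd != 0) next           # dark orbit: laser off, no record
    if (t < dead_until) next               # stage moving: no localization
    em$position <- pos_fun(t)
    em$brightness <- brightness
    center <- state$stage + state$galvo
    means <- sector_mean_counts(psf, em, center, cfg$orbit_radius,
                                cfg$n_sectors)
    if (nd == 1 && state$mode == "track" && !identical(prev_galvo, state$galvo)) {
      # 'on the fly' update: the first sector of the new orbit still runs
      # from the previous centre
      old_center <- state$stage + prev_galvo
      m_old <- sector_mean_counts(psf, em, old_center, cfg$orbit_radius,
                                  cfg$n_sectors)
      means[1, ] <- m_old[1, ]
    }
    cts <- if (noise) matrix(stats::rpois(length(means), means),
                             nrow = cfg$n_sectors) else means
    sc <- sector_counts(cts, timestamp = t, orbit_center = center)
    prev_galvo <- state$galvo
    if (em$bleach_rate > 0) brightness <- brightness * exp(-em$bleach_rate)
    fb <- feedback_step(state, sc, cfg, lut_xy, lut_z)
    state <- fb$state
    rec <- fb$record
    if (state$mode == "search") {
      sp <- spiral_search(state, cfg)
      state <- sp$state
      if (sp$lost) { status <- "lost"; ri <- ri + 1L; recs[[ri]] <- rec; break }
    } else {
      lr <- long_range_recenter(state, cfg, t)
      state <- lr$state
      if (nzchar(lr$axis)) {
        rec$recenter_axis <- lr$axis
        dead_until <- lr$dead_until
      }
    }
    ri <- ri + 1L
    recs[[ri]] <- rec
  }
  out <- do.call(rbind, recs[seq_len(ri)])
  attr(out, "status") <- status
  attr(out, "config") <- cfg
  attr(out, "luts") <- list(xy = lut_xy, z = lut_z)
  class(out) <- c("raw_trajectory", "data.frame")
  out
}
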