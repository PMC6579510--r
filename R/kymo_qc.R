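#' Kymograph projection of a trajectory
#'
#' Projects the trajectory onto the axon axis (x) against time, carrying
#' the per-sample motion-state label for colour coding.
#'
#' @param traj Trajectory data.frame (`t_s`, `x_nm`).
#' @param labels Optional per-sample state labels (character).
#' @return data.frame `t_s`, `x_um`, `state`.
#' @export
kymograph <- function(traj, labels = NULL) {
  stopifnot(nrow(traj) >= 1)
  data.frame(t_s = traj$t_s, x_um = traj$x_nm / 1000,
             state = labels %||% rep("unlabeled", nrow(traj)),
             stringsAsFactors = FALSE)
}

#' @rdname kymograph
#' @param ky A [kymograph()] data.frame.
#' @param objects Optional stationary-object table (`x_nm`, `length_nm`)
#'   overlaid as horizontal bands.
#' @param palette Named colours per state.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_kymograph <- function(ky, objects = NULL,
                           palette = c(fast_antero = "forestgreen",
                                       slow_antero = "gold",
                                       fast_retro = "royalblue",
                                       slow_retro = "darkorange",
                                       stationary = "red",
                                       unlabeled = "grey40"), ...) {
  graphics::plot(ky$t_s, ky$x_um, type = "n", xlab = "time (s)",
                 ylab = "position along axon (µm)", ...)
  if (!is.null(objects)) {
    for (i in seq_len(nrow(objects))) {
      graphics::rect(min(ky$t_s), (objects$x_nm[i] - objects$length_nm[i] / 2) / 1000,
                     max(ky$t_s), (objects$x_nm[i] + objects$length_nm[i] / 2) / 1000,
                     col = grDevices::adjustcolor("grey", 0.4), border = NA)
    }
  }
  cols <- palette[ky$state]
  cols[is.na(cols)] <- "grey40"
  graphics::points(ky$t_s, ky$x_um, col = cols, pch = 16, cex = 0.3)
  invisible(ky)
}

#' Heartbeat-artifact screen for in vivo trajectories
#'
#' Trajectories recorded close to blood vessels pick up a periodic
#' oscillation perpendicular to the transport axis. This screen computes
#' the amplitude spectrum of the lateral component perpendicular to the
#' axon axis (y), after removing slow drift with a 1 s running mean, and
#' flags the trajectory when a spectral peak inside the heartbeat band
#' exceeds the amplitude threshold.
#'
#' @param traj Trajectory data.frame (`t_s`, `y_nm`), >= 10 s of data.
#' @param band Frequency band to screen (Hz), default 1-4.
#' @param amp_threshold Peak oscillation amplitude (nm) above which the
#'   trajectory is flagged.
#' @param detrend_window Running-mean window (s) removed before the FFT.
#' @return List with `flagged`, `peak_freq_hz`, `peak_amp_nm` and the
#'   `spectrum` data.frame (`freq_hz`, `amp_nm`).
#' @export
qc_heartbeat <- function(traj, band = c(1, 4), amp_threshold = 15,
                         detrend_window = 1) {
  dt <- stats::median(diff(traj$t_s))
  if ((nrow(traj) - 1) * dt < 10) stop("at least 10 s of data are required")
  k <- ceiling(detrend_window / dt)
  if (k %% 2 == 0) k <- k + 1
  y <- traj$y_nm - smooth_positions(traj$y_nm, k)
  n <- length(y)
  sp <- stats::fft(y)
  freq <- (seq_len(n) - 1) / (n * dt)
  half <- 2:floor(n / 2)
  amp <- 2 * Mod(sp[half]) / n
  freq <- freq[half]
  inband <- freq >= band[1] & freq <= band[2]
  if (!any(inband))
    return(list(flagged = FALSE, peak_freq_hz = NA_real_,
                peak_amp_nm = NA_real_,
                spectrum = data.frame(freq_hz = freq, amp_nm = amp)))
  i <- which(inband)[which.max(amp[inband])]
  list(flagged = amp[i] > amp_threshold, peak_freq_hz = freq[i],
       peak_amp_nm = amp[i],
       spectrum = data.frame(freq_hz = freq, amp_nm = amp))
}
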