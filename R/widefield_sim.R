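#' Describe a synthetic wide-field scene
#'
#' A wide-field scene holds the static content and the camera model for
#' rendering a time-lapse movie of the axon: stationary blobs (resting
#' mitochondria, rendered as diffraction-blurred line segments), one moving
#' blob following a supplied trajectory, and a Poisson + Gaussian read-noise
#' camera. The field of view is anchored at `origin` (sample-fixed nm of the
#' centre of pixel (1,1)) and shifts at long-range recentering events.
#'
#' @param shape Image shape in pixels, `c(ny, nx)`.
#' @param pixel_size Camera pixel size in nm/px (default 135).
#' @param frame_rate Frames per second (default 2).
#' @param stationary data.frame with columns `x_nm`, `y_nm` (centroid),
#'   `length_nm`, `intensity` and optionally `orientation` (radians,
#'   default 0 = along the axon/x axis).
#' @param moving_intensity Peak-integrated intensity of the moving blob
#'   (counts per frame); 0 disables it.
#' @param psf_sigma Gaussian blur s.d. of the widefield PSF (nm).
#' @param background Mean background level (counts/px/frame).
#' @param read_noise Gaussian read noise s.d. (counts).
#' @param origin Sample-fixed nm coordinates of pixel (1,1), `c(x, y)`.
#' @return A `widefield_scene` object.
#' @export
widefield_scene <- function(shape = c(128, 128), pixel_size = 135,
                            frame_rate = 2,
                            stationary = NULL, moving_intensity = 2000,
                            psf_sigma = 120, background = 10,
                            read_noise = 2, origin = c(0, 0)) {
  stopifnot(pixel_size > 0, frame_rate > 0, psf_sigma > 0,
            background >= 0, read_noise >= 0)
  if (!is.null(stationary)) {
    stopifnot(all(c("x_nm", "y_nm", "length_nm", "intensity") %in%
                    names(stationary)))
    if (is.null(stationary$orientation)) stationary$orientation <- 0
    fx <- (stationary$x_nm - origin[1]) / pixel_size
    fy <- (stationary$y_nm - origin[2]) / pixel_size
    if (any(fx < 0 | fx > shape[2] - 1 | fy < 0 | fy > shape[1] - 1))
      stop("all stationary blob positions must lie inside the field of view")
  }
  structure(list(shape = shape, pixel_size = pixel_size,
                 frame_rate = frame_rate, stationary = stationary,
                 moving_intensity = moving_intensity, psf_sigma = psf_sigma,
                 background = background, read_noise = read_noise,
                 origin = origin),
            class = "widefield_scene")
}

# Add a blurred line blob to an image (in place, returns image).
# cx, cy in pixel units (0-based centre of pixel (1,1) at 0), length in px.
render_blob <- function(img, cx, cy, len_px, theta, intensity, sigma_px,
                        n_sub = 15) {
  ny <- nrow(img); nx <- ncol(img)
  if (len_px <= 0) n_sub <- 1
  u <- if (n_sub == 1) 0 else seq(-len_px / 2, len_px / 2, length.out = n_sub)
  sx <- cx + u * cos(theta)
  sy <- cy + u * sin(theta)
  half <- ceiling(4 * sigma_px + len_px / 2) + 1
  x0 <- max(1, floor(cx - half)); x1 <- min(nx, ceiling(cx + half))
  y0 <- max(1, floor(cy - half)); y1 <- min(ny, ceiling(cy + half))
  if (x0 > x1 || y0 > y1) return(img)
  px <- (x0:x1) - 1; py <- (y0:y1) - 1
  amp <- intensity / (n_sub * 2 * pi * sigma_px^2)
  gx <- exp(-outer(px, sx, "-")^2 / (2 * sigma_px^2)) # (nx_loc x n_sub)
  gy <- exp(-outer(py, sy, "-")^2 / (2 * sigma_px^2)) # (ny_loc x n_sub)
  img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] + amp * gy %*% t(gx)
  img
}

#' Render a synthetic wide-field movie
#'
#' Renders the scene at `frame_rate` over the duration of the supplied
#' ground-truth trajectory. Stationary blobs are drawn in every frame at
#' fixed sample coordinates; the moving blob is drawn at the trajectory
#' position linearly interpolated to the frame time. At each recentering
#' event the field of view jumps so that the tracked particle returns to the
#' field centre, emulating the stage recentering of long-range tracking.
#'
#' @param scene A [widefield_scene()].
#' @param truth A trajectory data.frame with columns `t_s`, `x_nm`, `y_nm`
#'   (e.g. from [generate_state_trajectory()]).
#' @param recenter_times Numeric vector of recentering event times (s); may
#'   be empty.
#' @param noise Draw Poisson + read noise (`TRUE`) or return noiseless
#'   expectations.
#' @return A numeric array `ny x nx x nframes` with attributes
#'   `pixel_size`, `frame_interval`, `recenter_frames` (frame indices of the
#'   events) and `origins` (nframes x 2 matrix of the sample-fixed origin of
#'   each frame).
#' @export
render_widefield_movie <- function(scene, truth, recenter_times = numeric(0),
                                   noise = TRUE) {
  stopifnot(inherits(scene, "widefield_scene"))
  if (is.null(truth) || nrow(truth) == 0) stop("empty trajectory")
  dur <- max(truth$t_s) - min(truth$t_s)
  if (scene$frame_rate > 1 / mean(diff(truth$t_s)) + 1e-9)
    stop("scene frame rate must not exceed the trajectory sample rate")
  nf <- floor(dur * scene$frame_rate)
  if (nf < 1) stop("trajectory too short for one frame")
  tf <- min(truth$t_s) + (seq_len(nf) - 1) / scene$frame_rate
  mx <- stats::approx(truth$t_s, truth$x_nm, xout = tf)$y
  my <- stats::approx(truth$t_s, truth$y_nm, xout = tf)$y
  ny <- scene$shape[1]; nx <- scene$shape[2]
  recenter_times <- sort(recenter_times)
  rec_frames <- integer(0)
  origins <- matrix(NA_real_, nf, 2)
  origin <- scene$origin
  centre_px <- c((nx - 1) / 2, (ny - 1) / 2)
  out <- array(0, dim = c(ny, nx, nf))
  sig_px <- scene$psf_sigma / scene$pixel_size
  next_rec <- 1L
  for (i in seq_len(nf)) {
    while (next_rec <= length(recenter_times) &&
           recenter_times[next_rec] <= tf[i]) {
      # stage recentering: put the tracked particle back at the field centre
      origin <- c(mx[i] - centre_px[1] * scene$pixel_size,
                  my[i] - centre_px[2] * scene$pixel_size)
      rec_frames <- c(rec_frames, i)
      next_rec <- next_rec + 1L
    }
    origins[i, ] <- origin
    img <- matrix(scene$background, ny, nx)
    st <- scene$stationary
    if (!is.null(st)) for (b in seq_len(nrow(st))) {
      img <- render_blob(img,
                         (st$x_nm[b] - origin[1]) / scene$pixel_size,
                         (st$y_nm[b] - origin[2]) / scene$pixel_size,
                         st$length_nm[b] / scene$pixel_size,
                         st$orientation[b], st$intensity[b], sig_px)
    }
    if (scene$moving_intensity > 0) {
      img <- render_blob(img,
                         (mx[i] - origin[1]) / scene$pixel_size,
                         (my[i] - origin[2]) / scene$pixel_size,
                         0, 0, scene$moving_intensity, sig_px)
    }
    if (noise) {
      img <- matrix(stats::rpois(length(img), img) +
                      stats::rnorm(length(img), 0, scene$read_noise), ny, nx)
      img[img < 0] <- 0
    }
    out[, , i] <- img
  }
  structure(out, pixel_size = scene$pixel_size,
            frame_interval = 1 / scene$frame_rate,
            recenter_frames = unique(rec_frames), origins = origins)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Images are stored as 32-bit float TIFF pages scaled by `scale` so that
#' photon counts survive the round trip exactly up to floating precision.
#'
#' @param stack Numeric array ny x nx x nframes.
#' @param path Output file.
#' @param scale Divisor applied before writing (float TIFF range).
#' @return `path`, invisibly (writer); the array (reader).
#' @export
write_movie_tiff <- function(stack, path, scale = 1) {
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (i in seq_along(pages)) out[, , i] <- pages[[i]] * scale
  out
}
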