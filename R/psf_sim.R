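#' Gaussian-beam PSF model for orbital tracking
#'
#' Describes the confocal excitation/detection volume used by the orbital
#' tracker: a lateral Gaussian beam of 1/e^2 radius `w_xy`, an axial Gaussian
#' envelope of 1/e^2 half-width `w_z`, and two detection planes placed
#' equidistant above and below the orbit focal plane, separated by
#' `plane_sep`. `background` is the expected background count rate in
#' photons per orbit and per detection plane.
#'
#' @param w_xy Lateral 1/e^2 beam waist (nm). Default 300 nm.
#' @param w_z Axial 1/e^2 half-width of the detection envelope (nm).
#'   Default 700 nm.
#' @param plane_sep Axial distance between the two detection planes (nm).
#'   Default 1000 nm.
#' @param background Expected background photons per orbit per plane (>= 0).
#' @return An object of class `psf_model`.
#' @examples
#' psf <- psf_model()
#' @export
psf_model <- function(w_xy = 300, w_z = 700, plane_sep = 1000, background = 0) {
  stopifnot(is.numeric(w_xy), w_xy > 0, is.numeric(w_z), w_z > 0,
            is.numeric(plane_sep), plane_sep > 0,
            is.numeric(background), background >= 0)
  structure(list(w_xy = w_xy, w_z = w_z, plane_sep = plane_sep,
                 background = background),
            class = "psf_model")
}

#' A fluorescent emitter (point or extended)
#'
#' An emitter is a point source or, for `length > 0`, a uniform line of
#' sub-emitters in the lateral plane whose total brightness equals
#' `brightness`. Mitochondria are well approximated by such a line segment.
#'
#' @param position Numeric length-3, sample-fixed position (x, y, z) in nm.
#' @param brightness Expected photons per orbit and per detection plane for a
#'   point emitter sitting exactly on the beam axis in the focal plane,
#'   before axial-plane attenuation.
#' @param length Emitter extent in nm (0 = point emitter).
#' @param orientation Orientation of the line in the lateral plane, radians
#'   from the x axis.
#' @param bleach_rate Per-illuminated-orbit exponential decay rate of the
#'   brightness (>= 0; 0 = no bleaching).
#' @return An object of class `emitter`.
#' @export
emitter <- function(position = c(0, 0, 0), brightness = 500, length = 0,
                    orientation = 0, bleach_rate = 0) {
  stopifnot(length(position) == 3, all(is.finite(position)),
            brightness >= 0, length >= 0, bleach_rate >= 0)
  structure(list(position = as.numeric(position), brightness = brightness,
                 length = length, orientation = orientation,
                 bleach_rate = bleach_rate),
            class = "emitter")
}

# Lateral sub-emitter offsets for a line emitter; a point emitter is a single
# sub-emitter. Offsets are relative to the emitter centre, each carrying
# brightness/n so that the total equals the nominal brightness.
sub_emitter_offsets <- function(em, n_sub = 33) {
  if (em$length <= 0) return(cbind(0, 0))
  # midpoint rule: O(h^2) error, no endpoint bias
  u <- em$length * ((seq_len(n_sub) - 0.5) / n_sub - 0.5)
  cbind(u * cos(em$orientation), u * sin(em$orientation))
}

#' Expected photon rate from an emitter for a given beam position
#'
#' Evaluates the Gaussian-beam response of one detection plane: for a point
#' emitter at lateral distance r from the beam axis and axial distance
#' (z - z_plane) from a detection plane,
#' rate = brightness * exp(-2 r^2 / w_xy^2) * exp(-2 (z - z_plane)^2 / w_z^2).
#' For an extended emitter the response is averaged over the uniform line of
#' sub-emitters. The value is a rate per unit orbit fraction: integrating it
#' over a full orbit (e.g. averaging over sector positions and summing the
#' sectors) yields expected photons per orbit.
#'
#' @param psf A [psf_model()].
#' @param em An [emitter()].
#' @param beam_center Numeric length-3, beam focal position (x, y, z) in nm.
#'   Detection plane `plane` sits at `z + plane_sep/2` (plane 1) or
#'   `z - plane_sep/2` (plane 2).
#' @param plane 1 or 2.
#' @param n_sub Number of sub-emitters used for the line integral of an
#'   extended emitter.
#' @return Non-negative expected rate (photons per orbit, per plane, for a
#'   beam dwelling at `beam_center` the whole orbit).
#' @export
expected_rate <- function(psf, em, beam_center, plane = 1, n_sub = 33) {
  stopifnot(inherits(psf, "psf_model"), inherits(em, "emitter"))
  if (!all(is.finite(beam_center)) || length(beam_center) != 3)
    stop("invalid geometry: beam_center must be a finite (x, y, z) position")
  if (!plane %in% c(1, 2)) stop("plane must be 1 or 2")
  off <- sub_emitter_offsets(em, n_sub)
  dx <- em$position[1] + off[, 1] - beam_center[1]
  dy <- em$position[2] + off[, 2] - beam_center[2]
  lat <- mean(exp(-2 * (dx^2 + dy^2) / psf$w_xy^2))
  z_plane <- beam_center[3] + if (plane == 1) psf$plane_sep / 2 else -psf$plane_sep / 2
  ax <- exp(-2 * (em$position[3] - z_plane)^2 / psf$w_z^2)
  em$brightness * lat * ax
}

# Expected sector means for one orbit: an n_sectors x 2 matrix of expected
# photon counts per sector and detection plane (background included).
# The beam sweeps each sector; the sector mean is approximated by averaging
# the point response at `arc_pts` equally spaced positions along the arc.
sector_mean_counts <- function(psf, em, orbit_center, orbit_radius,
                               n_sectors = 16, arc_pts = 5, n_sub = 33) {
  if (orbit_radius <= 0) stop("orbit_radius must be > 0 (no modulation possible)")
  k <- rep(seq_len(n_sectors), each = arc_pts)
  j <- rep(seq_len(arc_pts), times = n_sectors)
  phi <- 2 * pi * ((k - 1) + (j - 0.5) / arc_pts) / n_sectors
  bx <- orbit_center[1] + orbit_radius * cos(phi)
  by <- orbit_center[2] + orbit_radius * sin(phi)
  off <- sub_emitter_offsets(em, n_sub)
  # lateral response averaged over sub-emitters, for each beam arc position
  ex <- outer(bx, em$position[1] + off[, 1], "-")
  ey <- outer(by, em$position[2] + off[, 2], "-")
  lat <- rowMeans(exp(-2 * (ex^2 + ey^2) / psf$w_xy^2))
  sec_lat <- colMeans(matrix(lat, nrow = arc_pts)) # mean over arc positions
  z1 <- orbit_center[3] + psf$plane_sep / 2
  z2 <- orbit_center[3] - psf$plane_sep / 2
  ax <- exp(-2 * (em$position[3] - c(z1, z2))^2 / psf$w_z^2)
  means <- em$brightness * outer(sec_lat, ax) / n_sectors
  means + psf$background / n_sectors
}

#' Simulate the photon counts of a single orbit
#'
#' Sweeps the beam around a circle of radius `orbit_radius` about
#' `orbit_center` and draws, for each of `n_sectors` angular sectors and each
#' of the two detection planes, a Poisson photon count whose mean is the
#' sector-averaged Gaussian-beam response plus background.
#'
#' @inheritParams expected_rate
#' @param orbit_center Beam orbit centre (x, y, z) nm.
#' @param orbit_radius Orbit radius in nm (> 0).
#' @param n_sectors Number of angular sectors (default 16).
#' @param noise If `FALSE`, return the expected means instead of Poisson draws.
#' @param timestamp Time attached to the orbit (s).
#' @param arc_pts Arc positions averaged per sector (beam motion within a
#'   sector).
#' @return A `sector_counts` object: list with `counts` (n_sectors x 2
#'   matrix), `timestamp`, `orbit_center`, `illuminated`.
#' @export
simulate_orbit <- function(psf, em, orbit_center, orbit_radius,
                           n_sectors = 16, noise = TRUE, timestamp = 0,
                           arc_pts = 5) {
  means <- sector_mean_counts(psf, em, orbit_center, orbit_radius,
                              n_sectors, arc_pts)
  counts <- if (noise) {
    matrix(stats::rpois(length(means), means), nrow = n_sectors)
  } else means
  sector_counts(counts, timestamp = timestamp, orbit_center = orbit_center)
}

#' Construct a sector-counts record
#'
#' @param counts n_sectors x 2 matrix of photon counts (sectors x detection
#'   planes), non-negative.
#' @param timestamp Orbit time (s).
#' @param orbit_center Beam orbit centre (nm).
#' @param illuminated `FALSE` for dark orbits (which carry zero counts and
#'   are excluded from localization).
#' @return A `sector_counts` object.
#' @export
sector_counts <- function(counts, timestamp = 0, orbit_center = c(0, 0, 0),
                          illuminated = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2, nrow(counts) >= 8, all(counts >= 0))
  structure(list(counts = counts, timestamp = timestamp,
                 orbit_center = orbit_center, illuminated = illuminated),
            class = "sector_counts")
}
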