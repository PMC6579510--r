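# Shared fixtures: default optics and memoized look-up tables (built once
# per test run; building them is deterministic and noiseless).
.fixtures <- new.env(parent = emptyenv())

default_psf <- function() psf_model()
default_cfg <- function(...) orbit_config(...)

get_luts <- function() {
  if (is.null(.fixtures$luts)) {
    psf <- default_psf()
    cfg <- default_cfg()
    .fixtures$luts <- list(xy = build_lut(psf, cfg, "lateral"),
                           z = build_lut(psf, cfg, "axial"))
  }
  .fixtures$luts
}

# Quadrature oracle: orbit-averaged total expected photons per orbit for a
# (possibly extended) emitter, integrating the point response along the
# orbit with n_quad points and along the emitter line with n_line points.
quadrature_orbit_total <- function(psf, em, center, r_orbit,
                                   n_quad = 2000, n_line = 1000) {
  phi <- 2 * pi * (seq_len(n_quad) - 0.5) / n_quad
  bx <- center[1] + r_orbit * cos(phi)
  by <- center[2] + r_orbit * sin(phi)
  u <- if (em$length > 0)
    seq(-em$length / 2, em$length / 2, length.out = n_line) else 0
  ex <- em$position[1] + u * cos(em$orientation)
  ey <- em$position[2] + u * sin(em$orientation)
  lat <- rowMeans(exp(-2 * (outer(bx, ex, "-")^2 + outer(by, ey, "-")^2) /
                        psf$w_xy^2))
  ax <- exp(-2 * (em$position[3] - center[3] -
                    c(1, -1) * psf$plane_sep / 2)^2 / psf$w_z^2)
  em$brightness * mean(lat) * sum(ax)
}

# Noiseless sector means for a given emitter offset (planes kept separate).
noiseless_orbit <- function(psf, em, center = c(0, 0, 0),
                            cfg = default_cfg()) {
  orbitrack:::sector_mean_counts(psf, em, center, cfg$orbit_radius,
                                 cfg$n_sectors)
}

# Simple noiseless trajectory data.frame helper.
straight_traj <- function(v_um_s = 0.5, duration = 2, dt = 0.01, y = 0) {
  t <- seq(0, duration, by = dt)
  data.frame(t_s = t, x_nm = v_um_s * 1000 * t, y_nm = rep(y, length(t)),
             z_nm = 0)
}
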