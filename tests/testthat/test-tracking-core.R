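test_that("first-order Fourier coefficients follow the stated convention", {
  phi <- 2 * pi * (1:16 - 0.5) / 16
  expect_equal(first_order_coeffs(cbind(rep(100, 16), 0)),
               list(a0 = 200, a1 = 0, b1 = 0, no_signal = FALSE))
  fc <- first_order_coeffs(cbind(100 + 50 * cos(phi), 0))
  expect_equal(c(fc$a0, fc$a1, fc$b1), c(200, 50, 0), tolerance = 1e-12)
  fc <- first_order_coeffs(cbind(100 + 50 * sin(phi), 0))
  expect_equal(atan2(fc$b1, fc$a1), pi / 2, tolerance = 1e-12)
  expect_true(first_order_coeffs(cbind(rep(0, 16), 0))$no_signal)
})

test_that("lateral localization matches a grid-search oracle", {
  psf <- default_psf(); cfg <- default_cfg(); luts <- get_luts()
  # uniform counts = centered particle
  z <- localize_xy(sector_counts(cbind(rep(50, 16), rep(50, 16))),
                   luts$xy, cfg)
  expect_equal(as.numeric(z), c(0, 0), tolerance = 1e-9)

  em <- emitter(position = c(50, 0, 0), brightness = 1000)
  m <- noiseless_orbit(psf, em)
  est <- localize_xy(sector_counts(m), luts$xy, cfg)

  # oracle: dense grid search minimizing the squared difference between
  # the measured and predicted sector means
  grid <- expand.grid(dx = seq(40, 60, by = 0.25), dy = seq(-5, 5, by = 0.25))
  sse <- mapply(function(dx, dy) {
    emg <- emitter(position = c(dx, dy, 0), brightness = 1000)
    sum((noiseless_orbit(psf, emg) - m)^2)
  }, grid$dx, grid$dy)
  best <- grid[which.min(sse), ]
  expect_equal(as.numeric(est), c(best$dx, best$dy), tolerance = 0.5)
  expect_equal(as.numeric(est), c(50, 0), tolerance = 1)

  # rotational equivariance: offset rotated by 90 degrees
  em90 <- emitter(position = c(0, 50, 0), brightness = 1000)
  est90 <- localize_xy(sector_counts(noiseless_orbit(psf, em90)), luts$xy, cfg)
  expect_equal(as.numeric(est90), c(0, 50), tolerance = 1)
})

test_that("axial localization recovers the plane-contrast displacement", {
  psf <- default_psf(); cfg <- default_cfg(); luts <- get_luts()
  expect_equal(as.numeric(localize_z(c(100, 100), luts$z, cfg)), 0,
               tolerance = 1e-9)
  expect_gt(as.numeric(localize_z(c(150, 100), luts$z, cfg)), 0)
  expect_true(attr(localize_z(c(0, 0), luts$z, cfg), "no_signal"))

  em <- emitter(position = c(0, 0, 200), brightness = 1000)
  m <- noiseless_orbit(psf, em)
  expect_equal(as.numeric(localize_z(sector_counts(m), luts$z, cfg)), 200,
               tolerance = 5)
})

test_that("look-up tables are monotone and invert the forward model", {
  psf <- default_psf(); cfg <- default_cfg(); luts <- get_luts()
  expect_equal(stats::approx(luts$xy$mod, luts$xy$disp, 0)$y, 0)
  expect_true(all(diff(luts$xy$mod) > 0))
  expect_true(all(diff(luts$z$mod) > 0))

  # lateral round trip over the valid range: error <= max(1 %, 1 nm)
  for (d in seq(10, 220, by = 30)) {
    em <- emitter(position = c(d, 0, 0), brightness = 1000)
    est <- localize_xy(sector_counts(noiseless_orbit(psf, em)), luts$xy, cfg)
    expect_lt(abs(est[1] - d), max(0.01 * d, 1))
    expect_lt(abs(est[2]), 1)
  }
  # axial round trip: error <= 5 nm
  for (z in seq(-600, 600, by = 200)) {
    em <- emitter(position = c(0, 0, z), brightness = 1000)
    est <- localize_z(sector_counts(noiseless_orbit(psf, em)), luts$z, cfg)
    expect_lt(abs(est - z), 5)
  }
})

test_that("an extended emitter localizes at its centre of mass", {
  # the first-order coefficients encode the excitation-weighted centre of
  # mass; with the extension perpendicular to the displacement the
  # weighting is symmetric and the estimate matches the point emitter
  psf <- default_psf(); cfg <- default_cfg(); luts <- get_luts()
  for (len in c(100, 200)) {
    emp <- emitter(position = c(80, 0, 0), brightness = 1000)
    eml <- emitter(position = c(80, 0, 0), brightness = 1000, length = len,
                   orientation = pi / 2)
    dp <- localize_xy(sector_counts(noiseless_orbit(psf, emp)), luts$xy, cfg)[1]
    dl <- localize_xy(sector_counts(noiseless_orbit(psf, eml)), luts$xy, cfg)[1]
    expect_lt(abs(dl - dp) / dp, 0.02)
  }
  # at the tracking fixed point (centered orbit) symmetry makes the
  # estimate exactly zero whatever the length or orientation
  for (orient in c(0, pi / 3)) {
    eml <- emitter(position = c(0, 0, 0), brightness = 1000, length = 600,
                   orientation = orient)
    dl <- localize_xy(sector_counts(noiseless_orbit(psf, eml)), luts$xy, cfg)
    expect_lt(sqrt(sum(dl^2)), 1e-6)
  }
})

test_that("feedback converges onto a stationary emitter within 3 orbits", {
  psf <- default_psf(); cfg <- default_cfg(); luts <- get_luts()
  em <- emitter(brightness = 1000)
  st <- tracker_state(c(100, 0, 0))
  for (i in 1:3) {
    m <- noiseless_orbit(psf, em, center = st$stage + st$galvo)
    fb <- feedback_step(st, sector_counts(m, timestamp = i * 0.005), cfg,
                        luts$xy, luts$z)
    st <- fb$state
  }
  expect_lt(sqrt(sum((st$stage + st$galvo - em$position)^2)), 1)
  expect_true(fb$record$tracked)

  # counts below threshold engage the search modus
  fb2 <- feedback_step(st, sector_counts(matrix(0, 16, 2)), cfg,
                       luts$xy, luts$z)
  expect_false(fb2$record$tracked)
  expect_identical(fb2$state$mode, "search")
})

test_that("the search spiral grows monotonically and reacquires", {
  cfg <- default_cfg(count_threshold = 50)
  st <- tracker_state(); st$mode <- "search"; st$spiral_origin <- c(0, 0, 0)
  radii <- numeric(40)
  for (k in 1:40) {
    sp <- spiral_search(st, cfg)
    st <- sp$state
    radii[k] <- sqrt(sum((st$galvo[1:2])^2))
  }
  expect_true(all(diff(radii) >= 0))
  expect_false(sp$lost)

  # emitter jumping 800 nm away: counts fall below threshold, the spiral
  # engages and reacquires. Geometric oracle: the capture radius is the
  # largest probe-emitter distance at which the noiseless count rate still
  # reaches the threshold; the spiral must reacquire within one turn after
  # first reaching (jump - capture) radius.
  psf <- default_psf(); luts <- get_luts()
  em <- emitter(brightness = 1500)
  counts_at <- function(d) {
    em$position <- c(d, 0, 0)
    sum(noiseless_orbit(psf, em, cfg = cfg))
  }
  capture <- uniroot(function(d) counts_at(d) - cfg$count_threshold,
                     c(100, 2000))$root
  jump_d <- 800
  expect_lt(capture, jump_d) # the jump genuinely loses the particle
  jump <- function(t) if (t < 0.5) c(0, 0, 0) else
    jump_d * c(cos(0.7), sin(0.7), 0)
  em$position <- c(0, 0, 0)
  tr <- run_tracking(jump, psf, em, cfg, duration = 3,
                     lut_xy = luts$xy, lut_z = luts$z, noise = FALSE)
  expect_identical(attr(tr, "status"), "ok")
  lost_at <- tr$t_s[!tr$tracked][1]
  reacq <- tr$t_s[tr$tracked & tr$t_s > lost_at][1]
  expect_false(is.na(reacq))
  turn_probes <- ceiling(2 * pi / cfg$spiral_step)
  k_max <- ceiling((jump_d - capture) / cfg$spiral_pitch * turn_probes) +
    turn_probes
  expect_lt(reacq - lost_at,
            (k_max + 2) * cfg$orbit_period * cfg$dark_orbit_factor)
  # once reacquired, tracking settles back onto the emitter
  tail_est <- tr[tr$t_s > 2.5 & tr$tracked, c("x_nm", "y_nm")]
  expect_equal(colMeans(tail_est), c(x_nm = jump_d * cos(0.7),
                                     y_nm = jump_d * sin(0.7)),
               tolerance = 0.01)

  # a vanished emitter exhausts the spiral and the run ends as lost
  gone <- function(t) if (t < 0.2) c(0, 0, 0) else c(1e6, 0, 0)
  tr2 <- run_tracking(gone, psf, emitter(brightness = 1500), cfg,
                      duration = 20, lut_xy = luts$xy, lut_z = luts$z,
                      noise = FALSE)
  expect_identical(attr(tr2, "status"), "lost")
})

test_that("long-range recentering preserves sample-fixed continuity", {
  cfg <- default_cfg()
  st <- tracker_state(c(2000, -3000, 0))
  lr <- long_range_recenter(st, cfg, t = 1)
  expect_identical(lr$axis, "")

  st$galvo <- c(10100, 0, 0)
  lr <- long_range_recenter(st, cfg, t = 1)
  expect_identical(lr$axis, "x")
  expect_equal(lr$state$stage[1], 10100)
  expect_equal(lr$state$galvo[1], 0)
  expect_equal(lr$dead_until, 1 + 0.063)

  # closed loop: constant velocity crossing the threshold
  psf <- default_psf(); luts <- get_luts()
  tr <- run_tracking(function(t) c(3000 * t, 0, 0), psf,
                     emitter(brightness = 1600), cfg, duration = 5,
                     lut_xy = luts$xy, lut_z = luts$z, seed = 4)
  ev <- which(nzchar(tr$recenter_axis))
  expect_length(ev, 1)
  t_ev <- tr$t_s[ev]
  # records pause for the x dead time
  expect_gte(tr$t_s[ev + 1] - t_ev, 0.063)
  # no step discontinuity: residual level matches before and after
  res <- tr$x_nm - 3000 * tr$t_s
  before <- res[tr$t_s > t_ev - 1 & tr$t_s <= t_ev]
  after <- res[tr$t_s > t_ev & tr$t_s <= t_ev + 1]
  sigma <- sd(res[tr$t_s < t_ev - 1])
  expect_lt(abs(mean(after) - mean(before)), 2 * sigma)
})

test_that("dark orbits halve the sampling rate without harming tracking", {
  psf <- default_psf(); luts <- get_luts()
  cfg2 <- default_cfg(dark_orbit_factor = 2, orbit_period = 0.005)
  tr <- run_tracking(function(t) c(0, 0, 0), psf, emitter(brightness = 1000),
                     cfg2, duration = 1.5, lut_xy = luts$xy, lut_z = luts$z,
                     seed = 5)
  expect_equal(median(diff(tr$t_s)), 0.01) # 100 Hz effective sampling
  expect_true(all(tr$tracked))
})

test_that("localization precision scales with photon shot noise", {
  psf <- default_psf(); luts <- get_luts(); cfg <- default_cfg()
  N <- c(200, 800, 3200)
  stds <- vapply(seq_along(N), function(i) {
    tr <- run_tracking(function(t) c(0, 0, 0), psf,
                       emitter(brightness = N[i]), cfg, duration = 3,
                       lut_xy = luts$xy, lut_z = luts$z, seed = 10 + i)
    sd(tr$x_nm)
  }, numeric(1))
  slope <- coef(lm(log(stds) ~ log(N)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  # quadrupling the photons halves the noise (within 20 %)
  expect_equal(stds[1] / stds[2], 2, tolerance = 0.2)
})
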