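# Shared synthetic scene: an axon along x in mid-field, two resting
# mitochondria, one moving blob crossing the field.
make_scene_fixture <- function(seed = 5, duration = 60, snr_intensity = 3000,
                               stationary = NULL) {
  set.seed(seed)
  axon_y <- 48 * 135
  # an anterograde-dominant track sweeps through the field of view
  truth <- generate_state_trajectory(motion_params_invivo(),
                                     duration = duration, seed = seed)
  truth$y_nm <- truth$y_nm + axon_y
  origin <- c(-1350, 0)
  if (is.null(stationary)) {
    # rest the blobs on the in-field part of the path (inside the corridor)
    xs <- truth$x_nm[truth$x_nm > 0 & truth$x_nm < origin[1] + 92 * 135]
    bx <- stats::quantile(xs, c(0.3, 0.75))
    stationary <- data.frame(x_nm = as.numeric(bx),
                             y_nm = axon_y + c(-100, 100),
                             length_nm = c(1000, 1400),
                             intensity = snr_intensity)
  }
  scene <- widefield_scene(shape = c(96, 96), pixel_size = 135,
                           stationary = stationary,
                           moving_intensity = snr_intensity,
                           origin = origin)
  list(truth = truth, scene = scene, origin = origin, axon_y = axon_y)
}

traj_to_px <- function(truth, origin, pixel_size = 135)
  cbind((truth$x_nm - origin[1]) / pixel_size,
        (truth$y_nm - origin[2]) / pixel_size)

test_that("the polynomial camera map recovers exact and warped transforms", {
  set.seed(1)
  P <- as.matrix(expand.grid(x = seq(0, 96, length.out = 5),
                             y = seq(0, 96, length.out = 5)))
  # identity control points
  m <- fit_poly_map(P, P)
  expect_equal(m$residual_rms, 0, tolerance = 1e-9)
  expect_equal(apply_poly_map(m, rbind(c(10, 20))), rbind(c(10, 20)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # pure translation is inside the affine subset
  m2 <- fit_poly_map(P, cbind(P[, 1] + 500, P[, 2] - 200))
  expect_equal(m2$residual_rms, 0, tolerance = 1e-9)
  expect_equal(apply_poly_map(m2, rbind(c(0, 0))), rbind(c(500, -200)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # synthetic second-order warp sampled at the 25 grid points
  warp <- cbind(135 * P[, 1] + 0.02 * P[, 1]^2 - 0.01 * P[, 1] * P[, 2],
                135 * P[, 2] + 0.015 * P[, 2]^2 + 3)
  m3 <- fit_poly_map(P, warp)
  expect_lt(m3$residual_rms, 1e-6)
  expect_equal(apply_poly_map(m3, P), warp, tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(fit_poly_map(P[1:10, ], P[1:10, ]), "at least 12")
  Pd <- cbind(seq_len(20), 2 * seq_len(20)) # collinear -> rank deficient
  expect_error(fit_poly_map(Pd, Pd), "degenerate")
})

test_that("remove_moving removes movers and leaves resting objects", {
  # static stack: output identical to input (dI = 0), never increased
  fx <- make_scene_fixture()
  static_scene <- fx$scene
  static_scene$moving_intensity <- 0
  mv <- render_widefield_movie(static_scene, fx$truth, noise = FALSE)
  st <- remove_moving(mv, 10)
  expect_equal(st[, , 1], mv[, , 1], tolerance = 1e-12)
  expect_equal(dim(st)[3], dim(mv)[3] - 10)

  # direct substitution: I(t) = 100, I(t+10) = 0 -> I_stationary(t) = 0
  toy <- array(0, dim = c(4, 4, 12)); toy[2, 2, 1] <- 100
  expect_equal(remove_moving(toy, 10)[2, 2, 1], 0)
  expect_error(remove_moving(toy, 12), "lag")

  # full round trip: the moving blob is suppressed below 10 % of its peak
  mv2 <- render_widefield_movie(fx$scene, fx$truth, noise = FALSE)
  st2 <- remove_moving(mv2, 10)
  expect_true(all(st2 <= mv2[, , seq_len(dim(st2)[3])] + 1e-9))
  m <- mean_segments(st2)[[1]]
  mover_px <- traj_to_px(fx$truth, fx$origin)
  peak <- max(mv2) # rendered mover/stationary peak intensity
  # probe the mean image along the mover's path, away from resting blobs
  bl <- fx$scene$stationary
  away <- abs(fx$truth$x_nm - bl$x_nm[1]) > bl$length_nm[1] / 2 + 1000 &
    abs(fx$truth$x_nm - bl$x_nm[2]) > bl$length_nm[2] / 2 + 1000
  probe <- unique(round(mover_px[away, , drop = FALSE]))
  probe <- probe[probe[, 1] >= 0 & probe[, 1] < 96 &
                   probe[, 2] >= 0 & probe[, 2] < 96, , drop = FALSE]
  vals <- m[cbind(probe[, 2] + 1, probe[, 1] + 1)]
  expect_lt(max(vals) - fx$scene$background, 0.1 * peak)
  # while the resting blobs survive in the mean image: compare against the
  # noiseless static scene (mover disabled)
  sc0 <- fx$scene; sc0$moving_intensity <- 0
  ref <- render_widefield_movie(sc0, fx$truth, noise = FALSE)[, , 1]
  iy <- round(bl$y_nm[1] / 135) + 1
  ix <- round((bl$x_nm[1] - fx$origin[1]) / 135) + 1
  expect_gt(m[iy, ix] - fx$scene$background,
            0.7 * (ref[iy, ix] - fx$scene$background))
})

test_that("mean segments are split at recentering events", {
  toy <- array(rep(1:6, each = 4), dim = c(2, 2, 6))
  # two events -> three segments, the last discarded -> 2 mean images
  ms <- mean_segments(toy, recenter_frames = c(3, 5))
  expect_length(ms, 2)
  expect_equal(ms[[1]], matrix(1.5, 2, 2))
  expect_equal(ms[[2]], matrix(3.5, 2, 2))
  # no events: the single mean image is kept
  ms0 <- mean_segments(toy, recenter_frames = integer(0))
  expect_length(ms0, 1)
  expect_equal(ms0[[1]], matrix(3.5, 2, 2))

  # noisy piecewise-static movie: segment means approach the scene
  fx <- make_scene_fixture()
  sc <- fx$scene; sc$moving_intensity <- 0
  mv <- render_widefield_movie(sc, fx$truth, noise = TRUE)
  truth_img <- render_widefield_movie(sc, fx$truth, noise = FALSE)[, , 1]
  m <- mean_segments(mv, integer(0))[[1]]
  n <- dim(mv)[3]
  # pixel-wise error ~ sqrt(var/n); compare rms against that scale
  expect_lt(sqrt(mean((m - truth_img)^2)),
            3 * sqrt(max(truth_img) / n + sc$read_noise^2 / n))
})

test_that("stationary-object detection is accurate at SNR >= 10", {
  fx <- make_scene_fixture()
  mv <- render_widefield_movie(fx$scene, fx$truth, noise = TRUE)
  st <- remove_moving(mv, 10)
  m <- mean_segments(st)[[1]]
  tp <- traj_to_px(fx$truth, fx$origin)
  map <- identity_poly_map(135, fx$origin)
  det <- detect_stationary(m, tp, map)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_nm), ]
  bl <- fx$scene$stationary[order(fx$scene$stationary$x_nm), ]
  # centroid within 1 px, length within 2 px
  expect_lt(max(abs(det$x_nm - bl$x_nm)), 135)
  expect_lt(max(abs(det$length_nm - bl$length_nm)), 2 * 135)

  # blank image -> nothing
  expect_equal(nrow(detect_stationary(matrix(0, 96, 96), tp, map)), 0)

  # a bright blob 40 px off the trajectory corridor is excluded
  off <- fx$scene
  off$stationary <- rbind(off$stationary,
                          data.frame(x_nm = off$stationary$x_nm[1],
                                     y_nm = fx$axon_y - 40 * 135,
                                     length_nm = 1000, intensity = 3000,
                                     orientation = 0))
  mv2 <- render_widefield_movie(off, fx$truth, noise = FALSE)
  m2 <- mean_segments(remove_moving(mv2, 10))[[1]]
  det2 <- detect_stationary(m2, tp, map)
  expect_true(all(abs(det2$y_nm - fx$axon_y) < 6 * 135))
  expect_equal(nrow(det2), 2)
})

test_that("detection precision holds across random scenes", {
  # centroid error <= 1 px and length error <= 2 px across random scenes
  set.seed(9)
  errs <- t(replicate(25, {
    seed <- sample.int(1e6, 1)
    axon_y <- 48 * 135
    truth <- generate_state_trajectory(motion_params_invivo(),
                                       duration = 20, seed = seed)
    truth$y_nm <- truth$y_nm + axon_y
    origin <- c(-1350, 0)
    xs <- truth$x_nm[truth$x_nm > 0 & truth$x_nm < origin[1] + 92 * 135]
    x0 <- as.numeric(stats::quantile(xs, runif(1, 0.3, 0.7)))
    len <- runif(1, 800, 1600)
    snr_int <- runif(1, 2000, 4000)
    scene <- widefield_scene(
      shape = c(96, 96), pixel_size = 135, moving_intensity = 0,
      stationary = data.frame(x_nm = x0, y_nm = axon_y + runif(1, -200, 200),
                              length_nm = len, intensity = snr_int),
      origin = origin)
    mv <- render_widefield_movie(scene, truth, noise = TRUE)
    m <- mean_segments(mv, integer(0))[[1]]
    det <- detect_stationary(m, traj_to_px(truth, origin),
                             identity_poly_map(135, origin))
    if (nrow(det) != 1) return(c(NA, NA))
    c(abs(det$x_nm - x0) / 135, abs(det$length_nm - len) / 135)
  }))
  expect_true(all(is.finite(errs)))
  expect_true(all(errs[, 1] <= 1))
  expect_true(all(errs[, 2] <= 2))
})

test_that("occupancy fractions split time by local object presence", {
  t <- seq(0, 10, by = 0.01)
  traj <- data.frame(t_s = t, x_nm = 1000 * t, y_nm = 0)
  lab <- rep("fast_antero", length(t))

  # no objects: everything is free and fractions sum to 1
  occ0 <- occupancy_fractions(lab, traj, NULL)
  expect_identical(unique(occ0$condition), "free")
  expect_equal(sum(occ0$fraction), 1)

  # construction: stationary exactly inside the object zone
  objects <- data.frame(x_nm = 5000, length_nm = 1000)
  lab2 <- ifelse(traj$x_nm >= 4000 & traj$x_nm <= 6000, "stationary",
                 "fast_antero")
  occ <- occupancy_fractions(lab2, traj, objects, capture = 500)
  occd <- occ[occ$condition == "occupied" & occ$state == "stationary", ]
  expect_equal(occd$fraction, 1)
  for (cond in unique(occ$condition))
    expect_equal(sum(occ$fraction[occ$condition == cond]), 1)

  # invariant under time reversal
  occ_rev <- occupancy_fractions(rev(lab2),
                                 data.frame(t_s = t,
                                            x_nm = rev(traj$x_nm), y_nm = 0),
                                 objects, capture = 500)
  expect_equal(occ[order(occ$condition, occ$state), "fraction"],
               occ_rev[order(occ_rev$condition, occ_rev$state), "fraction"])
})

test_that("crossing times profile dwell along the axon", {
  # constant 0.5 um/s: 0.2 s per 100 nm bin
  tr <- straight_traj(0.5, duration = 20)
  ct <- crossing_times(tr)
  mid <- ct$fine$t_1_s[c(-1, -nrow(ct$fine))]
  expect_equal(median(mid, na.rm = TRUE), 0.2, tolerance = 0.01)

  # a 12 s pause inside one 1 um bin flags that bin (> 10 s rule)
  t2 <- seq(0, 32, by = 0.01)
  x2 <- ifelse(t2 < 10, 500 * t2,
        ifelse(t2 < 22, 5000, 5000 + 500 * (t2 - 22)))
  tr2 <- data.frame(t_s = t2, x_nm = x2, y_nm = 0)
  ct2 <- crossing_times(tr2)
  bin5 <- ct2$coarse[ct2$coarse$x_nm == 5500, ]
  expect_equal(bin5$fraction_slow, 1)
  expect_true(all(ct2$coarse$fraction_slow[ct2$coarse$x_nm < 5000] == 0))

  # 16 trajectories sharing a pause site: flagged fraction = pausing fraction
  pause_here <- rep(c(TRUE, FALSE), 8)
  trs <- lapply(seq_len(16), function(i) {
    if (pause_here[i]) tr2 else
      data.frame(t_s = seq(0, 20, by = 0.01),
                 x_nm = 500 * seq(0, 20, by = 0.01), y_nm = 0)
  })
  ct3 <- crossing_times(trs)
  expect_equal(ct3$coarse$fraction_slow[ct3$coarse$x_nm == 5500], 0.5)

  # unvisited bins are missing, not zero
  short <- straight_traj(0.5, duration = 2)
  ct4 <- crossing_times(list(short, tr))
  expect_true(any(is.na(ct4$fine$t_1_s)))
})
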