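#' Write / read a trajectory table
#'
#' Trajectories travel as plain tabular text with a commented header that
#' records units and the coordinate convention (sample-fixed nm, x = axon
#' axis, anterograde = +x). Positions are written with 1e-3 nm precision so
#' a write/read round trip is lossless at that resolution.
#'
#' @param traj Trajectory data.frame (any subset of `t_s`, `x_nm`, `y_nm`,
#'   `z_nm`, `counts`, `tracked`, `recenter_axis`, `state`, ...).
#' @param path Output file.
#' @return `path` invisibly (writer); the data.frame with a `header`
#'   attribute (reader).
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# orbitrack trajectory table",
    "# coordinates: sample-fixed nm; x = axon axis; anterograde = +x",
    "# t_s: time [s]; *_nm: position [nm]; counts: photons/orbit;",
    "# tracked: logical; recenter_axis: x/y/'' ; state: motion state label",
    paste0("# columns: ", paste(names(traj), collapse = "\t"))), con)
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param col_map Optional named character vector renaming file columns to
#'   the canonical names, e.g. `c(t_s = "time", x_nm = "x")` for deposited
#'   trajectory files with a different dialect.
#' @param ... Passed to [utils::read.table()].
#' @export
read_trajectory <- function(path, col_map = NULL, ...) {
  hdr <- character(0)
  con <- file(path, "r")
  while (length(l <- readLines(con, 1)) && startsWith(l, "#"))
    hdr <- c(hdr, l)
  close(con)
  if (length(l) == 0) stop("empty trajectory file")
  # tab-delimited files may carry empty fields (e.g. recenter_axis)
  sep <- if (grepl("\t", l)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, fill = TRUE, ...)
  if ("recenter_axis" %in% names(df))
    df$recenter_axis[is.na(df$recenter_axis)] <- ""
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df))
        names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  if (!is.null(df$t_s) && is.unsorted(df$t_s))
    stop("trajectory times must be monotone increasing")
  attr(df, "header") <- hdr
  df
}

#' Default run configuration
#'
#' Nested configuration for a full simulate-track-segment-colocalize run,
#' serializable to YAML. Serializing then parsing a configuration is the
#' identity.
#'
#' @param seed Global integer seed from which every stochastic stage
#'   derives its own stream.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    psf = list(w_xy = 300, w_z = 700, plane_sep = 1000, background = 0),
    orbit = list(orbit_radius = 150, n_sectors = 16, orbit_period = 0.005,
                 dark_orbit_factor = 2, count_threshold = 20,
                 recenter_threshold = 10000,
                 recenter_dead_time = list(x = 0.063, y = 0.035)),
    emitter = list(brightness = 500, length = 0, bleach_rate = 0),
    motion = list(preset = "invivo", direction = "anterograde",
                  duration = 60, sigma = 5, sigma_z = 30, dt = 0.01),
    segmentation = list(window = 64, tau_interval = c(0.03, 0.06),
                        smooth = 5, n_shuffles = 10, min_active = 0.15,
                        mode = "cosine"),
    widefield = list(shape = c(128, 128), pixel_size = 135, frame_rate = 2,
                     moving_intensity = 2000, psf_sigma = 120,
                     background = 10, read_noise = 2, remove_lag = 10,
                     k_sigma = 5, corridor = c(51, 11), capture = 500)),
    class = "run_config")
}

#' @rdname default_config
#' @param config A `run_config` (or plain nested list).
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' @rdname default_config
#' @return `config_hash()`: the md5 of the canonical YAML serialization.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

as_psf <- function(cfg) do.call(psf_model, cfg$psf)
as_orbit_cfg <- function(cfg) {
  oc <- cfg$orbit
  oc$recenter_dead_time <- unlist(oc$recenter_dead_time)
  oc$plane_sep <- cfg$psf$plane_sep
  do.call(orbit_config, oc)
}
as_motion_params <- function(cfg) {
  m <- cfg$motion
  if (identical(m$preset, "uniform"))
    motion_params_uniform(sigma = m$sigma, sigma_z = m$sigma_z, dt = m$dt)
  else
    motion_params_invivo(direction = m$direction, sigma = m$sigma,
                         sigma_z = m$sigma_z, dt = m$dt)
}
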