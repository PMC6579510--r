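#' Second-order polynomial camera-to-tracking coordinate map
#'
#' Fits two bivariate second-order polynomials mapping camera pixel
#' coordinates to tracking-frame nm, from paired control points (25
#' back-reflection locations are recommended; at least 12 well-spread
#' points are required).
#'
#' @param camera_px n x 2 matrix/data.frame of camera coordinates (px).
#' @param tracking_nm n x 2 matrix/data.frame of tracking coordinates (nm).
#' @return A `poly_map_2d`: list with `coef` (6 x 2 coefficient matrix for
#'   the basis 1, x, y, x^2, xy, y^2) and `residual_rms` (nm).
#' @export
fit_poly_map <- function(camera_px, tracking_nm) {
  P <- as.matrix(camera_px); Q <- as.matrix(tracking_nm)
  stopifnot(ncol(P) == 2, ncol(Q) == 2, nrow(P) == nrow(Q))
  if (nrow(P) < 12) stop("at least 12 control points are required (25 recommended)")
  X <- poly_design(P)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("degenerate control-point configuration (rank-deficient design)")
  coef <- qr.coef(qrX, Q)
  res <- Q - X %*% coef
  structure(list(coef = coef, residual_rms = sqrt(mean(res^2))),
            class = "poly_map_2d")
}

poly_design <- function(P)
  cbind(1, P[, 1], P[, 2], P[, 1]^2, P[, 1] * P[, 2], P[, 2]^2)

#' @rdname fit_poly_map
#' @param map A `poly_map_2d`.
#' @param pts n x 2 camera coordinates to transform.
#' @return n x 2 matrix of tracking-frame nm.
#' @export
apply_poly_map <- function(map, pts) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
  poly_design(pts) %*% map$coef
}

#' Identity camera-to-tracking map
#'
#' Convenience map for synthetic data where camera pixels and tracking
#' coordinates share the frame up to the pixel pitch and an offset.
#'
#' @param pixel_size nm per pixel.
#' @param origin Tracking-frame nm of camera pixel (0, 0).
#' @return A `poly_map_2d`.
#' @export
identity_poly_map <- function(pixel_size = 135, origin = c(0, 0)) {
  coef <- matrix(0, 6, 2)
  coef[1, ] <- origin
  coef[2, 1] <- pixel_size
  coef[3, 2] <- pixel_size
  structure(list(coef = coef, residual_rms = 0), class = "poly_map_2d")
}
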