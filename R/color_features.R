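#' Colour feature names used by the pixel segmentation model
#'
#' Fifteen features from five colour spaces, in fixed order:
#' RGB (scaled to \[0,1\]), HSV (H in degrees), CIELAB, CIELUV and
#' YCbCr (BT.601 full range, scaled to \[0,1\]).
#'
#' @return Character vector of length 15.
#' @export
color_feature_names <- function() {
  c("r", "g", "b",
    "h", "s", "v",
    "l_lab", "a_lab", "b_lab",
    "l_luv", "u_luv", "v_luv",
    "y_ycbcr", "cb", "cr")
}

# sRGB gamma expansion, vectorised.
srgb_linearize <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

# D65 reference white (2 degree observer), Y normalised to 1.
D65 <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

#' Compute the 15 colour features for a set of 8-bit RGB pixels
#'
#' Converts sRGB pixels (D65 white point) into the feature vector used by
#' the decision-tree segmentation model: raw channels scaled to \[0,1\];
#' HSV with hue in degrees (H = 0 for achromatic pixels); CIELAB; CIELUV;
#' and full-range BT.601 YCbCr scaled to \[0,1\].
#'
#' @param rgb Numeric matrix with three columns (R, G, B) in \[0,255\],
#'   or a single length-3 vector.
#' @return Numeric matrix, one row per pixel, 15 named columns
#'   (see [color_feature_names()]).
#' @examples
#' color_features(c(255, 0, 0))["h"]   # 0 degrees
#' @export
color_features <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  rgb <- as.matrix(rgb)
  stopifnot(ncol(rgb) == 3, all(is.finite(rgb)), all(rgb >= 0), all(rgb <= 255))
  r <- rgb[, 1] / 255; g <- rgb[, 2] / 255; b <- rgb[, 3] / 255

  # HSV -- grDevices::rgb2hsv returns h as a fraction of a turn
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  h_deg <- hsv["h", ] * 360
  h_deg[h_deg >= 360] <- 0

  # linear RGB -> XYZ (sRGB primaries, D65)
  rl <- srgb_linearize(r); gl <- srgb_linearize(g); bl <- srgb_linearize(b)
  X <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  Y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  Z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl

  # CIELAB
  eps <- (6 / 29)^3
  fxyz <- function(t) ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- fxyz(X / D65["X"]); fy <- fxyz(Y / D65["Y"]); fz <- fxyz(Z / D65["Z"])
  L <- 116 * fy - 16
  a_lab <- 500 * (fx - fy)
  b_lab <- 200 * (fy - fz)

  # CIELUV (same L*)
  up <- function(X, Y, Z) 4 * X / (X + 15 * Y + 3 * Z)
  vp <- function(X, Y, Z) 9 * Y / (X + 15 * Y + 3 * Z)
  denom <- X + 15 * Y + 3 * Z
  u_prime <- ifelse(denom > 0, 4 * X / denom, 0)
  v_prime <- ifelse(denom > 0, 9 * Y / denom, 0)
  un <- up(D65["X"], D65["Y"], D65["Z"])
  vn <- vp(D65["X"], D65["Y"], D65["Z"])
  u_luv <- 13 * L * (u_prime - un)
  v_luv <- 13 * L * (v_prime - vn)

  # YCbCr, BT.601 full range, kept in [0, 1]
  yy <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- (b - yy) / 1.772 + 0.5
  cr <- (r - yy) / 1.402 + 0.5

  out <- cbind(r, g, b, h_deg, hsv["s", ], hsv["v", ],
               L, a_lab, b_lab, L, u_luv, v_luv, yy, cb, cr)
  dimnames(out) <- list(NULL, color_feature_names())
  out
}

#' Colour features for every pixel of an image
#'
#' @param img Numeric array `H x W x 3` with values in \[0,1\] (as returned
#'   by [png::readPNG()]). Pixels are ordered column-major, matching
#'   `matrix(values, H, W)`.
#' @return Numeric matrix `(H*W) x 15`.
#' @export
image_color_features <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  n <- prod(dim(img)[1:2])
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3])) * 255
  color_features(rgb)
}
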