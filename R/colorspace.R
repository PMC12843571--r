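## RGB <-> YUV and RGB <-> YCbCr conversion.
##
## Structural fusion runs on the luminance (Y) plane only; PET chrominance
## (U,V or Cb,Cr) is carried through the pipeline untouched so that the
## metabolic color map survives fusion exactly.

## Analog BT.601 YUV pair. The V-row green coefficient is -0.515, the
## standard value; with it the gray axis maps to u = v = 0 exactly and the
## inverse below is consistent to ~4e-4 over the RGB cube. A historically
## circulated misprint (-0.1515) is available via `matrix = "printed"`; it
## breaks the gray axis and is kept only for comparison.
.yuv_forward_bt601 <- matrix(c(
  0.299, 0.587, 0.114,
  -0.147, -0.289, 0.436,
  0.615, -0.515, -0.100
), 3, 3, byrow = TRUE)

.yuv_forward_printed <- matrix(c(
  0.299, 0.587, 0.114,
  -0.147, -0.289, 0.436,
  0.615, -0.1515, -0.100
), 3, 3, byrow = TRUE)

.yuv_inverse <- matrix(c(
  1, 0, 1.1401,
  1, -0.395, -0.581,
  1, 2.032, 0
), 3, 3, byrow = TRUE)

apply_color_matrix <- function(img, M) {
  d <- dim(img)
  flat <- matrix(img, d[1] * d[2], 3L)
  out <- flat %*% t(M)
  array(out, dim = d)
}

#' Convert an RGB image to YUV
#'
#' Per-pixel linear map with rows (0.299, 0.587, 0.114),
#' (-0.147, -0.289, 0.436), (0.615, -0.515, -0.100). Gray inputs
#' (r = g = b) yield u = v = 0 to machine precision.
#'
#' @param img H x W x 3 RGB array with values in \[0,1\].
#' @param matrix `"bt601"` (default) or `"printed"` for the misprinted
#'   V-row coefficient -0.1515 (breaks the gray axis; comparison only).
#' @return H x W x 3 array of class `yuv_image` (planes y, u, v).
#' @seealso [yuv_to_rgb()]
#' @export
rgb_to_yuv <- function(img, matrix = c("bt601", "printed")) {
  assert_plane3(img)
  matrix <- match.arg(matrix)
  M <- if (matrix == "bt601") .yuv_forward_bt601 else .yuv_forward_printed
  out <- apply_color_matrix(img, M)
  class(out) <- c("yuv_image", "array")
  out
}

#' Convert a YUV image back to RGB
#'
#' Per-pixel map R = Y + 1.1401 V, G = Y - 0.395 U - 0.581 V,
#' B = Y + 2.032 U; the result is clipped to \[0,1\] (out-of-gamut pixels
#' are saturated).
#'
#' @param img H x W x 3 YUV array.
#' @return H x W x 3 array of class `rgb_image`.
#' @export
yuv_to_rgb <- function(img) {
  assert_plane3(img)
  out <- clip01(apply_color_matrix(img, .yuv_inverse))
  class(out) <- c("rgb_image", "array")
  out
}

#' Convert RGB to full-range BT.601 YCbCr
#'
#' Y = 0.299 R + 0.587 G + 0.114 B, Cb = (B - Y)/1.772 + 0.5,
#' Cr = (R - Y)/1.402 + 0.5. This formulation is an exact algebraic
#' inverse pair with [ycbcr_to_rgb()].
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @return H x W x 3 array of class `ycbcr_image` (planes y, cb, cr; the
#'   chrominance planes are offset-centered at 0.5).
#' @export
rgb_to_ycbcr <- function(img) {
  assert_plane3(img)
  r <- plane(img, 1); g <- plane(img, 2); b <- plane(img, 3)
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- (b - y) / 1.772 + 0.5
  cr <- (r - y) / 1.402 + 0.5
  out <- array(c(y, cb, cr), dim = dim(img))
  class(out) <- c("ycbcr_image", "array")
  out
}

#' Convert full-range BT.601 YCbCr back to RGB
#'
#' Exact inverse of [rgb_to_ycbcr()]; output clipped to \[0,1\].
#'
#' @param img H x W x 3 YCbCr array.
#' @return H x W x 3 array of class `rgb_image`.
#' @export
ycbcr_to_rgb <- function(img) {
  assert_plane3(img)
  y <- plane(img, 1); cb <- plane(img, 2); cr <- plane(img, 3)
  r <- y + 1.402 * (cr - 0.5)
  b <- y + 1.772 * (cb - 0.5)
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- clip01(array(c(r, g, b), dim = dim(img)))
  class(out) <- c("rgb_image", "array")
  out
}

#' Luminance plane of an RGB image
#'
#' The Y row of the YUV conversion: 0.299 R + 0.587 G + 0.114 B. Also used
#' for grayscale conversion when reading color files.
#'
#' @param img H x W x 3 RGB array.
#' @return numeric matrix (Image2D).
#' @export
luminance <- function(img) {
  assert_plane3(img)
  0.299 * plane(img, 1) + 0.587 * plane(img, 2) + 0.114 * plane(img, 3)
}
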