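#' @keywords internal
"_PACKAGE"

## Core image containers and low-level raster utilities.
##
## An Image2D is a plain numeric matrix (rows = image rows) with values on
## the [0,1] intensity scale.  Three-plane images (RGB, YUV, YCbCr) are
## H x W x 3 numeric arrays carrying a lightweight S3 class tag so that
## colorspace bookkeeping is explicit; all pipeline functions also accept
## untagged arrays of the right shape.

#' Clip values to the unit interval
#'
#' @param x numeric vector, matrix or array.
#' @return `x` with every element forced into \[0,1\].
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Min-max rescale to \[0,1\]
#'
#' Used to map signed high-frequency residuals onto the intensity scale the
#' feature extractor expects. A constant input maps to all zeros.
#'
#' @param x numeric matrix or array.
#' @return rescaled object of the same shape.
#' @export
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    return(x * 0)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

assert_image2d <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix (Image2D)", arg), call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("`%s` contains NA values", arg), call. = FALSE)
  invisible(img)
}

assert_plane3 <- function(img, arg = deparse(substitute(img))) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 numeric array", arg), call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("`%s` contains NA values", arg), call. = FALSE)
  invisible(img)
}

#' Construct an RGB image from three planes
#'
#' Planes must share one shape; values are clipped to \[0,1\] on
#' construction.
#'
#' @param r,g,b numeric matrices of identical dimensions.
#' @return an H x W x 3 array of class `rgb_image`.
#' @export
rgb_image <- function(r, g, b) {
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b))) {
    stop("r, g, b planes must have identical dimensions", call. = FALSE)
  }
  out <- array(c(clip01(r), clip01(g), clip01(b)), dim = c(dim(r), 3L))
  class(out) <- c("rgb_image", class(out))
  out
}

#' Construct a YUV image from luminance and chrominance planes
#'
#' The luminance plane is clipped to \[0,1\]; U and V are signed and kept
#' as-is (their natural ranges are about \[-0.436, 0.436\] and
#' \[-0.615, 0.615\]).
#'
#' @param y,u,v numeric matrices of identical dimensions.
#' @return an H x W x 3 array of class `yuv_image`.
#' @export
yuv_image <- function(y, u, v) {
  if (!all(dim(y) == dim(u)) || !all(dim(y) == dim(v))) {
    stop("y, u, v planes must have identical dimensions", call. = FALSE)
  }
  out <- array(c(clip01(y), u, v), dim = c(dim(y), 3L))
  class(out) <- c("yuv_image", class(out))
  out
}

plane <- function(img, i) img[, , i, drop = TRUE]

## ---- deterministic seeded evaluation ------------------------------------

## Evaluate `code` under `set.seed(seed)` while leaving the caller's RNG
## stream untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## ---- padding and window sums --------------------------------------------

## Symmetric (edge-inclusive reflective) index vector for length n, pad r:
## the tiling 1..n, n..1 repeats with period 2n, so pads wider than the
## image fold back again.
reflect_idx <- function(n, r) {
  i <- (1L - r):(n + r)
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Reflective (symmetric) padding of a matrix
#'
#' Pads by mirroring including the edge pixel, the border convention used by
#' every windowed filter in the package.
#'
#' @param img numeric matrix.
#' @param r pad width in pixels on every side.
#' @return padded matrix of size (H+2r) x (W+2r).
#' @export
pad_reflect <- function(img, r) {
  assert_image2d(img)
  img[reflect_idx(nrow(img), r), reflect_idx(ncol(img), r)]
}

## Sliding-window sums over a (2r+1)^2 box with reflective padding,
## computed with a summed-area table; exact (no approximation).
win_sum <- function(img, r) {
  xp <- pad_reflect(img, r)
  n <- nrow(xp); m <- ncol(xp)
  S <- matrix(0, n + 1L, m + 1L)
  S[-1L, -1L] <- t(apply(apply(xp, 2L, cumsum), 1L, cumsum))
  h <- nrow(img); w <- ncol(img)
  ri <- seq_len(h); ci <- seq_len(w)
  k <- 2L * r + 1L
  S[ri + k, ci + k, drop = FALSE] - S[ri, ci + k, drop = FALSE] -
    S[ri + k, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

win_mean <- function(img, r) win_sum(img, r) / (2 * r + 1)^2

## ---- resampling ----------------------------------------------------------

#' Bilinear resize of a matrix or 3-plane array
#'
#' Pixel centers are aligned as in common imaging libraries:
#' `src = (dst + 0.5) * scale - 0.5`, with edge clamping.
#'
#' @param img numeric matrix or H x W x 3 array.
#' @param out_h,out_w output dimensions in pixels.
#' @return resized object of the same kind.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  if (length(dim(img)) == 3L) {
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (c in seq_len(dim(img)[3])) {
      out[, , c] <- resize_bilinear(img[, , c], out_h, out_w)
    }
    class(out) <- class(img)
    return(out)
  }
  assert_image2d(img)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  src_r <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  src_c <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  r0 <- pmin(floor(src_r), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(floor(src_c), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- src_r - r0; fc <- src_c - c0
  a <- img[r0 + 1, c0 + 1, drop = FALSE]
  b <- img[r0 + 1, c1 + 1, drop = FALSE]
  d <- img[r1 + 1, c0 + 1, drop = FALSE]
  e <- img[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w)
  wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}

## Bilinear rotation about the image center (degrees, counter-clockwise);
## samples falling outside the source are filled with `bg`.
rotate_bilinear <- function(img, angle, bg = 0) {
  assert_image2d(img)
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sr <- cos(th) * rr - sin(th) * cc + cy
  sc <- sin(th) * rr + cos(th) * cc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v[!ok] <- bg
    matrix(v, h, w)
  }
  out <- (1 - fr) * ((1 - fc) * gv(r0, c0) + fc * gv(r0, c0 + 1)) +
    fr * ((1 - fc) * gv(r0 + 1, c0) + fc * gv(r0 + 1, c0 + 1))
  out
}

## Separable Gaussian blur with reflective padding; kernel truncated at
## ceiling(3*sigma).
gaussian_blur <- function(img, sigma) {
  assert_image2d(img)
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  xp <- pad_reflect(img, r)
  ## convolve rows then columns
  h <- nrow(img); w <- ncol(img)
  tmp <- matrix(0, h + 2L * r, w)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * xp[, i:(i + w - 1L), drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[i:(i + h - 1L), , drop = FALSE]
  }
  out
}
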