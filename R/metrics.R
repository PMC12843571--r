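## Fusion quality metric suite. No-reference metrics (entropy, standard
## deviation, average gradient) describe the fused image itself;
## reference-based metrics (MSE, PSNR, SSIM, correlation) compare it with
## a ground-truth fused image; the perceptual distance compares deep
## feature maps. All intensities are on the [0,1] scale, so PSNR uses
## MAX = 1 (consequently PSNR = 10 log10(1 / MSE)).

#' Shannon entropy of an image (bits)
#'
#' Histogram entropy over 256 equal-width bins on \[0,1\] (right-closed
#' last bin), `-sum p_i log2 p_i` with `0 log 0 := 0`. Range \[0, 8\].
#'
#' @param img Image2D in \[0,1\].
#' @param bins number of histogram bins (default 256).
#' @return entropy in bits.
#' @export
entropy <- function(img, bins = 256L) {
  assert_image2d(img)
  b <- pmin(floor(as.vector(img) * bins), bins - 1L)
  p <- tabulate(b + 1L, nbins = bins) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Population standard deviation of an image
#'
#' Contrast measure: `sqrt(mean((f - mean(f))^2))` (divide by MN, not
#' MN - 1).
#'
#' @param img Image2D.
#' @return standard deviation in intensity units.
#' @export
std_dev <- function(img) {
  assert_image2d(img)
  mu <- mean(img)
  sqrt(mean((img - mu)^2))
}

#' Average gradient of an image
#'
#' Sharpness measure: the mean over the (M-1) x (N-1) grid of
#' `sqrt((dx^2 + dy^2) / 2)` with forward differences
#' `dx(s,t) = f(s+1,t) - f(s,t)`, `dy(s,t) = f(s,t+1) - f(s,t)`.
#'
#' @param img Image2D with at least 2 rows and 2 columns.
#' @return average gradient (intensity per pixel).
#' @export
avg_gradient <- function(img) {
  assert_image2d(img)
  m <- nrow(img); n <- ncol(img)
  if (m < 2 || n < 2) stop("image must be at least 2 x 2", call. = FALSE)
  dx <- img[-1, -n, drop = FALSE] - img[-m, -n, drop = FALSE]
  dy <- img[-m, -1, drop = FALSE] - img[-m, -n, drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Mean squared error between two images
#'
#' @param ref,img Image2D matrices of identical shape.
#' @return mean of squared differences (intensity^2).
#' @export
mse <- function(ref, img) {
  assert_image2d(ref); assert_image2d(img)
  if (!all(dim(ref) == dim(img))) stop("shape mismatch", call. = FALSE)
  mean((ref - img)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(max_val^2 / MSE)`. Identical images (MSE = 0) return `Inf`
#' with a warning.
#'
#' @param ref,img Image2D matrices of identical shape.
#' @param max_val peak intensity (default 1 for \[0,1\]-scaled images).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, img, max_val = 1) {
  e <- mse(ref, img)
  if (e == 0) {
    warning("MSE is zero; PSNR is infinite")
    return(Inf)
  }
  10 * log10(max_val^2 / e)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma 1.5, symmetric
#' padding) and the universal stabilizing constants
#' `C1 = (0.01 max_val)^2`, `C2 = (0.03 max_val)^2`.
#'
#' @param ref,img Image2D matrices of identical shape.
#' @param max_val peak intensity (default 1).
#' @param window_radius half-size of the Gaussian window (default 5).
#' @param sigma Gaussian window scale (default 1.5).
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(ref, img, max_val = 1, window_radius = 5L, sigma = 1.5) {
  assert_image2d(ref); assert_image2d(img)
  if (!all(dim(ref) == dim(img))) stop("shape mismatch", call. = FALSE)
  r <- window_radius
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  fil <- function(x) {
    xp <- pad_reflect(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(2 * r + 1)) {
      for (j in seq_len(2 * r + 1)) {
        out <- out + k[i, j] *
          xp[i:(i + nrow(x) - 1L), j:(j + ncol(x) - 1L), drop = FALSE]
      }
    }
    out
  }
  c1 <- (0.01 * max_val)^2
  c2 <- (0.03 * max_val)^2
  mu_x <- fil(ref); mu_y <- fil(img)
  sxx <- fil(ref * ref) - mu_x^2
  syy <- fil(img * img) - mu_y^2
  sxy <- fil(ref * img) - mu_x * mu_y
  smap <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(smap)
}

#' Pearson correlation coefficient between two images
#'
#' Linear correlation over all pixels (population statistics). Undefined
#' (error) when either image is constant.
#'
#' @param ref,img Image2D matrices of identical shape.
#' @return correlation in \[-1, 1\].
#' @export
cc <- function(ref, img) {
  assert_image2d(ref); assert_image2d(img)
  if (!all(dim(ref) == dim(img))) stop("shape mismatch", call. = FALSE)
  sr <- std_dev(ref); si <- std_dev(img)
  if (sr == 0 || si == 0) {
    stop("correlation undefined: an input image is constant", call. = FALSE)
  }
  mean((ref - mean(ref)) * (img - mean(img))) / (sr * si)
}

#' Perceptual distance between two color images
#'
#' Deep-feature distance in the LPIPS style: both images are passed
#' through a convolutional feature extractor; per block, feature vectors
#' are unit-normalized along the channel axis and the mean squared
#' difference is taken over positions; block values (scaled into \[0,1\]
#' by the unit-sphere diameter) are averaged with uniform weights. Zero
#' for identical images, symmetric, bounded in \[0,1\].
#'
#' Uniform layer/channel weights are used in place of learned calibration
#' weights, so values are comparable within a study but not with published
#' LPIPS numbers.
#'
#' @param img1,img2 H x W x 3 RGB arrays in \[0,1\].
#' @param backend a `feature_extractor` (see [vgg_backbone()]).
#' @return perceptual distance in \[0, 1\].
#' @export
perceptual_distance <- function(img1, img2, backend) {
  assert_plane3(img1); assert_plane3(img2)
  if (!inherits(backend, "feature_extractor")) {
    stop("backend must be a feature_extractor", call. = FALSE)
  }
  f1 <- extract_features(backend, img1)
  f2 <- extract_features(backend, img2)
  unit_norm <- function(f) {
    nrm <- sqrt(apply(f^2, c(1, 2), sum)) + 1e-10
    f / array(nrm, dim = dim(f))
  }
  vals <- mapply(function(a, b) {
    a <- unit_norm(a); b <- unit_norm(b)
    ## squared distance between unit vectors is at most 4
    mean(apply((a - b)^2, c(1, 2), sum)) / 4
  }, f1, f2)
  mean(vals)
}

#' Evaluate a fused result against references
#'
#' No-reference metrics (EN, SD, AG) are computed on the luminance of the
#' fused RGB image; reference-based metrics (MSE, PSNR, SSIM, CC) on
#' luminance against the supplied reference; perceptual distances on RGB
#' against up to three references (ground-truth proxy, PET, MRI). Fields
#' without a supplied reference are omitted.
#'
#' @param fused a `fused_result` or an H x W x 3 RGB array.
#' @param reference optional RGB ground-truth image.
#' @param pet,mri optional RGB/grayscale originals for the multi-reference
#'   perceptual protocol.
#' @param perceptual_backend optional `feature_extractor`; if absent, the
#'   perceptual fields are omitted.
#' @return one-row data.frame (the metrics report).
#' @export
evaluate <- function(fused, reference = NULL, pet = NULL, mri = NULL,
                     perceptual_backend = NULL) {
  fused_rgb <- if (inherits(fused, "fused_result")) fused$fused_rgb else fused
  assert_plane3(fused_rgb)
  lum <- luminance(fused_rgb)
  rep_row <- data.frame(en = entropy(lum), sd = std_dev(lum),
                        ag = avg_gradient(lum))
  if (!is.null(reference)) {
    ref_lum <- if (length(dim(reference)) == 3L) luminance(reference) else reference
    m <- mse(ref_lum, lum)
    rep_row$mse <- m
    rep_row$psnr <- if (m == 0) Inf else 10 * log10(1 / m)
    rep_row$ssim <- ssim(ref_lum, lum)
    rep_row$cc <- cc(ref_lum, lum)
  }
  if (!is.null(perceptual_backend)) {
    as_rgb3 <- function(x) {
      if (length(dim(x)) == 3L) x else array(rep(x, 3), dim = c(dim(x), 3L))
    }
    if (!is.null(reference)) {
      rep_row$lpips_ref <- perceptual_distance(fused_rgb, as_rgb3(reference),
                                               perceptual_backend)
    }
    if (!is.null(pet)) {
      rep_row$lpips_pet <- perceptual_distance(fused_rgb, as_rgb3(pet),
                                               perceptual_backend)
    }
    if (!is.null(mri)) {
      rep_row$lpips_mri <- perceptual_distance(fused_rgb, as_rgb3(mri),
                                               perceptual_backend)
    }
  }
  rep_row
}

#' Write a metrics report to CSV
#'
#' @param report data.frame as returned by [evaluate()] (rows may be
#'   accumulated across pairs).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
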