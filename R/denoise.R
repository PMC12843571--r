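## Hybrid denoising chain: bilateral filtering for MRI, two-phase
## non-local means + guided filtering for PET. Every filter uses symmetric
## (edge-inclusive reflective) padding and evaluates its defining formula
## exactly: the vectorized implementations are algebraically identical to a
## direct double loop over the window definitions.

#' Bilateral filter parameters
#'
#' @param sigma_s spatial Gaussian scale in pixels.
#' @param sigma_r range (intensity) Gaussian scale.
#' @param radius half-window in pixels; the window is (2r+1) x (2r+1).
#' @return list of class `bilateral_params`.
#' @export
bilateral_params <- function(sigma_s = 3, sigma_r = 0.1, radius = 5L) {
  stopifnot(sigma_s > 0, sigma_r > 0, radius >= 1)
  structure(list(sigma_s = sigma_s, sigma_r = sigma_r, radius = as.integer(radius)),
            class = "bilateral_params")
}

#' Non-local means parameters
#'
#' @param h filtering strength (intensity units); patch distances are
#'   weighted by exp(-||Px - Pi||^2 / h^2).
#' @param patch_radius patch half-size in pixels.
#' @param search_radius search-window half-size in pixels (>= patch_radius).
#' @return list of class `nlm_params`.
#' @export
nlm_params <- function(h = 0.1, patch_radius = 3L, search_radius = 10L) {
  stopifnot(h > 0, patch_radius >= 0, search_radius >= patch_radius)
  structure(list(h = h, patch_radius = as.integer(patch_radius),
                 search_radius = as.integer(search_radius)),
            class = "nlm_params")
}

#' Guided filter parameters
#'
#' @param radius window half-size in pixels.
#' @param eps edge-preservation regularizer (intensity^2 units).
#' @param var_floor tiny additive floor in the a-coefficient denominator so
#'   constant windows (0/0) stay defined even at eps = 0.
#' @return list of class `guided_params`.
#' @export
guided_params <- function(radius = 4L, eps = 1e-4, var_floor = 1e-12) {
  stopifnot(radius >= 1, eps >= 0, var_floor >= 0)
  structure(list(radius = as.integer(radius), eps = eps, var_floor = var_floor),
            class = "guided_params")
}

#' Bilateral filter
#'
#' Edge-preserving smoother: each output pixel is the normalized sum of
#' neighbors weighted by a spatial Gaussian of Euclidean pixel distance and
#' a range Gaussian of intensity difference,
#' `Id(x) = sum_i Gs(||x-i||) Gr(|I(x)-I(i)|) I(i) / W(x)`.
#'
#' @param img Image2D in \[0,1\].
#' @param params a [bilateral_params()].
#' @return filtered Image2D.
#' @export
bilateral <- function(img, params = bilateral_params()) {
  assert_image2d(img)
  stopifnot(inherits(params, "bilateral_params"))
  r <- params$radius
  xp <- pad_reflect(img, r)
  h <- nrow(img); w <- ncol(img)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  inv2ss <- 1 / (2 * params$sigma_s^2)
  inv2sr <- 1 / (2 * params$sigma_r^2)
  for (dy in -r:r) {
    for (dx in -r:r) {
      shifted <- xp[(1 + r + dy):(h + r + dy), (1 + r + dx):(w + r + dx), drop = FALSE]
      ws <- exp(-(dy^2 + dx^2) * inv2ss)
      wgt <- ws * exp(-(img - shifted)^2 * inv2sr)
      num <- num + wgt * shifted
      den <- den + wgt
    }
  }
  num / den
}

#' Non-local means filter
#'
#' Patch-similarity weighted averaging: for every pixel x, the pixels i of
#' the surrounding search window are averaged with weights
#' `w(x,i) = exp(-||Px - Pi||^2 / h^2) / Z(x)`, where Px, Pi are square
#' patches and Z(x) normalizes the weights to sum to one.
#'
#' Patch distances are computed exactly through per-offset squared
#' difference images and summed-area-table patch sums; the result is
#' identical (to floating-point round-off) to the direct patch loop.
#'
#' @param img Image2D in \[0,1\].
#' @param params an [nlm_params()].
#' @return filtered Image2D.
#' @export
nlm <- function(img, params = nlm_params()) {
  assert_image2d(img)
  stopifnot(inherits(params, "nlm_params"))
  p <- params$patch_radius; s <- params$search_radius
  R <- p + s
  xp <- pad_reflect(img, R)
  h <- nrow(img); w <- ncol(img)
  hp <- nrow(xp); wp <- ncol(xp)
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  inv_h2 <- 1 / params$h^2
  ## the "core" grid covers every pixel any patch can touch: image + p pad
  core_r <- (1L + s):(hp - s)   # length h + 2p
  core_c <- (1L + s):(wp - s)
  k <- 2L * p + 1L
  for (dy in -s:s) {
    for (dx in -s:s) {
      ## squared difference between the padded image and its (dy,dx) shift
      ## on the core grid; |dy|,|dx| <= s keeps every access inside xp
      D <- (xp[core_r, core_c, drop = FALSE] -
            xp[core_r + dy, core_c + dx, drop = FALSE])^2
      ## exact patch sums via a summed-area table: centers sit at rows
      ## p+1..p+h of the core grid, so patch top-left corners are 1..h
      S <- matrix(0, nrow(D) + 1L, ncol(D) + 1L)
      S[-1L, -1L] <- t(apply(apply(D, 2L, cumsum), 1L, cumsum))
      ri <- seq_len(h); ci <- seq_len(w)
      pd <- S[ri + k, ci + k, drop = FALSE] - S[ri, ci + k, drop = FALSE] -
        S[ri + k, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
      wgt <- exp(-pd * inv_h2)
      centers <- xp[(R + dy + 1L):(R + dy + h), (R + dx + 1L):(R + dx + w), drop = FALSE]
      num <- num + wgt * centers
      den <- den + wgt
    }
  }
  num / den
}

#' Guided filter
#'
#' Fits a local linear model of the guide in every (2r+1)^2 window,
#' `a_k = cov(I, p) / (var(I) + eps)`, `b_k = mean(p) - a_k mean(I)`, and
#' averages the coefficients of all windows covering a pixel
#' (overlap-average completion), giving `q = mean(a) * I + mean(b)`.
#'
#' @param p_img noisy input Image2D.
#' @param guide guide Image2D, same shape.
#' @param params a [guided_params()].
#' @return filtered Image2D.
#' @export
guided_filter <- function(p_img, guide, params = guided_params()) {
  assert_image2d(p_img); assert_image2d(guide)
  if (!all(dim(p_img) == dim(guide))) {
    stop("p_img and guide must have identical dimensions", call. = FALSE)
  }
  stopifnot(inherits(params, "guided_params"))
  r <- params$radius
  m_i <- win_mean(guide, r)
  m_p <- win_mean(p_img, r)
  m_ii <- win_mean(guide * guide, r)
  m_ip <- win_mean(guide * p_img, r)
  var_i <- m_ii - m_i * m_i
  cov_ip <- m_ip - m_i * m_p
  a <- cov_ip / (var_i + params$eps + params$var_floor)
  b <- m_p - a * m_i
  win_mean(a, r) * guide + win_mean(b, r)
}

#' Denoise an MRI image
#'
#' Thin wrapper: bilateral filtering with MRI defaults (edge-preserving
#' smoothing of Gaussian scanner noise).
#'
#' @param img Image2D in \[0,1\].
#' @param params a [bilateral_params()].
#' @return denoised Image2D.
#' @export
denoise_mri <- function(img, params = bilateral_params()) {
  bilateral(img, params)
}

#' Denoise a PET image
#'
#' Two-phase chain: per-channel non-local means, then per-channel guided
#' filtering using the luminance of the NLM output as the guide, so that
#' all three channels are regularized toward one shared structural
#' reference.
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @param nlm_params an [nlm_params()].
#' @param guided_params a [guided_params()].
#' @return denoised RGB array (clipped to \[0,1\]).
#' @export
denoise_pet <- function(img, nlm_params = svdfusion::nlm_params(),
                        guided_params = svdfusion::guided_params()) {
  assert_plane3(img)
  step1 <- img
  for (c in 1:3) step1[, , c] <- nlm(plane(img, c), nlm_params)
  guide <- luminance(step1)
  out <- step1
  for (c in 1:3) out[, , c] <- guided_filter(plane(step1, c), guide, guided_params)
  out <- clip01(out)
  class(out) <- c("rgb_image", "array")
  out
}
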