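## Modality-specific synthetic degradation: additive Gaussian noise for MRI
## (scanner-induced statistical fluctuation), Poisson photon noise for PET
## (stochastic photon emission/detection). All draws are seeded and
## bit-reproducible.

#' Noise specification
#'
#' @param kind `"gaussian"`, `"poisson"` or `"none"`.
#' @param sigma2 Gaussian variance on the \[0,1\] intensity scale
#'   (intensity^2 units); the reference degraded condition uses 0.25 and
#'   the sensitivity sweep {0.01, 0.04, 0.09, 0.16, 0.25}.
#' @param peak Poisson photon-count scale: expected counts at intensity 1.
#'   Default 255, an 8-bit photon budget.
#' @param seed integer RNG seed.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "gaussian", "poisson"),
                       sigma2 = 0.25, peak = 255, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (peak <= 0) stop("peak must be > 0", call. = FALSE)
  structure(list(kind = kind, sigma2 = sigma2, peak = peak,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add i.i.d. Gaussian noise to an image
#'
#' Returns `img + N(0, sigma2)` clipped to \[0,1\]. The pre-clip noise
#' field is attached as attribute `"noise_field"` so that variance
#' bookkeeping is not biased by clipping.
#'
#' @param img Image2D (numeric matrix) in \[0,1\].
#' @param sigma2 noise variance (>= 0), intensity^2 units.
#' @param seed integer seed; two calls with the same seed are bit-identical.
#' @param clip clip the output to \[0,1\] (default TRUE).
#' @return degraded Image2D with attribute `noise_field`.
#' @export
add_gaussian <- function(img, sigma2, seed = 1L, clip = TRUE) {
  assert_image2d(img)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 < 0) {
    stop("sigma2 must be a single non-negative number", call. = FALSE)
  }
  if (sigma2 == 0) {
    field <- matrix(0, nrow(img), ncol(img))
    out <- img
  } else {
    field <- with_seed(seed, matrix(stats::rnorm(length(img), 0, sqrt(sigma2)),
                                    nrow(img), ncol(img)))
    out <- img + field
    if (clip) out <- clip01(out)
  }
  attr(out, "noise_field") <- field
  out
}

#' Add Poisson photon noise to an image
#'
#' Intensities are interpreted as expected photon counts `img * peak`;
#' the output is `Poisson(img * peak) / peak`, clipped to \[0,1\].
#' Variance of the output is approximately `img / peak` (variance = mean
#' for Poisson counts).
#'
#' @param img Image2D or H x W x 3 RGB array in \[0,1\]; color images are
#'   degraded independently per channel.
#' @param peak photon-count scale (> 0), counts at intensity 1.
#' @param seed integer seed.
#' @return degraded image of the same shape.
#' @export
add_poisson <- function(img, peak = 255, seed = 1L) {
  if (!is.numeric(peak) || length(peak) != 1L || peak <= 0) {
    stop("peak must be a single positive number", call. = FALSE)
  }
  d <- dim(img)
  counts <- with_seed(seed, stats::rpois(length(img), lambda = as.vector(img) * peak))
  out <- clip01(array(counts / peak, dim = d))
  if (is.matrix(img)) out <- matrix(out, d[1], d[2])
  class(out) <- class(img)
  out
}

#' Apply a noise specification
#'
#' @param img image (matrix or 3-plane array).
#' @param spec a [noise_spec()].
#' @return degraded image.
#' @export
apply_noise <- function(img, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  switch(spec$kind,
    none = img,
    gaussian = add_gaussian(img, spec$sigma2, spec$seed),
    poisson = add_poisson(img, spec$peak, spec$seed)
  )
}

#' Gaussian-variance sweep over an MRI/PET pair
#'
#' Degrades the MRI with each variance in `sigma2_list` while the PET is
#' degraded once with Poisson noise at `peak` under the same seed, so the
#' PET member is identical across entries.
#'
#' @param mri Image2D.
#' @param pet H x W x 3 RGB array.
#' @param sigma2_list non-empty numeric vector of Gaussian variances.
#' @param peak Poisson photon-count scale for the PET member.
#' @param seed integer seed.
#' @return a list with one element per variance, each a list
#'   `(sigma2, mri, pet)`.
#' @export
noise_sweep <- function(mri, pet, sigma2_list = c(0.01, 0.04, 0.09, 0.16, 0.25),
                        peak = 255, seed = 1L) {
  assert_image2d(mri)
  if (length(sigma2_list) == 0) stop("sigma2_list must be non-empty", call. = FALSE)
  pet_noisy <- add_poisson(pet, peak = peak, seed = seed)
  lapply(sigma2_list, function(s2) {
    list(sigma2 = s2,
         mri = add_gaussian(mri, s2, seed = seed),
         pet = pet_noisy)
  })
}
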