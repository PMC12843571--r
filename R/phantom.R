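## Seeded phantom MRI/PET pair generator. The phantoms emulate the two
## structural regimes the pipeline assumes: the MRI is piecewise smooth
## with sharp ellipse boundaries and fine sinusoidal texture (high average
## gradient); the PET is a smooth colored "metabolic" intensity field
## mapped through a hot-style colormap, so it carries low-frequency
## luminance and non-trivial chrominance. A deterministic ground-truth
## proxy enables reference-based metric plumbing without any external
## dataset; it is a synthetic construction, not a claim about how real
## reference fusions are produced.

ellipse_mask <- function(size, cy, cx, ry, rx, angle = 0) {
  rr <- matrix(seq_len(size), size, size) / size - cy
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) / size - cx
  ca <- cos(angle); sa <- sin(angle)
  u <- ca * rr + sa * cc
  v <- -sa * rr + ca * cc
  (u / ry)^2 + (v / rx)^2 <= 1
}

#' Generate a phantom MRI/PET pair
#'
#' MRI: skull ring + brain tissue with a slow radial gradient, seeded
#' internal ellipses (lesion-like structures with sharp boundaries), dark
#' ventricles, and fine sinusoidal texture. PET: a smooth field of seeded
#' Gaussian metabolic blobs mapped through a hot-style colormap
#' (black-red-yellow-white). The ground-truth proxy combines the mean of
#' the two luminances with the PET chrominance.
#'
#' @param seed integer seed; the pair is bit-reproducible given the seed.
#' @param size square image size in pixels (>= 32; default 256).
#' @return list of class `phantom_pair`: `mri` (Image2D), `pet`
#'   (`rgb_image`), `gt_proxy` (`rgb_image`), `params` (seed and size).
#' @export
make_phantom_pair <- function(seed = 1L, size = 256L) {
  if (size < 32) stop("size must be >= 32", call. = FALSE)
  size <- as.integer(size)
  with_seed(seed, {
    rr <- matrix(seq_len(size), size, size) / size
    cc <- matrix(seq_len(size), size, size, byrow = TRUE) / size
    rad <- sqrt((rr - 0.5)^2 + (cc - 0.5)^2)

    ## ---- MRI: piecewise-smooth anatomy with sharp edges ----
    mri <- matrix(0, size, size)
    skull_outer <- ellipse_mask(size, 0.5, 0.5, 0.46, 0.40)
    skull_inner <- ellipse_mask(size, 0.5, 0.5, 0.42, 0.36)
    brain <- ellipse_mask(size, 0.5, 0.5, 0.40, 0.34)
    mri[skull_outer & !skull_inner] <- 0.95
    mri[brain] <- 0.45 + 0.25 * (1 - rad[brain] / 0.5)
    ## ventricles: two dark central ellipses
    vent1 <- ellipse_mask(size, 0.48, 0.44, 0.10, 0.045, 0.3)
    vent2 <- ellipse_mask(size, 0.48, 0.56, 0.10, 0.045, -0.3)
    mri[vent1 | vent2] <- 0.12
    ## lesion-like internal ellipses with sharp boundaries
    n_les <- sample(3:5, 1)
    for (i in seq_len(n_les)) {
      le <- ellipse_mask(size,
                         stats::runif(1, 0.3, 0.7), stats::runif(1, 0.3, 0.7),
                         stats::runif(1, 0.03, 0.09), stats::runif(1, 0.03, 0.09),
                         stats::runif(1, 0, pi))
      le <- le & brain
      mri[le] <- mri[le] + stats::runif(1, -0.3, 0.35)
    }
    ## fine sinusoidal texture inside the brain (gives the MRI its high
    ## average gradient)
    f1 <- stats::runif(1, 24, 40); f2 <- stats::runif(1, 24, 40)
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    tex <- 0.05 * sin(2 * pi * f1 * rr + ph1) * sin(2 * pi * f2 * cc + ph2)
    mri[brain] <- mri[brain] + tex[brain]
    mri <- clip01(mri)

    ## ---- PET: smooth metabolic blobs through a hot colormap ----
    act <- matrix(0, size, size)
    n_blob <- sample(3:5, 1)
    for (i in seq_len(n_blob)) {
      by <- stats::runif(1, 0.3, 0.7); bx <- stats::runif(1, 0.3, 0.7)
      bs <- stats::runif(1, 0.06, 0.16); amp <- stats::runif(1, 0.5, 1)
      act <- act + amp * exp(-((rr - by)^2 + (cc - bx)^2) / (2 * bs^2))
    }
    act <- act / max(act)
    act[!brain] <- act[!brain] * 0.05   # low uptake outside the brain
    ## hot colormap: black -> red -> yellow -> white
    pet <- rgb_image(clip01(3 * act), clip01(3 * act - 1), clip01(3 * act - 2))

    ## ---- ground-truth proxy ----
    pet_yuv <- rgb_to_yuv(pet)
    gt_y <- 0.5 * (mri + plane(pet_yuv, 1))
    gt_proxy <- yuv_to_rgb(array(c(gt_y, plane(pet_yuv, 2), plane(pet_yuv, 3)),
                                 dim = c(size, size, 3L)))

    structure(list(mri = mri, pet = pet, gt_proxy = gt_proxy,
                   params = list(seed = as.integer(seed), size = size,
                                 n_lesions = n_les, n_blobs = n_blob)),
              class = "phantom_pair")
  })
}

#' Generate an image of exact numerical rank r
#'
#' Sum of `r` outer products of seeded positive random vectors, scaled
#' into (0, 1\]; the singular value sigma_{r+1} is zero to round-off.
#' Fixture for the SVD decomposition contracts.
#'
#' @param r target rank, 1 <= r <= size.
#' @param size square image size.
#' @param seed integer seed.
#' @return Image2D of numerical rank `r`.
#' @export
make_rank_r_image <- function(r, size = 32L, seed = 1L) {
  if (r < 1 || r > size) stop("r must be in [1, size]", call. = FALSE)
  with_seed(seed, {
    m <- matrix(0, size, size)
    for (i in seq_len(r)) {
      m <- m + outer(stats::runif(size, 0.1, 1), stats::runif(size, 0.1, 1))
    }
    m / max(m)
  })
}
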