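## Hybrid fusion of a grayscale MRI and a color PET image.
##
## Luminance planes are split by SVD into low-frequency structure L and
## high-frequency detail H. The L components are fused with weights
## proportional to their energies (alpha = E_MRI / (E_MRI + E_PET)); the H
## components are fused through a single scalar gate, the mean of the two
## modalities' mean feature activations, applied to the PET detail map
## (the MRI contributes its activation statistics, not its spatial detail).
## The fused luminance Y_f = L_f + H_f is recombined with the PET's
## untouched chrominance planes and converted back to RGB.

#' Energy-adaptive low-frequency fusion
#'
#' `alpha = E_MRI / (E_MRI + E_PET)` with `E = sum(L^2)`;
#' `L_f = alpha L_MRI + (1 - alpha) L_PET`. When both energies are zero
#' the weights degenerate to 0.5/0.5 (with a warning).
#'
#' @param l_mri,l_pet low-frequency Image2D components, same shape.
#' @return list with `fused` (Image2D) and `weights` (list `e_mri`,
#'   `e_pet`, `alpha`, `beta`; `alpha + beta == 1` exactly).
#' @export
fuse_lf <- function(l_mri, l_pet) {
  assert_image2d(l_mri); assert_image2d(l_pet)
  if (!all(dim(l_mri) == dim(l_pet))) {
    stop("low-frequency components must have identical shapes", call. = FALSE)
  }
  e_mri <- sum(l_mri^2)
  e_pet <- sum(l_pet^2)
  if (e_mri + e_pet > 0) {
    alpha <- e_mri / (e_mri + e_pet)
  } else {
    warning("both low-frequency energies are zero; using alpha = 0.5")
    alpha <- 0.5
  }
  beta <- 1 - alpha
  list(fused = alpha * l_mri + beta * l_pet,
       weights = list(e_mri = e_mri, e_pet = e_pet, alpha = alpha, beta = beta))
}

#' Compute the high-frequency feature gate
#'
#' Signed high-frequency maps are min-max rescaled to \[0,1\], passed
#' through the feature extractor, and summarized as mean activations
#' mu_MRI and mu_PET; the gate is their average.
#'
#' @param extractor a `feature_extractor`.
#' @param h_mri,h_pet high-frequency Image2D maps.
#' @return list of class `feature_gate`: `mu_mri`, `mu_pet`,
#'   `gate = (mu_mri + mu_pet) / 2`.
#' @export
feature_gate <- function(extractor, h_mri, h_pet) {
  mu_mri <- mean_activation(extractor, rescale01(h_mri))
  mu_pet <- mean_activation(extractor, rescale01(h_pet))
  structure(list(mu_mri = mu_mri, mu_pet = mu_pet,
                 gate = (mu_mri + mu_pet) / 2),
            class = "feature_gate")
}

#' Feature-gated high-frequency fusion
#'
#' `H_f = gate * H_PET`, an elementwise scalar modulation of the PET
#' detail map; the MRI detail map enters only through its mean activation
#' inside the gate.
#'
#' @param h_mri,h_pet high-frequency Image2D maps, same shape.
#' @param gate a `feature_gate` or a bare scalar.
#' @return fused high-frequency Image2D.
#' @export
fuse_hf <- function(h_mri, h_pet, gate) {
  assert_image2d(h_mri); assert_image2d(h_pet)
  if (!all(dim(h_mri) == dim(h_pet))) {
    stop("high-frequency components must have identical shapes", call. = FALSE)
  }
  g <- if (inherits(gate, "feature_gate")) gate$gate else gate
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g)) {
    stop("gate must be a single finite number", call. = FALSE)
  }
  g * h_pet
}

#' Reconstruct a fused RGB image from luminance and chrominance planes
#'
#' `Y_f = L_f + H_f` (no internal clipping, so luminance additivity is
#' exact), reattached to the supplied chrominance planes and converted to
#' RGB; clipping to \[0,1\] happens only at this final conversion.
#'
#' @param l_f,h_f fused low- and high-frequency Image2D components.
#' @param u,v chrominance planes (U/V for `"yuv"`, Cb/Cr for `"ycbcr"`).
#' @param color_space `"yuv"` (default) or `"ycbcr"`.
#' @return H x W x 3 array of class `rgb_image`.
#' @export
reconstruct <- function(l_f, h_f, u, v, color_space = c("yuv", "ycbcr")) {
  color_space <- match.arg(color_space)
  y_f <- l_f + h_f
  stack <- array(c(y_f, u, v), dim = c(dim(y_f), 3L))
  if (color_space == "yuv") yuv_to_rgb(stack) else ycbcr_to_rgb(stack)
}

## Luminance/chrominance split in the configured color space.
split_color <- function(rgb, color_space) {
  enc <- if (color_space == "yuv") rgb_to_yuv(rgb) else rgb_to_ycbcr(rgb)
  list(y = plane(enc, 1), u = plane(enc, 2), v = plane(enc, 3))
}

#' Fuse one MRI/PET pair
#'
#' End-to-end pipeline: optional modality-specific degradation, optional
#' hybrid denoising, luminance/chrominance split of the PET, SVD
#' decomposition of both luminances at the configured rank, energy-adaptive
#' low-frequency fusion, feature-gated high-frequency fusion, luminance
#' reconstruction, chrominance reattachment and inverse color conversion.
#' Deterministic given the configuration (all randomness flows from its
#' seeds).
#'
#' Modes: `"svd_vgg"` (full hybrid, default); `"svd_only"` (the
#' high-frequency components are discarded, output luminance is the fused
#' low-frequency component alone); `"vgg_only"` (no decomposition: the
#' gate, computed from the full rescaled luminances, directly modulates
#' the PET luminance); `"rgb_svd_vgg"` (ablation in RGB space, see
#' [fuse_rgb_mode()]).
#'
#' @param mri Image2D (grayscale) or RGB array (converted via its
#'   luminance).
#' @param pet H x W x 3 RGB array.
#' @param config a [fusion_config()].
#' @return object of class `fused_result`: `fused_rgb`, `y_fused`,
#'   `l_fused`, `h_fused`, `weights`, `gate`, `u`, `v`, `decomposition`
#'   (per-modality `svd_decomposition`s), `inputs` (the preprocessed
#'   working images) and `config`.
#' @export
fuse_pair <- function(mri, pet, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  if (length(dim(mri)) == 3L) mri <- luminance(mri)
  assert_image2d(mri); assert_plane3(pet)
  if (length(mri) == 0 || length(pet) == 0) {
    stop("empty input image", call. = FALSE)
  }
  size <- config$working_size
  mri <- clip01(resize_bilinear(mri, size, size))
  pet <- clip01(resize_bilinear(pet, size, size))
  class(pet) <- c("rgb_image", "array")

  ## degradation (off unless configured)
  mri <- apply_noise(mri, config$noise_mri)
  attr(mri, "noise_field") <- NULL
  pet <- apply_noise(pet, config$noise_pet)

  ## hybrid denoising (off unless configured)
  if (config$denoise) {
    mri <- denoise_mri(mri, config$bilateral)
    pet <- denoise_pet(pet, config$nlm, config$guided)
  }

  if (config$mode == "rgb_svd_vgg") {
    return(fuse_rgb_mode(mri, pet, config))
  }

  pc <- split_color(pet, config$color_space)
  extractor <- if (config$mode == "svd_only") NULL else resolve_backbone(config)

  if (config$mode == "vgg_only") {
    gate <- feature_gate(extractor, rescale01(mri), rescale01(pc$y))
    l_f <- matrix(0, size, size)
    h_f <- gate$gate * pc$y
    weights <- list(e_mri = NA_real_, e_pet = NA_real_,
                    alpha = NA_real_, beta = NA_real_)
    dec <- NULL
  } else {
    dec_mri <- svd_decompose(mri, config$k)
    dec_pet <- svd_decompose(pc$y, config$k)
    lf <- fuse_lf(dec_mri$low, dec_pet$low)
    l_f <- lf$fused
    weights <- lf$weights
    if (config$mode == "svd_only") {
      gate <- NULL
      h_f <- matrix(0, size, size)
    } else {
      gate <- feature_gate(extractor, dec_mri$high, dec_pet$high)
      h_f <- fuse_hf(dec_mri$high, dec_pet$high, gate)
    }
    dec <- list(mri = dec_mri, pet = dec_pet)
  }

  y_f <- l_f + h_f
  fused_rgb <- reconstruct(l_f, h_f, pc$u, pc$v, config$color_space)
  structure(list(fused_rgb = fused_rgb, y_fused = y_f, l_fused = l_f,
                 h_fused = h_f, weights = weights, gate = gate,
                 u = pc$u, v = pc$v, decomposition = dec,
                 inputs = list(mri = mri, pet = pet), config = config),
            class = "fused_result")
}

#' RGB-space ablation fusion
#'
#' Per-channel SVD + feature-gated fusion carried out directly in RGB: the
#' grayscale MRI is replicated across channels and each of R, G, B is
#' fused with the corresponding PET channel by the same low/high-frequency
#' rules. The chrominance-preservation property is deliberately given up;
#' this mode exists as a baseline for the colorspace design.
#'
#' @param mri Image2D at the working size.
#' @param pet H x W x 3 RGB array at the working size.
#' @param config a [fusion_config()].
#' @return `fused_result`; `weights` and `gate` hold per-channel lists,
#'   chrominance fields are NULL.
#' @export
fuse_rgb_mode <- function(mri, pet, config = fusion_config()) {
  if (length(dim(mri)) == 3L) mri <- luminance(mri)
  assert_image2d(mri); assert_plane3(pet)
  size <- config$working_size
  mri <- clip01(resize_bilinear(mri, size, size))
  pet <- clip01(resize_bilinear(pet, size, size))
  extractor <- resolve_backbone(config)
  fused <- array(0, dim = c(size, size, 3L))
  weights <- list(); gates <- list()
  for (c in 1:3) {
    dec_mri <- svd_decompose(mri, config$k)
    dec_pet <- svd_decompose(pet[, , c], config$k)
    lf <- fuse_lf(dec_mri$low, dec_pet$low)
    gate <- feature_gate(extractor, dec_mri$high, dec_pet$high)
    h_f <- fuse_hf(dec_mri$high, dec_pet$high, gate)
    fused[, , c] <- lf$fused + h_f
    weights[[c]] <- lf$weights
    gates[[c]] <- gate
  }
  fused_rgb <- clip01(fused)
  class(fused_rgb) <- c("rgb_image", "array")
  structure(list(fused_rgb = fused_rgb, y_fused = luminance(fused_rgb),
                 l_fused = NULL, h_fused = NULL,
                 weights = weights, gate = gates, u = NULL, v = NULL,
                 decomposition = NULL,
                 inputs = list(mri = mri, pet = pet), config = config),
            class = "fused_result")
}

#' @export
print.fused_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("fused_result: %dx%d, mode=%s, color_space=%s, k=%s\n",
              dim(x$fused_rgb)[1], dim(x$fused_rgb)[2], cfg$mode,
              cfg$color_space,
              if (is.null(cfg$k)) "full" else cfg$k))
  if (is.list(x$weights) && !is.list(x$weights[[1]])) {
    cat(sprintf("  LF weights: alpha=%.4f beta=%.4f\n",
                x$weights$alpha, x$weights$beta))
  }
  if (inherits(x$gate, "feature_gate")) {
    cat(sprintf("  HF gate: mu_mri=%.4f mu_pet=%.4f gate=%.4f\n",
                x$gate$mu_mri, x$gate$mu_pet, x$gate$gate))
  }
  invisible(x)
}
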