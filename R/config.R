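## Pipeline configuration: every knob of the fusion pipeline in one
## validated object, so CLI runs and API runs share a single source of
## truth and a single seed.

#' Fusion pipeline configuration
#'
#' @param mode fusion mode: `"svd_vgg"` (default), `"svd_only"`,
#'   `"vgg_only"`, `"rgb_svd_vgg"`.
#' @param color_space `"yuv"` (default) or `"ycbcr"`.
#' @param k SVD truncation rank; `NULL` (default) = full decomposition.
#' @param working_size square working resolution (default 256).
#' @param noise_mri,noise_pet [noise_spec()]s applied to the inputs
#'   (default: none).
#' @param denoise logical: run the hybrid denoising chain (bilateral for
#'   MRI, NLM + guided for PET) before fusion. Default FALSE (clean-input
#'   run).
#' @param bilateral,nlm,guided filter parameter objects.
#' @param backbone feature-extractor spec: one of `"vgg19"` (full-width
#'   random-initialized), `"small"` (1/8-width, same depth), `"zero"`,
#'   `"stub_identity"`, `"stub_zero"`, or a ready `feature_extractor`.
#' @param seed integer master seed (drives backbone initialization; noise
#'   specs carry their own seeds, set them from this for a fully seeded
#'   run).
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(mode = c("svd_vgg", "svd_only", "vgg_only", "rgb_svd_vgg"),
                          color_space = c("yuv", "ycbcr"),
                          k = NULL,
                          working_size = 256L,
                          noise_mri = noise_spec("none"),
                          noise_pet = noise_spec("none"),
                          denoise = FALSE,
                          bilateral = bilateral_params(),
                          nlm = nlm_params(),
                          guided = guided_params(),
                          backbone = "small",
                          seed = 1L) {
  if (length(mode) > 1) mode <- mode[1]
  if (!is.character(mode) ||
      !mode %in% c("svd_vgg", "svd_only", "vgg_only", "rgb_svd_vgg")) {
    stop("invalid `mode`: must be one of svd_vgg, svd_only, vgg_only, rgb_svd_vgg",
         call. = FALSE)
  }
  if (length(color_space) > 1) color_space <- color_space[1]
  if (!is.character(color_space) || !color_space %in% c("yuv", "ycbcr")) {
    stop("invalid `color_space`: must be yuv or ycbcr", call. = FALSE)
  }
  if (!is.null(k)) {
    if (!is.numeric(k) || length(k) != 1L || k < 1) {
      stop("k must be a single rank >= 1 or NULL", call. = FALSE)
    }
    k <- as.integer(k)
  }
  if (!is.numeric(working_size) || working_size < 32) {
    stop("working_size must be >= 32", call. = FALSE)
  }
  stopifnot(inherits(noise_mri, "noise_spec"), inherits(noise_pet, "noise_spec"),
            inherits(bilateral, "bilateral_params"), inherits(nlm, "nlm_params"),
            inherits(guided, "guided_params"))
  if (!inherits(backbone, "feature_extractor")) {
    if (!is.character(backbone) ||
        !backbone %in% c("small", "vgg19", "zero", "stub_identity", "stub_zero")) {
      stop(paste("invalid `backbone`: must be a feature_extractor or one of",
                 "small, vgg19, zero, stub_identity, stub_zero"), call. = FALSE)
    }
  }
  structure(list(mode = mode, color_space = color_space, k = k,
                 working_size = as.integer(working_size),
                 noise_mri = noise_mri, noise_pet = noise_pet,
                 denoise = isTRUE(denoise),
                 bilateral = bilateral, nlm = nlm, guided = guided,
                 backbone = backbone, seed = as.integer(seed)),
            class = "fusion_config")
}

## Materialize the configured backbone (a spec string or a ready
## feature_extractor).
resolve_backbone <- function(config) {
  b <- config$backbone
  if (inherits(b, "feature_extractor")) return(b)
  switch(b,
    vgg19 = vgg_backbone("random", seed = config$seed),
    small = vgg_backbone("random", seed = config$seed, width_scale = 1 / 8),
    zero = vgg_backbone("zero", seed = config$seed),
    stub_identity = stub_backbone("identity"),
    stub_zero = stub_backbone("zero"),
    stop(sprintf("unknown backbone spec '%s'", b), call. = FALSE)
  )
}

#' @export
print.fusion_config <- function(x, ...) {
  bk <- if (inherits(x$backbone, "feature_extractor")) x$backbone$arch else x$backbone
  cat(sprintf(paste0("fusion_config: mode=%s color_space=%s k=%s size=%d ",
                     "denoise=%s backbone=%s seed=%d\n"),
              x$mode, x$color_space,
              if (is.null(x$k)) "full" else x$k,
              x$working_size, x$denoise, bk, x$seed))
  cat(sprintf("  noise: mri=%s(sigma2=%g) pet=%s(peak=%g)\n",
              x$noise_mri$kind, x$noise_mri$sigma2,
              x$noise_pet$kind, x$noise_pet$peak))
  invisible(x)
}
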