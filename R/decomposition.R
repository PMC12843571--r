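## SVD split of a luminance plane: I = U S V', the rank-k reconstruction
## L = U S_k V' is the low-frequency structural component and H = I - L the
## high-frequency residual. By the Eckart-Young theorem L is the best
## rank-k approximation and ||H||_F^2 equals the discarded singular energy.

#' Decompose an image into low- and high-frequency components via SVD
#'
#' @param img Image2D (any H x W real matrix; the economy SVD handles
#'   non-square inputs).
#' @param k retained rank, `NULL` (default) for the full decomposition.
#'   Full rank leaves the high-frequency residual at round-off level.
#' @return an object of class `svd_decomposition`: list with `u`, `d`
#'   (singular values, non-increasing), `v`, `k`, `low` (L), `high`
#'   (H = img - L).
#' @examples
#' d <- svd_decompose(matrix(runif(64), 8, 8), k = 3)
#' max(abs(d$low + d$high - matrix(runif(64), 8, 8))) # additivity vs input
#' @export
svd_decompose <- function(img, k = NULL) {
  assert_image2d(img)
  r_max <- min(dim(img))
  if (!is.null(k)) {
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k > r_max) {
      stop(sprintf("k must be in [1, %d] or NULL for full rank", r_max),
           call. = FALSE)
    }
    k <- as.integer(k)
  }
  s <- svd(img)
  kk <- if (is.null(k)) r_max else k
  low <- s$u[, seq_len(kk), drop = FALSE] %*%
    (s$d[seq_len(kk)] * t(s$v[, seq_len(kk), drop = FALSE]))
  high <- img - low
  structure(list(u = s$u, d = s$d, v = s$v, k = k, low = low, high = high),
            class = "svd_decomposition")
}

#' @export
print.svd_decomposition <- function(x, ...) {
  cat(sprintf("svd_decomposition: %d x %d, k = %s, ||H||_F = %.3g\n",
              nrow(x$low), ncol(x$low),
              if (is.null(x$k)) "full" else x$k,
              sqrt(sum(x$high^2))))
  invisible(x)
}

#' Fusion quality as a function of SVD truncation rank
#'
#' Runs the full fusion pipeline on one MRI/PET pair at each rank in
#' `k_list` (use `NA` for the full decomposition) and tabulates per-rank
#' low-rank approximation errors and fusion metrics; when `reference` is
#' supplied, reference-based metrics (MSE/PSNR/SSIM/CC) are included.
#'
#' @param mri Image2D.
#' @param pet H x W x 3 RGB array.
#' @param k_list integer vector of ranks; `NA` entries mean full rank.
#' @param config a [fusion_config()]; its `k` field is overridden per row.
#' @param reference optional RGB reference image for fidelity metrics.
#' @return data.frame, one row per rank, columns `k`, `alpha`, `gate`,
#'   `lowrank_err_mri`, `lowrank_err_pet` (Frobenius norms of the
#'   truncation residuals), the no-reference metrics and, if a reference is
#'   given, the reference-based ones.
#' @export
rank_sweep <- function(mri, pet, k_list, config = fusion_config(),
                       reference = NULL) {
  stopifnot(length(k_list) >= 1)
  rows <- lapply(k_list, function(k) {
    cfg <- config
    cfg$k <- if (is.na(k)) NULL else as.integer(k)
    res <- fuse_pair(mri, pet, cfg)
    met <- evaluate(res, reference = reference)
    data.frame(
      k = if (is.na(k)) Inf else k,
      alpha = res$weights$alpha,
      gate = if (is.null(res$gate)) NA_real_ else res$gate$gate,
      lowrank_err_mri = sqrt(sum(res$decomposition$mri$high^2)),
      lowrank_err_pet = sqrt(sum(res$decomposition$pet$high^2)),
      met,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
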