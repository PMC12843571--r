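# Fusion algebra: energy-adaptive LF weights, scalar HF gating, luminance
# additivity, chrominance pass-through, ablation modes and determinism.

test_that("LF fusion weights follow the energy ratio", {
  # constructed constants: E_mri = 3, E_pet = 1 -> alpha = 0.75
  l_mri <- matrix(sqrt(3) / 2, 2, 2)   # sum of squares = 3
  l_pet <- matrix(0.5, 2, 2)           # sum of squares = 1
  lf <- fuse_lf(l_mri, l_pet)
  expect_equal(lf$weights$alpha, 0.75)
  expect_equal(lf$weights$beta, 0.25)
  expect_equal(lf$fused, 0.75 * l_mri + 0.25 * l_pet)
  # identical inputs: alpha = 0.5 and the common input is returned
  same <- seeded_image(6, 6, 1)
  lf2 <- fuse_lf(same, same)
  expect_equal(lf2$weights$alpha, 0.5)
  expect_equal(lf2$fused, same)
  # one-sided energy: alpha = 1
  lf3 <- fuse_lf(same, matrix(0, 6, 6))
  expect_equal(lf3$weights$alpha, 1)
  expect_equal(lf3$fused, same)
  # degenerate zero-energy pair
  expect_warning(lf4 <- fuse_lf(matrix(0, 3, 3), matrix(0, 3, 3)), "alpha = 0.5")
  expect_equal(lf4$weights$alpha, 0.5)
})

test_that("alpha + beta = 1 exactly for random LF pairs", {
  for (seed in 1:10) {
    lf <- fuse_lf(seeded_image(8, 8, seed), seeded_image(8, 8, seed + 100))
    expect_identical(lf$weights$alpha + lf$weights$beta, 1)
    expect_gte(lf$weights$alpha, 0)
    expect_lte(lf$weights$alpha, 1)
  }
})

test_that("HF fusion is a scalar modulation of the PET detail map", {
  h_mri <- seeded_image(8, 8, 2) - 0.5
  h_pet <- seeded_image(8, 8, 3) - 0.5
  expect_identical(fuse_hf(h_mri, h_pet, 1), h_pet)         # unit gate
  expect_equal(fuse_hf(h_mri, h_pet, 0), matrix(0, 8, 8))   # zero gate
  # mu_mri = 0.4, mu_pet = 0.6 -> gate 0.5
  gate <- structure(list(mu_mri = 0.4, mu_pet = 0.6, gate = 0.5),
                    class = "feature_gate")
  expect_equal(fuse_hf(h_mri, h_pet, gate), 0.5 * h_pet)
  expect_error(fuse_hf(h_mri, h_pet, NaN), "finite")
})

test_that("reconstruction adds luminance components and carries chrominance", {
  l_f <- seeded_image(8, 8, 4) * 0.6
  z <- matrix(0, 8, 8)
  # zero HF and zero chrominance: grayscale output equal to clip(l_f)
  out <- reconstruct(l_f, z, z, z)
  for (c in 1:3) expect_equal(out[, , c], clip01(l_f), tolerance = 1e-12)
  # chrominance round-trips through the colorspace pair
  pair <- make_phantom_pair(7, 32)
  yuv <- rgb_to_yuv(pair$pet)
  rec <- reconstruct(yuv[, , 1], matrix(0, 32, 32), yuv[, , 2], yuv[, , 3])
  back <- rgb_to_yuv(rec)
  expect_lt(max(abs(back[, , 2] - yuv[, , 2])), 1e-3)
})

test_that("full pipeline: additivity, chrominance pass-through, determinism", {
  pair <- make_phantom_pair(11, 64)
  cfg <- fusion_config(working_size = 64, backbone = "stub_identity")
  res <- fuse_pair(pair$mri, pair$pet, cfg)
  # Y_f = L_f + H_f exactly (pre-clip)
  expect_identical(res$y_fused, res$l_fused + res$h_fused)
  # chrominance planes bit-identical to the (preprocessed) PET's
  pet_yuv <- rgb_to_yuv(res$inputs$pet)
  expect_identical(res$u, pet_yuv[, , 2, drop = TRUE])
  expect_identical(res$v, pet_yuv[, , 3, drop = TRUE])
  # determinism: same config twice is bit-identical
  res2 <- fuse_pair(pair$mri, pair$pet, cfg)
  expect_identical(res$fused_rgb, res2$fused_rgb)
  expect_identical(res$weights, res2$weights)
})

test_that("svd_only mode discards the high-frequency component", {
  pair <- make_phantom_pair(12, 48)
  cfg <- fusion_config(mode = "svd_only", working_size = 48)
  res <- fuse_pair(pair$mri, pair$pet, cfg)
  expect_true(all(res$h_fused == 0))
  expect_identical(res$y_fused, res$l_fused)
  expect_null(res$gate)
})

test_that("self-fusion fixed point: shared luminance with unit gate returns PET", {
  pair <- make_phantom_pair(13, 48)
  pet_yuv <- rgb_to_yuv(pair$pet)
  y_pet <- pet_yuv[, , 1, drop = TRUE]
  # PET whose luminance equals the MRI: use y_pet as the MRI input
  cfg <- fusion_config(working_size = 48, backbone = "stub_identity")
  res <- fuse_pair(y_pet, pair$pet, cfg)
  expect_equal(res$weights$alpha, 0.5, tolerance = 1e-12)
  # fused luminance = L + gate * H of the shared luminance
  dec <- svd_decompose(y_pet)
  expect_equal(res$y_fused, dec$low + res$gate$gate * dec$high, tolerance = 1e-9)
  # with a forced unit gate at full rank the result is PET itself up to
  # colorspace round-trip error
  rec <- reconstruct(dec$low, dec$high, pet_yuv[, , 2], pet_yuv[, , 3])
  expect_lt(max(abs(unclass(rec) - unclass(pair$pet))), 5e-3)
})

test_that("vgg_only mode gates the full PET luminance", {
  pair <- make_phantom_pair(14, 48)
  cfg <- fusion_config(mode = "vgg_only", working_size = 48,
                       backbone = "stub_identity")
  res <- fuse_pair(pair$mri, pair$pet, cfg)
  y_pet <- rgb_to_yuv(res$inputs$pet)[, , 1, drop = TRUE]
  expect_equal(res$y_fused, res$gate$gate * y_pet, tolerance = 1e-12)
  expect_true(all(res$l_fused == 0))
})

test_that("rgb ablation mode fuses channels symmetrically", {
  pair <- make_phantom_pair(15, 48)
  gray_pet <- rgb_image(luminance(pair$pet), luminance(pair$pet),
                        luminance(pair$pet))
  cfg <- fusion_config(mode = "rgb_svd_vgg", working_size = 48,
                       backbone = "stub_identity")
  res <- fuse_rgb_mode(pair$mri, gray_pet, cfg)
  expect_equal(res$fused_rgb[, , 1], res$fused_rgb[, , 2], tolerance = 1e-12)
  expect_equal(res$fused_rgb[, , 2], res$fused_rgb[, , 3], tolerance = 1e-12)
  # per-channel weights obey the LF postcondition
  for (c in 1:3) {
    expect_equal(res$weights[[c]]$alpha + res$weights[[c]]$beta, 1)
  }
  # on a colored phantom the RGB-space result differs from the YUV one
  res_rgb <- fuse_pair(pair$mri, pair$pet,
                       fusion_config(mode = "rgb_svd_vgg", working_size = 48,
                                     backbone = "stub_identity"))
  res_yuv <- fuse_pair(pair$mri, pair$pet,
                       fusion_config(working_size = 48,
                                     backbone = "stub_identity"))
  expect_gt(max(abs(unclass(res_rgb$fused_rgb) - unclass(res_yuv$fused_rgb))),
            1e-3)
})

test_that("ycbcr color space preserves its chrominance planes too", {
  pair <- make_phantom_pair(16, 48)
  cfg <- fusion_config(color_space = "ycbcr", working_size = 48,
                       backbone = "stub_identity")
  res <- fuse_pair(pair$mri, pair$pet, cfg)
  ycc <- rgb_to_ycbcr(res$inputs$pet)
  expect_identical(res$u, ycc[, , 2, drop = TRUE])
  expect_identical(res$v, ycc[, , 3, drop = TRUE])
})

test_that("noisy + denoised pipeline runs end to end and stays deterministic", {
  pair <- make_phantom_pair(17, 48)
  cfg <- fusion_config(
    working_size = 48, backbone = "stub_identity", denoise = TRUE,
    noise_mri = noise_spec("gaussian", sigma2 = 0.25, seed = 41),
    noise_pet = noise_spec("poisson", peak = 255, seed = 42),
    nlm = nlm_params(h = 0.2, patch_radius = 1, search_radius = 3),
    bilateral = bilateral_params(sigma_s = 2, sigma_r = 0.15, radius = 3))
  res <- fuse_pair(pair$mri, pair$pet, cfg)
  res2 <- fuse_pair(pair$mri, pair$pet, cfg)
  expect_identical(res$fused_rgb, res2$fused_rgb)
  expect_true(all(res$fused_rgb >= 0 & res$fused_rgb <= 1))
})
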