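# Metric suite against brute-force evaluations and closed forms.

test_that("entropy: constant, two-level, full ramp and brute force", {
  expect_equal(entropy(matrix(0.5, 8, 8)), 0)
  two <- matrix(c(0.1, 0.9), 8, 8)
  expect_equal(entropy(two), 1.0)
  # 256 levels exactly once per bin
  ramp <- matrix(seq(0, 255) / 255, 16, 16)
  expect_equal(entropy(ramp), 8.0)
  img <- seeded_image(12, 12, 1)
  expect_equal(entropy(img), brute_entropy(img), tolerance = 1e-12)
})

test_that("standard deviation: closed forms and brute force", {
  expect_equal(std_dev(matrix(0.7, 5, 5)), 0)
  half <- matrix(c(0, 1), 8, 8)
  expect_equal(std_dev(half), 0.5)
  img <- seeded_image(13, 11, 2)
  expect_lt(abs(std_dev(img) - brute_std_dev(img)), 1e-12)
})

test_that("average gradient: constant, ramp closed form, brute force", {
  expect_equal(avg_gradient(matrix(0.3, 6, 6)), 0)
  s <- 0.02
  ramp <- ramp_image(8, 10, step = s)
  expect_equal(avg_gradient(ramp), s / sqrt(2), tolerance = 1e-12)
  img <- seeded_image(9, 14, 3)
  expect_lt(abs(avg_gradient(img) - brute_avg_gradient(img)), 1e-12)
  expect_error(avg_gradient(matrix(1, 1, 5)), "2 x 2")
})

test_that("mse: identity, constant offset, brute force", {
  img <- seeded_image(10, 10, 4)
  expect_equal(mse(img, img), 0)
  ref <- matrix(0.2, 6, 6)
  expect_equal(mse(ref, ref + 0.1), 0.01, tolerance = 1e-12)
  other <- seeded_image(10, 10, 5)
  expect_lt(abs(mse(img, other) - brute_mse(img, other)), 1e-12)
  expect_error(mse(img, matrix(0, 3, 3)), "shape")
})

test_that("psnr follows the closed form with MAX = 1", {
  ref <- matrix(0.5, 8, 8)
  img <- ref + 0.1            # mse = 0.01
  expect_equal(psnr(ref, img), 20.0, tolerance = 1e-9)
  # MSE 0.00063 corresponds to ~32.007 dB on the [0,1] convention
  img2 <- ref + sqrt(0.00063)
  expect_equal(psnr(ref, img2), 10 * log10(1 / 0.00063), tolerance = 1e-9)
  expect_equal(psnr(ref, img2), 32.0066, tolerance = 1e-4)
  expect_warning(p <- psnr(ref, ref), "infinite")
  expect_identical(p, Inf)
})

test_that("ssim: identity, bounds, brute-force cross-check", {
  img <- seeded_image(12, 12, 6)
  expect_equal(ssim(img, img), 1)
  other <- seeded_image(12, 12, 7)
  v <- ssim(img, other)
  expect_lte(abs(v), 1)
  # independent double-loop evaluation
  expect_lt(abs(v - brute_ssim(img, other)), 1e-6)
  smooth <- make_phantom_pair(3, 32)
  expect_lt(abs(ssim(smooth$mri, luminance(smooth$pet)) -
                  brute_ssim(smooth$mri, luminance(smooth$pet))), 1e-6)
})

test_that("correlation coefficient: identity, reflection, brute force", {
  img <- seeded_image(10, 10, 8)
  expect_equal(cc(img, img), 1, tolerance = 1e-12)
  expect_equal(cc(img, 2 * mean(img) - img), -1, tolerance = 1e-12)
  other <- seeded_image(10, 10, 9)
  expect_lt(abs(cc(img, other) - brute_cc(img, other)), 1e-12)
  expect_error(cc(img, matrix(0.5, 10, 10)), "constant")
})

test_that("perceptual distance is a bounded semimetric with all references", {
  net <- vgg_backbone("random", seed = 3, width_scale = 1 / 16, input_size = 32L)
  a <- seeded_rgb(16, 16, 10)
  b <- seeded_rgb(16, 16, 11)
  expect_equal(perceptual_distance(a, a, net), 0, tolerance = 1e-12)
  d_ab <- perceptual_distance(a, b, net)
  expect_equal(d_ab, perceptual_distance(b, a, net))
  expect_gte(d_ab, 0)
  expect_lte(d_ab, 1)
  expect_error(perceptual_distance(a, b, "nope"), "feature_extractor")
})

test_that("evaluate composes the individual metrics bit-exactly", {
  pair <- make_phantom_pair(18, 48)
  cfg <- fusion_config(working_size = 48, backbone = "stub_identity")
  res <- fuse_pair(pair$mri, pair$pet, cfg)
  net <- vgg_backbone("random", seed = 3, width_scale = 1 / 16, input_size = 32L)
  rep_row <- evaluate(res, reference = pair$gt_proxy, pet = pair$pet,
                      mri = pair$mri, perceptual_backend = net)
  lum <- luminance(res$fused_rgb)
  ref_lum <- luminance(pair$gt_proxy)
  expect_identical(rep_row$en, entropy(lum))
  expect_identical(rep_row$sd, std_dev(lum))
  expect_identical(rep_row$ag, avg_gradient(lum))
  expect_identical(rep_row$mse, mse(ref_lum, lum))
  expect_identical(rep_row$ssim, ssim(ref_lum, lum))
  expect_identical(rep_row$cc, cc(ref_lum, lum))
  # PSNR/MSE functional relation on the report row
  expect_equal(rep_row$psnr, 10 * log10(1 / rep_row$mse), tolerance = 1e-12)
  # all three perceptual references present
  expect_true(all(c("lpips_ref", "lpips_pet", "lpips_mri") %in% names(rep_row)))
  # self-evaluation degenerates correctly
  self_rep <- evaluate(res, reference = res$fused_rgb)
  expect_equal(self_rep$mse, 0)
  expect_equal(self_rep$ssim, 1)
  expect_equal(self_rep$cc, 1, tolerance = 1e-12)
})

test_that("metric reports serialize to CSV one row per pair", {
  pair <- make_phantom_pair(19, 32)
  rows <- do.call(rbind, lapply(1:3, function(i) {
    evaluate(pair$gt_proxy, reference = pair$gt_proxy)
  }))
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(rows, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 3)
})
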