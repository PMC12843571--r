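# Bilateral, non-local means and guided filters against brute-force
# evaluations of their defining formulas, limit behaviors, and the
# noise-reduction property of the PET chain.

test_that("bilateral filter matches the brute-force double loop", {
  img <- seeded_image(8, 8, 101)
  for (prm in list(c(1.5, 0.1, 2), c(3, 0.25, 3))) {
    p <- bilateral_params(sigma_s = prm[1], sigma_r = prm[2], radius = prm[3])
    expect_lt(max(abs(bilateral(img, p) -
                        brute_bilateral(img, prm[1], prm[2], prm[3]))), 1e-10)
  }
})

test_that("bilateral filter leaves constant images unchanged", {
  img <- matrix(0.42, 10, 10)
  expect_equal(bilateral(img), img, tolerance = 1e-12)
})

test_that("bilateral with huge range scale reduces to spatial Gaussian blur", {
  img <- seeded_image(12, 12, 7)
  p <- bilateral_params(sigma_s = 2, sigma_r = 1e6, radius = 3)
  expect_lt(max(abs(bilateral(img, p) -
                      brute_gaussian_window_blur(img, 2, 3))), 1e-6)
})

test_that("non-local means matches the brute-force patch loop", {
  set.seed(55)
  step <- matrix(0, 12, 12); step[, 7:12] <- 0.8
  img <- clip01(step + matrix(rnorm(144, 0, 0.05), 12, 12))
  p <- nlm_params(h = 0.3, patch_radius = 1, search_radius = 3)
  expect_lt(max(abs(nlm(img, p) - brute_nlm(img, 0.3, 1, 3))), 1e-10)
  # second parameterization
  p2 <- nlm_params(h = 0.15, patch_radius = 2, search_radius = 4)
  expect_lt(max(abs(nlm(img, p2) - brute_nlm(img, 0.15, 2, 4))), 1e-10)
})

test_that("non-local means limits: constant image and huge h", {
  img <- matrix(0.6, 10, 10)
  expect_equal(nlm(img), img, tolerance = 1e-12)
  noisy <- seeded_image(9, 9, 3)
  p <- nlm_params(h = 1e6, patch_radius = 1, search_radius = 2)
  # all weights equal -> uniform mean over the (reflected) search window
  unif <- brute_nlm(noisy, 1e6, 1, 2)
  expect_lt(max(abs(nlm(noisy, p) - unif)), 1e-10)
  got <- nlm(noisy, p)
  # interior pixel: plain 5x5 box mean
  expect_equal(got[5, 5], mean(noisy[3:7, 3:7]), tolerance = 1e-6)
})

test_that("guided filter matches the brute-force window loops", {
  img <- seeded_image(10, 10, 77)
  guide <- seeded_image(10, 10, 78)
  for (prm in list(c(2, 1e-4), c(3, 1e-2))) {
    p <- guided_params(radius = prm[1], eps = prm[2])
    expect_lt(max(abs(guided_filter(img, guide, p) -
                        brute_guided(img, guide, prm[1], prm[2]))), 1e-10)
  }
})

test_that("guided filter identities: self-guidance, constant guide, big eps", {
  set.seed(12)
  img <- matrix(runif(100, 0, 1), 10, 10)  # non-constant windows
  # self-guidance with eps = 0: a = 1, b = 0 -> identity
  p0 <- guided_params(radius = 2, eps = 0)
  expect_lt(max(abs(guided_filter(img, img, p0) - img)), 1e-8)
  # constant guide: a = 0, output = double box mean of the input
  const_g <- matrix(0.5, 10, 10)
  got <- guided_filter(img, const_g, guided_params(radius = 2, eps = 1e-4))
  oracle <- brute_guided(img, const_g, 2, 1e-4)
  expect_lt(max(abs(got - oracle)), 1e-10)
  expect_lt(max(abs(got - svdfusion:::win_mean(svdfusion:::win_mean(img, 2), 2))), 1e-8)
  # eps -> infinity approaches the same box-mean limit
  big <- guided_filter(img, seeded_image(10, 10, 5), guided_params(radius = 2, eps = 1e8))
  expect_lt(max(abs(big - svdfusion:::win_mean(svdfusion:::win_mean(img, 2), 2))), 1e-6)
})

test_that("PET chain preserves shape, constants, and reduces Poisson noise", {
  # constant color image passes through (weights normalize, a ~ 0 with
  # b = window mean = the constant)
  const <- array(rep(c(0.8, 0.4, 0.1), each = 64), dim = c(8, 8, 3))
  out <- denoise_pet(const, nlm_params(h = 0.1, patch_radius = 1, search_radius = 2),
                     guided_params(radius = 2, eps = 1e-4))
  expect_lt(max(abs(unclass(out) - const)), 1e-6)
  expect_equal(dim(out), dim(const))

  # Monte-Carlo improvement on a phantom with strong photon noise
  pair <- make_phantom_pair(5, 48)
  noisy <- add_poisson(pair$pet, peak = 50, seed = 31)
  den <- denoise_pet(noisy, nlm_params(h = 0.2, patch_radius = 1, search_radius = 3),
                     guided_params(radius = 2, eps = 1e-3))
  mse_noisy <- mean((unclass(noisy) - unclass(pair$pet))^2)
  mse_den <- mean((unclass(den) - unclass(pair$pet))^2)
  expect_lt(mse_den, mse_noisy)
})

test_that("MRI bilateral denoising reduces Gaussian noise energy", {
  pair <- make_phantom_pair(6, 48)
  noisy <- add_gaussian(pair$mri, 0.01, seed = 4)
  den <- denoise_mri(noisy, bilateral_params(sigma_s = 2, sigma_r = 0.15, radius = 3))
  expect_lt(mean((den - pair$mri)^2), mean((noisy - pair$mri)^2))
})

test_that("filter parameter validation", {
  expect_error(bilateral_params(sigma_s = 0), "sigma_s")
  expect_error(nlm_params(patch_radius = 5, search_radius = 3))
  expect_error(guided_filter(matrix(0, 3, 3), matrix(0, 4, 4)), "identical")
})
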