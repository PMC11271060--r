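# Filter bank: LoG, pointwise transforms, gradient, stationary Haar
# wavelet, LBP-3D, and the 20-image enumeration contract.

interior <- function(a, b = 3) {
  d <- dim(a)
  a[(b + 1):(d[1] - b), (b + 1):(d[2] - b), (b + 1):(d[3] - b)]
}

test_that("LoG: constants vanish, quadratic ramps give constant response", {
  cst <- image_volume(array(5, c(12, 12, 12)))
  expect_lt(max(abs(interior(apply_log_of_gaussian(cst, 1)$values))), 1e-9)
  # x^2 along the first axis: smoothed Laplacian is 2, response 2*sigma^2
  x <- (seq_len(20) - 10)^2
  quad <- image_volume(array(rep(x, 20 * 20), c(20, 20, 20)))
  resp <- interior(apply_log_of_gaussian(quad, 1.5)$values, 7)
  expect_equal(as.vector(resp), rep(2 * 1.5^2, length(resp)),
               tolerance = 1e-6)
  expect_error(apply_log_of_gaussian(cst, -1), "sigma")
})

test_that("LoG impulse response equals the dense convolution oracle", {
  d <- c(9, 9, 9)
  imp <- array(0, d); imp[5, 5, 5] <- 1
  v <- image_volume(imp, spacing = c(1, 2, 1))
  got <- apply_log_of_gaussian(v, 1)$values
  # oracle: separable Gaussian smoothing then discrete Laplacian, dense
  kx <- plnmrad:::gaussian_kernel(1 / 1)
  ky <- plnmrad:::gaussian_kernel(1 / 2)
  sm <- oracle_convolve3d(imp, kx, ky, kx)
  lap <- oracle_convolve3d(sm, c(1, -2, 1), 1, 1) +
    oracle_convolve3d(sm, 1, c(1, -2, 1) / 4, 1) +
    oracle_convolve3d(sm, 1, 1, c(1, -2, 1))
  expect_equal(got, 1^2 * lap, tolerance = 1e-10)
})

test_that("pointwise transforms: range conventions and round trips", {
  v <- image_volume(array(c(-2, 3, 0, 1, -1, 2, 0.5, -0.5), c(2, 2, 2)))
  sq <- apply_pointwise(v, "square")$values
  expect_equal(sq[1:2], c(4, 9) / 3)  # x^2 / max|x|
  # squareroot then square recovers non-negative input exactly
  vp <- image_volume(array(abs(rnorm(27)) + 0.1, c(3, 3, 3)))
  rt <- apply_pointwise(vp, "squareroot")
  expect_equal(apply_pointwise(rt, "square")$values, vp$values,
               tolerance = 1e-10)
  # constants map to constants for all kinds
  cst <- image_volume(array(4, c(3, 3, 3)))
  for (k in c("logarithm", "square", "squareroot", "exponential"))
    expect_length(unique(as.vector(apply_pointwise(cst, k)$values)), 1)
  # monotone: ordering preserved
  set.seed(9)
  w <- image_volume(array(rnorm(64), c(4, 4, 4)))
  for (k in c("logarithm", "squareroot", "exponential"))
    expect_equal(order(apply_pointwise(w, k)$values), order(w$values))
})

test_that("gradient magnitude: constants, ramps, planes", {
  cst <- image_volume(array(2, c(8, 8, 8)))
  expect_equal(max(abs(apply_gradient(cst)$values)), 0)
  ramp <- image_volume(array(rep(2 * (1:10), 100), c(10, 10, 10)))
  expect_equal(as.vector(interior(apply_gradient(ramp)$values, 1)),
               rep(2, 8^3), tolerance = 1e-12)
  # plane a*x + b*y with anisotropic spacing
  a <- 3; b <- -2
  plane <- outer(outer(a * (1:10), b * (1:10), `+`), rep(0, 10), `+`)
  v <- image_volume(plane, spacing = c(1, 2, 1))
  g <- interior(apply_gradient(v)$values, 1)
  expect_equal(as.vector(g), rep(sqrt(a^2 + (b / 2)^2), 8^3),
               tolerance = 1e-12)
})

test_that("stationary Haar wavelet: constants, axis attribution, energy", {
  cst <- image_volume(array(3, c(6, 6, 6)))
  wb <- apply_wavelet_haar(cst)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_equal(unique(as.vector(wb$LLL$values)), 3 * 2^(3 / 2))
  for (b in names(wb)[-1]) expect_equal(max(abs(wb[[b]]$values)), 0)
  # a step along the first axis excites only x-highpass bands
  stepv <- image_volume(array(rep(c(0, 0, 0, 1, 1, 1), 36), c(6, 6, 6)))
  wb2 <- apply_wavelet_haar(stepv)
  expect_equal(max(abs(wb2$LLH$values - 0 * wb2$LLH$values)),
               0, tolerance = 1e-12)  # no z-detail
  expect_equal(max(abs(wb2$LHL$values)), 0)  # no y-detail
  expect_gt(max(abs(wb2$HLL$values)), 0.5)   # step concentrates in HLL
  # HLL is nonzero only where the x-step sits (rows 3 and 6 wrap)
  nz <- which(apply(abs(wb2$HLL$values) > 1e-12, 1, any))
  expect_equal(nz, c(3L, 6L))
  # orthonormal periodic pair: sub-band energies sum to 8x input energy
  set.seed(21)
  v <- image_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)))
  wb3 <- apply_wavelet_haar(v)
  e <- sum(vapply(wb3, function(b) sum(b$values^2), 0))
  expect_equal(e, 8 * sum(v$values^2), tolerance = 1e-9)
})

test_that("LBP-3D: three deterministic maps with degenerate sentinels", {
  cst <- image_volume(array(5, c(6, 6, 6)))
  lbp <- apply_lbp3d(cst)
  expect_named(lbp, c("m1", "m2", "k"))
  # constant volume: binary pattern all-ones -> harmonic band energies
  # constant across voxels; kurtosis at its degenerate sentinel 0
  expect_length(unique(round(as.vector(lbp$m1$values), 12)), 1)
  expect_length(unique(round(as.vector(lbp$m2$values), 12)), 1)
  expect_equal(unique(as.vector(lbp$k$values)), 0)
  set.seed(31)
  v <- image_volume(array(rnorm(216), c(6, 6, 6)))
  a <- apply_lbp3d(v)
  b <- apply_lbp3d(v)
  for (nm in names(a)) expect_identical(a[[nm]]$values, b[[nm]]$values)
})

test_that("filters are translation-equivariant on interiors", {
  set.seed(41)
  big <- array(rnorm(16^3), c(16, 16, 16))
  shifted <- plnmrad:::shift3d(big, c(1, 0, 0), fill = 0)
  ops <- list(function(v) apply_log_of_gaussian(v, 1),
              apply_gradient,
              function(v) apply_wavelet_haar(v)$HLH,
              function(v) apply_lbp3d(v)$m1)
  for (op in ops) {
    f1 <- op(image_volume(big))$values
    f2 <- op(image_volume(shifted))$values
    expect_equal(interior(f2, 6)[, , ],
                 interior(plnmrad:::shift3d(f1, c(1, 0, 0)), 6)[, , ],
                 tolerance = 1e-9)
  }
})

test_that("feature-image enumeration matches the bank arithmetic", {
  expect_length(enumerate_feature_images(bank_config()), 20)
  expect_equal(enumerate_feature_images(bank_config("original")), "original")
  no_wavelet <- bank_config(c("original", "log", "logarithm", "square",
                              "squareroot", "exponential", "gradient",
                              "lbp3d"))
  expect_length(enumerate_feature_images(no_wavelet), 12)
  v <- image_volume(array(rnorm(6^3), c(6, 6, 6)))
  fb <- filter_bank(v)
  expect_identical(names(fb), enumerate_feature_images(bank_config()))
  expect_error(bank_config("gabor"), "unknown")
})
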