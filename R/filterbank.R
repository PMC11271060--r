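# Filter bank: the original image plus 19 derived images from which radiomic
# features are extracted (3 Laplacian-of-Gaussian scales, 4 pointwise
# intensity transforms, gradient magnitude, 3 LBP-3D maps, 8 stationary Haar
# wavelet sub-bands).

# -- separable convolution with mirror (whole-sample reflective) boundary ----

convolve_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  c0 <- (length(kernel) + 1L) %/% 2L  # centre tap (kernel length is odd)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  idx <- seq_len(n)
  for (j in seq_along(kernel)) {
    if (kernel[j] == 0) next
    out <- out + kernel[j] * m[mirror_index(idx + (j - c0), n), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

smooth_gaussian <- function(values, sigma_mm, spacing) {
  for (axis in 1:3) {
    values <- convolve_axis(values, gaussian_kernel(sigma_mm / spacing[axis]), axis)
  }
  values
}

laplacian3d <- function(values, spacing) {
  out <- array(0, dim = dim(values))
  for (axis in 1:3) {
    k <- c(1, -2, 1) / spacing[axis]^2
    out <- out + convolve_axis(values, k, axis)
  }
  out
}

#' Laplacian-of-Gaussian filtered image
#'
#' Smooths with a spacing-aware sampled Gaussian of standard deviation
#' `sigma_mm` (separably, mirror boundary) and applies the discrete
#' 3D Laplacian, scale-normalized by `sigma^2` so responses are comparable
#' across scales.
#'
#' @param volume an [image_volume()].
#' @param sigma_mm Gaussian scale in millimetres (> 0).
#' @return A filtered [image_volume()].
#' @export
apply_log_of_gaussian <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "image_volume"))
  assert_scalar_number(sigma_mm, "sigma_mm", lower = .Machine$double.eps)
  sm <- smooth_gaussian(volume$values, sigma_mm, volume$spacing)
  as_volume_like(sigma_mm^2 * laplacian3d(sm, volume$spacing), volume)
}

#' Pointwise intensity transforms
#'
#' Monotone voxelwise transforms with the range-handling conventions of the
#' common radiomics extraction software: each output is rescaled by a
#' constant derived from the input's maximum absolute value so that the
#' output range is comparable to the input range. With `M = max(|x|)`
#' (`M = 1` when the input is identically zero):
#' \itemize{
#'   \item `square`: `x^2 / M`
#'   \item `squareroot`: `sign(x) * sqrt(|x| * M)`
#'   \item `logarithm`: `sign(x) * log(|x| + 1) * M / log(M + 1)`
#'   \item `exponential`: `exp(x * log(M) / M)` (identity scaling when `M <= 1`)
#' }
#'
#' @param volume an [image_volume()].
#' @param kind one of `"logarithm"`, `"square"`, `"squareroot"`, `"exponential"`.
#' @return A transformed [image_volume()].
#' @export
apply_pointwise <- function(volume,
                            kind = c("logarithm", "square", "squareroot",
                                     "exponential")) {
  stopifnot(inherits(volume, "image_volume"))
  kind <- match.arg(kind)
  x <- volume$values
  M <- max(abs(x))
  if (M == 0) M <- 1
  out <- switch(kind,
    square = x^2 / M,
    squareroot = sign(x) * sqrt(abs(x) * M),
    logarithm = sign(x) * log(abs(x) + 1) * (M / log(M + 1)),
    exponential = {
      c0 <- if (M > 1) log(M) / M else 1
      exp(x * c0)
    })
  as_volume_like(out, volume)
}

#' Gradient-magnitude image
#'
#' Spacing-aware central differences (mirror boundary) along each axis,
#' combined as the Euclidean gradient magnitude.
#'
#' @param volume an [image_volume()].
#' @return A filtered [image_volume()].
#' @export
apply_gradient <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  g2 <- array(0, dim = dim(volume$values))
  for (axis in 1:3) {
    k <- c(-1, 0, 1) / (2 * volume$spacing[axis])
    d <- convolve_axis(volume$values, rev(k), axis)
    g2 <- g2 + d^2
  }
  as_volume_like(sqrt(g2), volume)
}

# -- stationary Haar wavelet --------------------------------------------------

haar_axis <- function(a, axis, highpass) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = n)
  nxt <- c(seq_len(n)[-1], 1L)  # periodic neighbour
  out <- if (highpass) (m - m[nxt, , drop = FALSE]) / sqrt(2)
         else (m + m[nxt, , drop = FALSE]) / sqrt(2)
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Single-level stationary 3D Haar wavelet decomposition
#'
#' Undecimated (stationary) orthonormal Haar analysis along each axis with
#' periodic boundary, yielding the eight sub-bands `LLL` ... `HHH`, each on
#' the original grid. Letter k of a sub-band name gives the filter (L =
#' low-pass, H = high-pass) applied along array dimension k. With the
#' periodic orthonormal pair the energies satisfy
#' `sum of sub-band energies = 8 * input energy` exactly.
#'
#' @param volume an [image_volume()].
#' @return A named list of 8 [image_volume()]s
#'   (`LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`, `HHL`, `HHH`).
#' @export
apply_wavelet_haar <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  bands <- list()
  for (f1 in c("L", "H")) {
    a1 <- haar_axis(volume$values, 1L, f1 == "H")
    for (f2 in c("L", "H")) {
      a2 <- haar_axis(a1, 2L, f2 == "H")
      for (f3 in c("L", "H")) {
        a3 <- haar_axis(a2, 3L, f3 == "H")
        bands[[paste0(f1, f2, f3)]] <- as_volume_like(a3, volume)
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

# -- LBP-3D -------------------------------------------------------------------

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

# Trilinear sample of `a` at a constant fractional offset, mirror boundary.
sample_offset <- function(a, off) {
  d <- dim(a)
  i0 <- floor(off)
  f <- off - i0
  out <- array(0, dim = d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[1] else 1 - f[1]) *
         (if (cy) f[2] else 1 - f[2]) *
         (if (cz) f[3] else 1 - f[3])
    if (w == 0) next
    ix <- mirror_index(seq_len(d[1]) + i0[1] + cx, d[1])
    iy <- mirror_index(seq_len(d[2]) + i0[2] + cy, d[2])
    iz <- mirror_index(seq_len(d[3]) + i0[3] + cz, d[3])
    out <- out + w * a[ix, iy, iz]
  }
  out
}

real_sph_harm <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  l1 <- sqrt(3 / (4 * pi)) * cbind(x, y, z)
  l2 <- cbind(0.5 * sqrt(15 / pi) * x * y,
              0.5 * sqrt(15 / pi) * y * z,
              0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
              0.5 * sqrt(15 / pi) * x * z,
              0.25 * sqrt(15 / pi) * (x^2 - y^2))
  list(l1 = l1, l2 = l2)
}

#' Spherical local-binary-pattern maps (LBP-3D)
#'
#' For each voxel, intensities are sampled (trilinear, mirror boundary) at 12
#' icosahedron vertices on a sphere of `radius` voxels and binarized against
#' the centre value. The binary pattern, viewed as a function on the sphere,
#' is projected onto real spherical harmonics; the `m1` and `m2` maps are the
#' energies of harmonic levels 1 and 2, and `k` is the plain (non-excess)
#' kurtosis of the 12 raw sampled intensities (0 where the neighbourhood is
#' constant). Fully deterministic.
#'
#' @param volume an [image_volume()].
#' @param radius sampling radius in voxels (default 1).
#' @return Named list of 3 [image_volume()]s: `m1`, `m2`, `k`.
#' @export
apply_lbp3d <- function(volume, radius = 1) {
  stopifnot(inherits(volume, "image_volume"))
  a <- volume$values
  dirs <- icosahedron_vertices()
  np <- nrow(dirs)
  sph <- real_sph_harm(dirs)
  samples <- vector("list", np)
  for (p in seq_len(np)) samples[[p]] <- sample_offset(a, radius * dirs[p, ])
  # binary patterns and raw-sample moments
  c1 <- array(0, dim = dim(a)); c1y <- c1; c1z <- c1
  coef1 <- matrix(0, length(a), 3)
  coef2 <- matrix(0, length(a), 5)
  s_sum <- array(0, dim = dim(a)); s_sum2 <- s_sum; s_sum3 <- s_sum; s_sum4 <- s_sum
  for (p in seq_len(np)) {
    sp <- samples[[p]]
    b <- as.numeric(sp >= a)
    coef1 <- coef1 + outer(as.vector(b), sph$l1[p, ])
    coef2 <- coef2 + outer(as.vector(b), sph$l2[p, ])
    s_sum <- s_sum + sp
    s_sum2 <- s_sum2 + sp^2
    s_sum3 <- s_sum3 + sp^3
    s_sum4 <- s_sum4 + sp^4
  }
  w <- 4 * pi / np
  m1 <- sqrt(rowSums((w * coef1)^2))
  m2 <- sqrt(rowSums((w * coef2)^2))
  mu <- s_sum / np
  v <- s_sum2 / np - mu^2
  m4 <- (s_sum4 - 4 * mu * s_sum3 + 6 * mu^2 * s_sum2) / np - 3 * mu^4
  eps <- 1e-12 * max(1, max(abs(a))^2)
  k <- ifelse(v > eps, m4 / pmax(v, eps)^2, 0)
  list(m1 = as_volume_like(array(m1, dim(a)), volume),
       m2 = as_volume_like(array(m2, dim(a)), volume),
       k = as_volume_like(array(k, dim(a)), volume))
}

# -- bank configuration and application --------------------------------------

#' Filter-bank configuration
#'
#' @param filters character vector of enabled filters, a subset of
#'   `c("original", "log", "logarithm", "square", "squareroot", "exponential",
#'   "gradient", "lbp3d", "wavelet")`. The default enables the full bank.
#' @param sigmas_mm Laplacian-of-Gaussian scales in mm (default `c(0.5, 1, 1.5)`).
#' @return A `bank_config` list.
#' @export
bank_config <- function(filters = c("original", "log", "logarithm", "square",
                                    "squareroot", "exponential", "gradient",
                                    "lbp3d", "wavelet"),
                        sigmas_mm = c(0.5, 1, 1.5)) {
  allowed <- c("original", "log", "logarithm", "square", "squareroot",
               "exponential", "gradient", "lbp3d", "wavelet")
  bad <- setdiff(filters, allowed)
  if (length(bad)) stop_config("unknown filters: ", paste(bad, collapse = ", "))
  if (any(sigmas_mm <= 0)) stop_config("LoG sigmas must be positive")
  structure(list(filters = unique(filters), sigmas_mm = sigmas_mm),
            class = "bank_config")
}

sigma_label <- function(s) paste0("log_sigma_", gsub("\\.", "_", format(s)), "_mm")

#' Enumerate the derived-image names of a filter bank
#'
#' Canonical ordering of the images produced by [filter_bank()]. With the
#' full default bank there are exactly 20 names
#' (1 original + 3 LoG + 4 pointwise + 1 gradient + 3 LBP-3D + 8 wavelet),
#' which together with the per-image feature counts fixes the 3748-feature
#' space (see [extract_all()]).
#'
#' @param config a [bank_config()].
#' @return Character vector of image names.
#' @examples
#' length(enumerate_feature_images(bank_config()))  # 20
#' @export
enumerate_feature_images <- function(config = bank_config()) {
  stopifnot(inherits(config, "bank_config"))
  nm <- character(0)
  f <- config$filters
  if ("original" %in% f) nm <- c(nm, "original")
  if ("log" %in% f) nm <- c(nm, vapply(config$sigmas_mm, sigma_label, ""))
  for (pw in c("logarithm", "square", "squareroot", "exponential"))
    if (pw %in% f) nm <- c(nm, pw)
  if ("gradient" %in% f) nm <- c(nm, "gradient")
  if ("lbp3d" %in% f) nm <- c(nm, "lbp_3D_m1", "lbp_3D_m2", "lbp_3D_k")
  if ("wavelet" %in% f)
    nm <- c(nm, paste0("wavelet_", c("LLL", "LLH", "LHL", "LHH",
                                     "HLL", "HLH", "HHL", "HHH")))
  nm
}

#' Apply the filter bank to a volume
#'
#' @param volume an [image_volume()].
#' @param config a [bank_config()].
#' @return Named list of [image_volume()]s, one per name in
#'   [enumerate_feature_images()], in canonical order.
#' @export
filter_bank <- function(volume, config = bank_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(config, "bank_config"))
  out <- list()
  f <- config$filters
  if ("original" %in% f) out$original <- volume
  if ("log" %in% f)
    for (s in config$sigmas_mm)
      out[[sigma_label(s)]] <- apply_log_of_gaussian(volume, s)
  for (pw in c("logarithm", "square", "squareroot", "exponential"))
    if (pw %in% f) out[[pw]] <- apply_pointwise(volume, pw)
  if ("gradient" %in% f) out$gradient <- apply_gradient(volume)
  if ("lbp3d" %in% f) {
    lbp <- apply_lbp3d(volume)
    out$lbp_3D_m1 <- lbp$m1; out$lbp_3D_m2 <- lbp$m2; out$lbp_3D_k <- lbp$k
  }
  if ("wavelet" %in% f) {
    wv <- apply_wavelet_haar(volume)
    for (b in names(wv)) out[[paste0("wavelet_", b)]] <- wv[[b]]
  }
  out[enumerate_feature_images(config)]
}
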