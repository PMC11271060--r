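#' Construct a 3D image volume
#'
#' The basic spatial container of the package: a 3D scalar grid with voxel
#' spacing and origin in millimetres and a modality tag. T2-weighted images,
#' ADC maps and raw diffusion-weighted volumes all use this class.
#'
#' @param values numeric 3D array of voxel values.
#' @param spacing numeric length-3 vector of voxel spacing in mm (all > 0).
#' @param origin numeric length-3 vector, physical position (mm) of the first
#'   voxel centre.
#' @param modality one of `"T2"`, `"ADC"`, `"DWI-b100"`, `"DWI-b1000"`,
#'   `"mask"`, or `"derived"`.
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(rnorm(8), c(2, 2, 2)), spacing = c(1, 1, 3))
#' dim(v$values)
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "derived") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_config("'values' must be a 3D array")
  if (length(values) == 0L) stop_config("volume grid must be non-empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_config("'spacing' must be 3 positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_config("'origin' must be 3 finite numbers (mm)")
  modality <- match.arg(modality,
                        c("derived", "T2", "ADC", "DWI-b100", "DWI-b1000", "mask"))
  structure(list(values = values, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %s voxels, spacing %s mm\n", x$modality,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

as_volume_like <- function(values, ref, modality = "derived") {
  image_volume(values, spacing = ref$spacing, origin = ref$origin,
               modality = modality)
}

is_binary_mask <- function(values) all(values %in% c(0, 1))

check_mask <- function(mask, reference = NULL, require_nonempty = TRUE) {
  v <- if (inherits(mask, "image_volume")) mask$values else mask
  if (!is.array(v) || length(dim(v)) != 3L)
    stop_config("mask must be a 3D array or image_volume")
  if (!is_binary_mask(v)) stop_config("mask must be binary (0/1)")
  if (!is.null(reference) && !identical(dim(v), dim(reference$values)))
    stop_config("mask grid does not match its reference volume")
  if (require_nonempty && sum(v) < 1)
    stop_config("mask has no foreground voxels")
  array(as.numeric(v), dim = dim(v))
}

# NIfTI I/O -------------------------------------------------------------------

#' Read a NIfTI volume from disk
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach (the file format does not carry it).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = "derived") {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  vals <- as.array(img)
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vals)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  xf <- RNifti::xform(img)
  image_volume(array(as.numeric(vals), dim = dim(vals)),
               spacing = RNifti::pixdim(img)[1:3],
               origin = xf[1:3, 4],
               modality = modality)
}

#' Write an image volume to NIfTI
#'
#' Voxel values, spacing, and origin round-trip exactly; binary masks written
#' with `datatype = "uint8"` round-trip bit-exactly.
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"double"` (default) or `"uint8"` for
#'   masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# ADC computation -------------------------------------------------------------

#' Compute an ADC map from two diffusion-weighted volumes
#'
#' The apparent diffusion coefficient is obtained from the mono-exponential
#' diffusion model with the acquisition's two b-values,
#' `ADC = ln(S_low / S_high) / (b_high - b_low)` voxelwise, in mm^2/s.
#' Defaults correspond to b = 100 and b = 1000 s/mm^2. Signals are clamped to
#' a small positive floor (1e-8) before the logarithm.
#'
#' @param s_low [image_volume()] acquired at the low b-value.
#' @param s_high [image_volume()] acquired at the high b-value.
#' @param b_low,b_high the b-values in s/mm^2.
#' @return An ADC [image_volume()] on the same grid.
#' @examples
#' s1 <- image_volume(array(exp(1), c(2, 2, 2)))
#' s2 <- image_volume(array(1, c(2, 2, 2)))
#' range(compute_adc(s1, s2)$values)  # 1/900
#' @export
compute_adc <- function(s_low, s_high, b_low = 100, b_high = 1000) {
  stopifnot(inherits(s_low, "image_volume"), inherits(s_high, "image_volume"))
  if (!identical(dim(s_low$values), dim(s_high$values)) ||
      !isTRUE(all.equal(s_low$spacing, s_high$spacing)))
    stop("diffusion volumes are not aligned (grid or spacing mismatch)")
  if (b_high <= b_low) stop_config("b_high must exceed b_low")
  lo <- pmax(s_low$values, 1e-8)
  hi <- pmax(s_high$values, 1e-8)
  adc <- log(lo / hi) / (b_high - b_low)
  out <- as_volume_like(adc, s_low, modality = "ADC")
  out
}

# Resampling ------------------------------------------------------------------

# Mirror (whole-sample reflective) index into 1..n
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# Cubic B-spline prefilter along the first dimension of a matrix of lines
# (rows = samples along the axis, cols = independent lines). Unser's
# recursive algorithm with pole z = sqrt(3) - 2, mirror boundary.
bspline_prefilter_lines <- function(x) {
  n <- nrow(x)
  if (n == 1L) return(x * 1)
  z <- sqrt(3) - 2
  x <- x * 6
  cp <- matrix(0, n, ncol(x))
  # causal initialisation: geometric sum of z^k over the mirror-extended signal
  horizon <- ceiling(log(1e-12) / log(abs(z)))
  w <- z ^ (seq_len(horizon) - 1)
  ext <- mirror_index(seq_len(horizon), n)
  cp[1, ] <- drop(crossprod(x[ext, , drop = FALSE], w))
  for (i in 2:n) cp[i, ] <- x[i, ] + z * cp[i - 1, ]
  cm <- matrix(0, n, ncol(x))
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

# Evaluate 1D interpolation of lines (rows = source samples) at target
# positions t (0-based, in source index units).
interp_lines_1d <- function(x, t, interpolator) {
  n <- nrow(x)
  if (interpolator == "nearest") {
    idx <- mirror_index(round(t) + 1, n)
    return(x[idx, , drop = FALSE])
  }
  if (interpolator == "linear") {
    i0 <- floor(t)
    f <- t - i0
    a <- x[mirror_index(i0 + 1, n), , drop = FALSE]
    b <- x[mirror_index(i0 + 2, n), , drop = FALSE]
    return(a * (1 - f) + b * f)
  }
  # cubic B-spline on prefiltered coefficients
  cfs <- bspline_prefilter_lines(x)
  i0 <- floor(t)
  f <- t - i0
  w0 <- (1 - f)^3 / 6
  w1 <- (4 - 6 * f^2 + 3 * f^3) / 6
  w2 <- (1 + 3 * f + 3 * f^2 - 3 * f^3) / 6
  w3 <- f^3 / 6
  out <- w0 * cfs[mirror_index(i0,     n), , drop = FALSE] +
         w1 * cfs[mirror_index(i0 + 1, n), , drop = FALSE] +
         w2 * cfs[mirror_index(i0 + 2, n), , drop = FALSE] +
         w3 * cfs[mirror_index(i0 + 3, n), , drop = FALSE]
  out
}

# Apply 1D interpolation along axis `axis` of 3D array `a`, evaluating at
# 0-based source coordinates `t` (one per output sample along that axis).
interp_axis <- function(a, axis, t, interpolator) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- interp_lines_1d(m, t, interpolator)
  dim(out) <- c(length(t), d[setdiff(1:3, axis)])
  aperm(out, order(perm))
}

#' Resample a volume onto a reference grid
#'
#' Maps the moving volume onto the voxel grid of `reference` under the
#' identity physical transform (the pipeline assumes spatially aligned
#' acquisitions; registration estimation is out of scope). Interpolation is
#' separable along the three axes. The cubic B-spline interpolator uses exact
#' prefiltering so that it interpolates (reproduces sample values at source
#' grid nodes); use `"nearest"` for binary masks.
#'
#' @param moving [image_volume()] to resample.
#' @param reference [image_volume()] defining the output grid.
#' @param interpolator `"bspline"` (default), `"linear"`, or `"nearest"`.
#' @return An [image_volume()] on the reference grid.
#' @export
resample_to_reference <- function(moving, reference,
                                  interpolator = c("bspline", "linear", "nearest")) {
  stopifnot(inherits(moving, "image_volume"), inherits(reference, "image_volume"))
  interpolator <- match.arg(interpolator)
  if (identical(dim(moving$values), dim(reference$values)) &&
      isTRUE(all.equal(moving$spacing, reference$spacing)) &&
      isTRUE(all.equal(moving$origin, reference$origin))) {
    out <- moving
    out$origin <- reference$origin
    return(out)
  }
  a <- moving$values
  for (axis in 1:3) {
    phys <- reference$origin[axis] +
      (seq_len(dim(reference$values)[axis]) - 1) * reference$spacing[axis]
    t <- (phys - moving$origin[axis]) / moving$spacing[axis]  # 0-based
    a <- interp_axis(a, axis, t, interpolator)
  }
  image_volume(a, spacing = reference$spacing, origin = reference$origin,
               modality = moving$modality)
}

# Intensity normalization and discretization ----------------------------------

#' Normalize image intensities to zero mean, fixed scale
#'
#' Centres and rescales voxel intensities as `scale * (x - mean) / sd`. By
#' default the statistics are taken over the whole image (the convention of
#' the extraction settings used here); pass a mask to use masked statistics
#' instead.
#'
#' @param volume an [image_volume()].
#' @param mask optional binary mask restricting the statistics.
#' @param scale output standard deviation (default 100).
#' @return A normalized [image_volume()].
#' @export
normalize_intensity <- function(volume, mask = NULL, scale = 100) {
  stopifnot(inherits(volume, "image_volume"))
  x <- volume$values
  sel <- if (is.null(mask)) rep(TRUE, length(x)) else check_mask(mask, volume) > 0
  mu <- mean(x[sel])
  sdv <- stats::sd(x[sel])
  if (!is.finite(sdv) || sdv <= 0)
    stop("degenerate input: intensity standard deviation is zero")
  out <- as_volume_like(scale * (x - mu) / sdv, volume, modality = volume$modality)
  out
}

#' Discretize masked intensities into fixed-width gray-level bins
#'
#' Gray levels are `floor((x - min) / bin_width) + 1` over masked voxels; the
#' number of levels is `floor((max - min) / bin_width) + 1` (at least 1; a
#' maximum on an exact bin edge opens its own top level). Discretization is
#' invariant to adding a constant to all masked intensities.
#'
#' @param volume an [image_volume()] or bare 3D array.
#' @param mask binary mask (array or [image_volume()]), non-empty.
#' @param bin_width positive bin width in intensity units (default 25).
#' @return A `discretized_volume`: list with integer array `levels` (0 outside
#'   the mask), `n_levels`, `bin_width`, `mask`, and `spacing`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  x <- if (inherits(volume, "image_volume")) volume$values else volume
  spacing <- if (inherits(volume, "image_volume")) volume$spacing else c(1, 1, 1)
  assert_scalar_number(bin_width, "bin_width", lower = .Machine$double.eps)
  m <- check_mask(mask, if (inherits(volume, "image_volume")) volume else NULL)
  if (!identical(dim(m), dim(x))) stop_config("mask grid does not match volume")
  sel <- m > 0
  vals <- x[sel]
  lo <- min(vals)
  hi <- max(vals)
  # a maximum landing exactly on a bin edge opens a new (top) level
  n_levels <- as.integer(floor((hi - lo) / bin_width)) + 1L
  lev <- pmin(as.integer(floor((vals - lo) / bin_width)) + 1L, n_levels)
  levels <- array(0L, dim = dim(x))
  levels[sel] <- lev
  structure(list(levels = levels, n_levels = n_levels, bin_width = bin_width,
                 mask = sel, spacing = spacing),
            class = "discretized_volume")
}

#' @export
print.discretized_volume <- function(x, ...) {
  cat(sprintf("<discretized_volume> %d levels, %d masked voxels, bin width %s\n",
              x$n_levels, sum(x$mask), format(x$bin_width)))
  invisible(x)
}
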