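# 3D shape features of a binary VOI mask. The surface is the voxel-face
# ("blocky") mesh: the set of faces separating foreground from background
# voxels, with vertices at voxel corners. Areas and the mesh volume are
# computed on that mesh; consequently MeshVolume coincides with VoxelVolume
# (the divergence theorem over voxel faces is exact) and SurfaceArea refers
# to the voxelized surface, not a smoothed iso-surface.

# Surface-face inventory: for each axis and sign, foreground voxels whose
# neighbour in that direction is background (or outside the grid).
surface_faces <- function(mask) {
  d <- dim(mask)
  faces <- list()
  for (axis in 1:3) for (s in c(1, -1)) {
    off <- c(0L, 0L, 0L); off[axis] <- s
    nb <- shift3d(mask, -off, fill = 0)
    sel <- which(mask > 0 & nb == 0)
    if (length(sel)) {
      idx <- arrayInd(sel, d)
      faces[[length(faces) + 1L]] <- list(axis = axis, sign = s, idx = idx)
    }
  }
  faces
}

# Unique mesh vertices in half-step index units (integers = 2 * (i - 1) +/- 1)
surface_vertices <- function(faces) {
  vs <- matrix(0L, 0L, 3L)
  for (f in faces) {
    ctr <- 2L * (f$idx - 1L)
    n <- nrow(ctr)
    others <- setdiff(1:3, f$axis)
    base <- ctr
    base[, f$axis] <- base[, f$axis] + f$sign
    for (d1 in c(-1L, 1L)) for (d2 in c(-1L, 1L)) {
      v <- base
      v[, others[1]] <- v[, others[1]] + d1
      v[, others[2]] <- v[, others[2]] + d2
      vs <- rbind(vs, v)
    }
  }
  unique(vs)
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}

# Candidate vertices for the 3D diameter: union over the three slicing
# orientations of each slice's 2D convex hull (every 3D-hull vertex is a 2D
# hull vertex of its slice in at least one orientation).
diameter_candidates <- function(vp) {
  keep <- rep(FALSE, nrow(vp))
  for (axis in 1:3) {
    others <- setdiff(1:3, axis)
    sl <- split(seq_len(nrow(vp)), vp[, axis])
    for (ii in sl) {
      if (length(ii) <= 3L) { keep[ii] <- TRUE; next }
      h <- grDevices::chull(vp[ii, others[1]], vp[ii, others[2]])
      keep[ii[h]] <- TRUE
    }
  }
  vp[keep, , drop = FALSE]
}

#' Shape features of a binary mask
#'
#' The 14 standard 3D shape descriptors, computed once per VOI from the mask
#' geometry alone (intensity-independent). Maximum 2D diameters are the
#' largest in-plane distances between surface vertices sharing a plane:
#' `Slice` is in the (x, y) plane (grouped by z), `Column` in (x, z)
#' (grouped by y), and `Row` in (y, z) (grouped by x), for array dimensions
#' ordered (x, y, z). Axis lengths are `4 * sqrt(eigenvalue)` of the
#' physical-coordinate covariance of masked voxel centres.
#'
#' @param mask binary mask (3D array or [image_volume()]), non-empty.
#' @param spacing voxel spacing in mm (ignored if `mask` is an
#'   [image_volume()], which carries its own).
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (inherits(mask, "image_volume")) {
    spacing <- mask$spacing
    mask <- mask$values
  }
  m <- check_mask(mask)
  d <- dim(m)
  nvox <- sum(m)
  voxvol <- prod(spacing)
  faces <- surface_faces(m)

  # surface area and divergence-theorem volume over the face mesh
  area <- 0
  vol <- 0
  for (f in faces) {
    others <- setdiff(1:3, f$axis)
    a <- spacing[others[1]] * spacing[others[2]]
    area <- area + nrow(f$idx) * a
    # outward x-faces contribute sign * x_face * area to the volume integral
    if (f$axis == 1L) {
      xface <- (f$idx[, 1] - 1 + f$sign / 2) * spacing[1]
      vol <- vol + sum(f$sign * xface * a)
    }
  }

  vp_half <- surface_vertices(faces)             # half-step integer coords
  vp <- sweep(vp_half, 2, spacing / 2, `*`)      # physical mm

  d2 <- c(Slice = 0, Column = 0, Row = 0)
  grp_axis <- c(Slice = 3L, Column = 2L, Row = 1L)
  for (nm in names(grp_axis)) {
    ax <- grp_axis[[nm]]
    others <- setdiff(1:3, ax)
    best <- 0
    for (ii in split(seq_len(nrow(vp)), vp_half[, ax])) {
      pts <- vp[ii, others, drop = FALSE]
      if (nrow(pts) > 4L) {
        h <- grDevices::chull(pts[, 1], pts[, 2])
        pts <- pts[h, , drop = FALSE]
      }
      best <- max(best, max_pairwise_dist(pts))
    }
    d2[[nm]] <- best
  }
  max3d <- max_pairwise_dist(diameter_candidates(vp))

  coords <- (arrayInd(which(m > 0), d) - 1)
  coords <- sweep(coords, 2, spacing, `*`)
  cc <- sweep(coords, 2, colMeans(coords), `-`)
  ev <- sort(eigen(crossprod(cc) / nvox, symmetric = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)

  sphericity <- (36 * pi * vol^2)^(1 / 3) / area

  c(MeshVolume = vol,
    VoxelVolume = nvox * voxvol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = sphericity,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = d2[["Slice"]],
    Maximum2DDiameterColumn = d2[["Column"]],
    Maximum2DDiameterRow = d2[["Row"]],
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}
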