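# Gray-level texture-matrix feature families (GLCM, GLRLM, GLSZM, NGTDM,
# GLDM), computed from a discretized VOI. All families use the 3D
# 26-neighbourhood; GLCM and GLRLM evaluate the 13 unique direction offsets
# at distance 1 and average feature values over directions (not merged
# matrices). Entropies are in bits (log base 2).
#
# The neighbourhood structure depends on the mask only, so it is built once
# per VOI (mask_context) and shared across all filtered images; per-image
# work is then pure vector arithmetic on masked voxels.

check_disc <- function(disc) {
  if (!inherits(disc, "discretized_volume"))
    stop_config("expected a discretized_volume (see discretize())")
  if (sum(disc$mask) < 1) stop_config("mask has no foreground voxels")
  disc
}

safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

# Neighbourhood context of a mask: for each of the 13 unique offsets, the
# collision-free pair lists (p, q) of masked-voxel ranks such that voxel q
# is voxel p's neighbour at that offset; plus, per direction, the run-scan
# ordering of masked voxels and the mask-driven run breaks.
mask_context <- function(mask) {
  d <- dim(mask)
  sel <- which(mask > 0)
  n <- length(sel)
  rank_map <- integer(prod(d))
  rank_map[sel] <- seq_len(n)
  idx <- arrayInd(sel, d)
  offs <- offsets13()
  pairs <- vector("list", nrow(offs))
  runs <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- sweep(idx, 2, off, `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    nb_lin <- (nb[ok, 3] - 1L) * (d[1] * d[2]) + (nb[ok, 2] - 1L) * d[1] +
      nb[ok, 1]
    q <- rank_map[nb_lin]
    keep <- q > 0L
    pairs[[r]] <- list(p = which(ok)[keep], q = q[keep])
    # run-length scan order along this direction
    k1 <- idx[, 1] * off[2] - idx[, 2] * off[1]
    k2 <- idx[, 2] * off[3] - idx[, 3] * off[2]
    k3 <- idx[, 1] * off[3] - idx[, 3] * off[1]
    t_pos <- idx[, 1] * off[1] + idx[, 2] * off[2] + idx[, 3] * off[3]
    o <- order(k1, k2, k3, t_pos)
    brk <- c(TRUE, !(k1[o][-1] == k1[o][-n] & k2[o][-1] == k2[o][-n] &
                       k3[o][-1] == k3[o][-n] &
                       diff(t_pos[o]) == sum(off^2)))
    runs[[r]] <- list(o = o, brk = brk)
  }
  list(n = n, pairs = pairs, runs = runs)
}

disc_context <- function(disc) {
  ctx <- attr(disc, "mask_context")
  if (is.null(ctx)) ctx <- mask_context(disc$mask)
  ctx
}

# ---------------------------------------------------------------------------
# GLCM
# ---------------------------------------------------------------------------

glcm_features_one <- function(P) {
  present <- which(rowSums(P) + colSums(P) > 0)
  P <- P[present, present, drop = FALSE]
  P <- P / sum(P)
  i_lev <- as.numeric(present)
  ng <- length(i_lev)
  I <- matrix(i_lev, ng, ng)
  J <- t(I)
  px <- rowSums(P)
  py <- colSums(P)         # = px by symmetry
  mu_x <- sum(px * i_lev)
  mu_y <- sum(py * i_lev)
  var_x <- sum(px * (i_lev - mu_x)^2)
  var_y <- sum(py * (i_lev - mu_y)^2)
  kdiff <- abs(I - J)
  ksum <- I + J
  pd <- tapply(P, kdiff, sum)
  kd <- as.numeric(names(pd))
  ps <- tapply(P, ksum, sum)
  ks <- as.numeric(names(ps))
  da <- sum(pd * kd)
  hx <- -sum(px * safe_log2(px))
  hxy <- -sum(P * safe_log2(P))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * safe_log2(pxy))
  hxy2 <- -sum(pxy * safe_log2(pxy))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  correlation <- if (var_x > 0 && var_y > 0)
    (sum(P * I * J) - mu_x * mu_y) / sqrt(var_x * var_y) else 1
  mcc <- if (ng > 1) {
    Q <- (P / px) %*% t(P / matrix(py, ng, ng, byrow = FALSE))
    evs <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, evs[2])))
  } else 1
  c(Autocorrelation = sum(P * I * J),
    ClusterProminence = sum(P * (I + J - mu_x - mu_y)^4),
    ClusterShade = sum(P * (I + J - mu_x - mu_y)^3),
    ClusterTendency = sum(P * (I + J - mu_x - mu_y)^2),
    Contrast = sum(P * (I - J)^2),
    Correlation = correlation,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * safe_log2(pd)),
    DifferenceVariance = sum(pd * (kd - da)^2),
    Id = sum(P / (1 + kdiff)),
    Idm = sum(P / (1 + kdiff^2)),
    Idmn = sum(P / (1 + kdiff^2 / ng^2)),
    Idn = sum(P / (1 + kdiff / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(ifelse(kdiff > 0, P / pmax(kdiff, 1)^2, 0)),
    JointAverage = mu_x,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ps * ks),
    SumEntropy = -sum(ps * safe_log2(ps)),
    SumSquares = sum(P * (I - mu_x)^2))
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence of gray-level pairs at distance 1 over the 13
#' unique 3D direction offsets; the 24 standard GLCM features are computed
#' per direction and averaged over directions that contain at least one
#' voxel pair. For a single-level region `Correlation` and `MCC` are defined
#' as 1 (perfect association sentinel).
#'
#' @param disc a `discretized_volume` from [discretize()].
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(disc) {
  check_disc(disc)
  ctx <- disc_context(disc)
  lv <- disc$levels[disc$mask]
  ng <- disc$n_levels
  feats <- NULL
  n_dir <- 0L
  for (pr in ctx$pairs) {
    if (length(pr$p) == 0L) next
    cnt <- matrix(tabulate((lv[pr$p] - 1L) * ng + lv[pr$q], nbins = ng * ng),
                  ng, ng)
    f <- glcm_features_one(cnt + t(cnt))
    feats <- if (is.null(feats)) f else feats + f
    n_dir <- n_dir + 1L
  }
  if (n_dir == 0L)
    stop("no voxel pairs in any direction; region too small for GLCM")
  feats / n_dir
}

# ---------------------------------------------------------------------------
# GLRLM
# ---------------------------------------------------------------------------

glrlm_features_one <- function(run_lev, run_len, ng, n_vox) {
  nr <- length(run_len)
  nl <- max(run_len)
  R <- matrix(tabulate((run_lev - 1L) * nl + run_len, nbins = ng * nl),
              ng, nl, byrow = TRUE)
  i_lev <- seq_len(ng)
  l_len <- seq_len(nl)
  p <- R / nr
  pg <- rowSums(p)
  pl <- colSums(p)
  mu_i <- sum(pg * i_lev)
  mu_l <- sum(pl * l_len)
  I2 <- matrix(i_lev^2, ng, nl)
  L2 <- matrix(l_len^2, ng, nl, byrow = TRUE)
  c(ShortRunEmphasis = sum(p / L2),
    LongRunEmphasis = sum(p * L2),
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    RunLengthNonUniformityNormalized = sum(pl^2),
    RunPercentage = nr / n_vox,
    GrayLevelVariance = sum(pg * (i_lev - mu_i)^2),
    RunVariance = sum(pl * (l_len - mu_l)^2),
    RunEntropy = -sum(p * safe_log2(p)),
    LowGrayLevelRunEmphasis = sum(p / I2),
    HighGrayLevelRunEmphasis = sum(p * I2),
    ShortRunLowGrayLevelEmphasis = sum(p / (I2 * L2)),
    ShortRunHighGrayLevelEmphasis = sum(p * I2 / L2),
    LongRunLowGrayLevelEmphasis = sum(p * L2 / I2),
    LongRunHighGrayLevelEmphasis = sum(p * I2 * L2))
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices along the 13 unique 3D directions (distance-1 steps;
#' runs break at mask boundaries), with the 16 standard features averaged
#' over directions.
#'
#' @param disc a `discretized_volume` from [discretize()].
#' @return Named numeric vector of length 16.
#' @export
glrlm_features <- function(disc) {
  check_disc(disc)
  ctx <- disc_context(disc)
  lv <- disc$levels[disc$mask]
  n <- ctx$n
  feats <- NULL
  for (rn in ctx$runs) {
    lev_o <- lv[rn$o]
    new_run <- rn$brk | c(TRUE, lev_o[-1] != lev_o[-n])
    run_id <- cumsum(new_run)
    f <- glrlm_features_one(lev_o[new_run], tabulate(run_id),
                            disc$n_levels, n)
    feats <- if (is.null(feats)) f else feats + f
  }
  feats / length(ctx$runs)
}

# ---------------------------------------------------------------------------
# GLSZM
# ---------------------------------------------------------------------------

# Connected components (26-connectivity, equal level) on the masked-voxel
# graph: iterative minimum-label propagation over the precomputed pair
# lists with pointer-jumping compression.
label_zones_ctx <- function(lv, ctx) {
  lab <- seq_len(ctx$n)
  eq <- lapply(ctx$pairs, function(pr) {
    keep <- lv[pr$p] == lv[pr$q]
    list(p = pr$p[keep], q = pr$q[keep])
  })
  repeat {
    changed <- FALSE
    for (pr in eq) {
      if (length(pr$p) == 0L) next
      m <- pmin(lab[pr$p], lab[pr$q])
      if (any(lab[pr$p] > m)) { lab[pr$p] <- m; changed <- TRUE }
      m <- pmin(lab[pr$p], lab[pr$q])
      if (any(lab[pr$q] > m)) { lab[pr$q] <- m; changed <- TRUE }
    }
    repeat {
      jumped <- lab[lab]
      if (identical(jumped, lab)) break
      lab <- jumped
      changed <- TRUE
    }
    if (!changed) break
  }
  roots <- which(lab == seq_len(ctx$n))
  zone_of <- match(lab, roots)
  list(size = tabulate(zone_of, nbins = length(roots)),
       level = lv[roots])
}

glszm_features_one <- function(sizes, levels, ng, n_vox) {
  nz <- length(sizes)
  ns <- max(sizes)
  S <- matrix(tabulate((levels - 1L) * ns + sizes, nbins = ng * ns),
              ng, ns, byrow = TRUE)
  i_lev <- seq_len(ng)
  s_len <- seq_len(ns)
  p <- S / nz
  pg <- rowSums(p)
  psz <- colSums(p)
  mu_i <- sum(pg * i_lev)
  mu_s <- sum(psz * s_len)
  I2 <- matrix(i_lev^2, ng, ns)
  S2 <- matrix(s_len^2, ng, ns, byrow = TRUE)
  c(SmallAreaEmphasis = sum(p / S2),
    LargeAreaEmphasis = sum(p * S2),
    GrayLevelNonUniformity = sum(rowSums(S)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    SizeZoneNonUniformity = sum(colSums(S)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(psz^2),
    ZonePercentage = nz / n_vox,
    GrayLevelVariance = sum(pg * (i_lev - mu_i)^2),
    ZoneVariance = sum(psz * (s_len - mu_s)^2),
    ZoneEntropy = -sum(p * safe_log2(p)),
    LowGrayLevelZoneEmphasis = sum(p / I2),
    HighGrayLevelZoneEmphasis = sum(p * I2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (I2 * S2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * I2 / S2),
    LargeAreaLowGrayLevelEmphasis = sum(p * S2 / I2),
    LargeAreaHighGrayLevelEmphasis = sum(p * I2 * S2))
}

#' Gray-level size-zone matrix features
#'
#' Zones are maximal 26-connected components of equal gray level; the 16
#' standard size-zone features (including `ZoneEntropy`) are computed from
#' the level-by-size zone count matrix. Rotationally invariant (no
#' direction averaging).
#'
#' @param disc a `discretized_volume` from [discretize()].
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(disc) {
  check_disc(disc)
  ctx <- disc_context(disc)
  z <- label_zones_ctx(disc$levels[disc$mask], ctx)
  glszm_features_one(z$size, z$level, disc$n_levels, ctx$n)
}

# ---------------------------------------------------------------------------
# NGTDM
# ---------------------------------------------------------------------------

#' Neighbourhood gray-tone difference matrix features
#'
#' For each masked voxel with at least one masked 26-neighbour, the absolute
#' difference between its level and the mean level of those neighbours is
#' accumulated per gray level, yielding the classic Coarseness, Contrast,
#' Busyness, Complexity and Strength descriptors. Single-level regions give
#' Contrast = Busyness = Complexity = Strength = 0.
#'
#' @param disc a `discretized_volume` from [discretize()].
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(disc) {
  check_disc(disc)
  ctx <- disc_context(disc)
  lv <- disc$levels[disc$mask]
  nb_sum <- numeric(ctx$n)
  nb_cnt <- numeric(ctx$n)
  for (pr in ctx$pairs) {
    nb_sum[pr$p] <- nb_sum[pr$p] + lv[pr$q]
    nb_cnt[pr$p] <- nb_cnt[pr$p] + 1
    nb_sum[pr$q] <- nb_sum[pr$q] + lv[pr$p]
    nb_cnt[pr$q] <- nb_cnt[pr$q] + 1
  }
  valid <- nb_cnt > 0
  nv <- sum(valid)
  if (nv == 0)
    stop("no voxel has a masked neighbour; region too small for NGTDM")
  lev <- lv[valid]
  diffv <- abs(lev - nb_sum[valid] / nb_cnt[valid])
  ng <- disc$n_levels
  n_i <- tabulate(lev, nbins = ng)
  s_i <- numeric(ng)
  agg <- rowsum(diffv, lev)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  ngtdm_features_one(n_i, s_i, nv)
}

# Feature formulas from the NGTDM table (counts n_i, summed differences s_i,
# number of voxels with a valid neighbourhood).
ngtdm_features_one <- function(n_i, s_i, nv) {
  present <- which(n_i > 0)
  p <- n_i[present] / nv
  s <- s_i[present]
  i_lev <- present
  ngp <- length(present)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    ii <- matrix(i_lev, ngp, ngp)
    jj <- t(ii)
    pi_ <- matrix(p, ngp, ngp)
    pj_ <- t(pi_)
    si_ <- matrix(s, ngp, ngp)
    sj_ <- t(si_)
    contrast <- sum(pi_ * pj_ * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s) / nv
    busy_den <- sum(abs(ii * pi_ - jj * pj_))
    busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
    complexity <- sum(abs(ii - jj) * (pi_ * si_ + pj_ * sj_) / (pi_ + pj_)) / nv
    strength <- if (sum(s) > 0)
      sum((pi_ + pj_) * (ii - jj)^2) / sum(s) else 0
  } else {
    contrast <- busyness <- complexity <- strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

# ---------------------------------------------------------------------------
# GLDM
# ---------------------------------------------------------------------------

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is the number of its masked 26-neighbours whose
#' gray level differs from the centre level by at most `alpha`. The 14
#' standard features are computed from the level-by-dependence count matrix
#' (dependence-size index `j = dependence + 1` in the size-weighted
#' formulas).
#'
#' @param disc a `discretized_volume` from [discretize()].
#' @param alpha gray-level tolerance for dependence (default 0).
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(disc, alpha = 0) {
  check_disc(disc)
  ctx <- disc_context(disc)
  lv <- disc$levels[disc$mask]
  dep <- integer(ctx$n)
  for (pr in ctx$pairs) {
    ok <- abs(lv[pr$p] - lv[pr$q]) <= alpha
    dep[pr$p[ok]] <- dep[pr$p[ok]] + 1L
    dep[pr$q[ok]] <- dep[pr$q[ok]] + 1L
  }
  gldm_features_one(lv, dep, disc$n_levels)
}

# Feature formulas from per-voxel (gray level, dependence count) pairs.
gldm_features_one <- function(lv, dep, ng) {
  nd <- max(dep) + 1L
  D <- matrix(tabulate((lv - 1L) * nd + dep + 1L, nbins = ng * nd),
              ng, nd, byrow = TRUE)
  nz <- sum(D)
  i_lev <- seq_len(ng)
  j_dep <- seq_len(nd)   # dependence + 1
  p <- D / nz
  pg <- rowSums(p)
  pd <- colSums(p)
  mu_i <- sum(pg * i_lev)
  mu_j <- sum(pd * j_dep)
  I2 <- matrix(i_lev^2, ng, nd)
  J2 <- matrix(j_dep^2, ng, nd, byrow = TRUE)
  c(SmallDependenceEmphasis = sum(p / J2),
    LargeDependenceEmphasis = sum(p * J2),
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nz,
    DependenceNonUniformity = sum(colSums(D)^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2),
    GrayLevelVariance = sum(pg * (i_lev - mu_i)^2),
    DependenceVariance = sum(pd * (j_dep - mu_j)^2),
    DependenceEntropy = -sum(p * safe_log2(p)),
    LowGrayLevelEmphasis = sum(p / I2),
    HighGrayLevelEmphasis = sum(p * I2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (I2 * J2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * I2 / J2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * J2 / I2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * I2 * J2))
}
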