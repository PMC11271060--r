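# Brute-force oracles for the texture families and filters: deliberately
# slow, loop-based enumerations written directly from the matrix/operator
# definitions, independent of the vectorized implementation paths.

# Build a discretized_volume directly from a level array (0 = outside mask).
make_disc <- function(levels, spacing = c(1, 1, 1), bin_width = 1) {
  levels <- array(as.integer(levels), dim = dim(levels))
  structure(list(levels = levels, n_levels = max(levels), bin_width = bin_width,
                 mask = levels > 0L, spacing = spacing),
            class = "discretized_volume")
}

random_disc <- function(dm, n_levels, p_mask = 0.8) {
  lv <- array(sample.int(n_levels, prod(dm), replace = TRUE), dim = dm)
  lv[stats::runif(prod(dm)) > p_mask] <- 0L
  if (all(lv == 0L)) lv[1] <- 1L
  make_disc(lv)
}

all_offsets13 <- function() plnmrad:::offsets13()
all_offsets26 <- function() plnmrad:::offsets26()

in_grid <- function(co, d) all(co >= 1L) && all(co <= d)

# GLCM: symmetric pair counting by explicit voxel loop, one offset.
oracle_glcm_matrix <- function(lv, off) {
  d <- dim(lv)
  ng <- max(lv)
  P <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lv[x, y, z] == 0L) next
    nb <- c(x, y, z) + off
    if (!in_grid(nb, d)) next
    l2 <- lv[nb[1], nb[2], nb[3]]
    if (l2 == 0L) next
    P[lv[x, y, z], l2] <- P[lv[x, y, z], l2] + 1
    P[l2, lv[x, y, z]] <- P[l2, lv[x, y, z]] + 1
  }
  P
}

# GLRLM: explicit run scan along one direction.
oracle_glrlm_runs <- function(lv, off) {
  d <- dim(lv)
  runs_lev <- integer(0)
  runs_len <- integer(0)
  visited <- array(FALSE, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lv[x, y, z] == 0L || visited[x, y, z]) next
    prev <- c(x, y, z) - off
    # only start a scan at the beginning of a line segment
    if (in_grid(prev, d) && lv[prev[1], prev[2], prev[3]] != 0L) next
    co <- c(x, y, z)
    cur_lev <- 0L
    cur_len <- 0L
    while (in_grid(co, d) && lv[co[1], co[2], co[3]] != 0L) {
      visited[co[1], co[2], co[3]] <- TRUE
      l <- lv[co[1], co[2], co[3]]
      if (l == cur_lev) cur_len <- cur_len + 1L
      else {
        if (cur_len > 0L) {
          runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
        }
        cur_lev <- l; cur_len <- 1L
      }
      co <- co + off
    }
    if (cur_len > 0L) {
      runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
    }
  }
  list(lev = runs_lev, len = runs_len)
}

# GLSZM: recursive flood fill with 26-connectivity.
oracle_glszm_zones <- function(lv) {
  d <- dim(lv)
  seen <- array(FALSE, dim = d)
  offs <- all_offsets26()
  sizes <- integer(0)
  levels <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (lv[x, y, z] == 0L || seen[x, y, z]) next
    lev <- lv[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      co <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (!in_grid(nb, d)) next
        if (seen[nb[1], nb[2], nb[3]]) next
        if (lv[nb[1], nb[2], nb[3]] != lev) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
    sizes <- c(sizes, size)
    levels <- c(levels, lev)
  }
  list(size = sizes, level = levels)
}

# NGTDM: per-voxel neighbourhood means by explicit loop.
oracle_ngtdm <- function(lv) {
  d <- dim(lv)
  ng <- max(lv)
  offs <- all_offsets26()
  n_i <- integer(ng)
  s_i <- numeric(ng)
  n_valid <- 0L
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    l <- lv[x, y, z]
    if (l == 0L) next
    vals <- numeric(0)
    for (r in seq_len(nrow(offs))) {
      nb <- c(x, y, z) + offs[r, ]
      if (!in_grid(nb, d)) next
      l2 <- lv[nb[1], nb[2], nb[3]]
      if (l2 > 0L) vals <- c(vals, l2)
    }
    if (length(vals) == 0L) next
    n_valid <- n_valid + 1L
    n_i[l] <- n_i[l] + 1L
    s_i[l] <- s_i[l] + abs(l - mean(vals))
  }
  list(n = n_i, s = s_i, n_valid = n_valid)
}

# GLDM: dependence counting by explicit loop.
oracle_gldm <- function(lv, alpha = 0) {
  d <- dim(lv)
  offs <- all_offsets26()
  level <- integer(0)
  dep <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    l <- lv[x, y, z]
    if (l == 0L) next
    cnt <- 0L
    for (r in seq_len(nrow(offs))) {
      nb <- c(x, y, z) + offs[r, ]
      if (!in_grid(nb, d)) next
      l2 <- lv[nb[1], nb[2], nb[3]]
      if (l2 > 0L && abs(l2 - l) <= alpha) cnt <- cnt + 1L
    }
    level <- c(level, l)
    dep <- c(dep, cnt)
  }
  list(level = level, dep = dep)
}

# Dense 3D convolution with mirror boundary (separable kernels), for filter
# impulse-response checks.
oracle_convolve3d <- function(a, kx, ky, kz) {
  mirr <- function(i, n) plnmrad:::mirror_index(i, n)
  d <- dim(a)
  out <- array(0, dim = d)
  cx <- (length(kx) + 1L) %/% 2L
  cy <- (length(ky) + 1L) %/% 2L
  cz <- (length(kz) + 1L) %/% 2L
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (i in seq_along(kx)) for (j in seq_along(ky)) for (k in seq_along(kz)) {
      acc <- acc + kx[i] * ky[j] * kz[k] *
        a[mirr(x + i - cx, d[1]), mirr(y + j - cy, d[2]),
          mirr(z + k - cz, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

# AUC by exhaustive positive-negative pair counting (ties = 1/2).
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# DeLong structural components by explicit kernel enumeration.
oracle_delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(a) mean(vapply(neg, function(b) psi(a, b), 0)), 0)
  v01 <- vapply(neg, function(b) mean(vapply(pos, function(a) psi(a, b), 0)), 0)
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

# Small synthetic feature-table fixture for selection/modeling tests.
toy_tables <- function(n_pos = 40, n_neg = 60, p = 30, p_inf = 5,
                       rho = 0.95, effect = 1, seed = 1) {
  cfg <- sim_config(n_train_pos = n_pos, n_train_neg = n_neg,
                    n_internal = 0, n_external = 0,
                    prevalence_internal = 0, prevalence_external = 0,
                    n_features = p, n_informative = p_inf,
                    cross_tissue_rho = rho, effect_size = effect, seed = seed)
  simulate_feature_tables(cfg)
}
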