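# Synthetic cohorts: phantom image volumes with lesion/node masks, and fast
# paired feature tables with a planted lesion-node shared signature. These
# emulate the statistical structure the analysis assumes (a subset of
# "metastatic signature" features shared between primary-lesion and
# metastatic-node tissue in PLNM-positive cases); they make no attempt at
# anatomical realism.

#' Simulation configuration
#'
#' Cohort-shape defaults follow the study design the pipeline targets:
#' 263 training cases (93 PLNM-positive / 170 negative), 74 internal and 57
#' external validation cases with positive prevalences 19/74 and 14/57, and
#' a 15 mm minimum node short-axis diameter (the radiological >= 1.5 cm
#' inclusion rule). Signal-shape defaults (`n_features = 500`,
#' `n_informative = 20`, `cross_tissue_rho = 0.95`, `effect_size = 0.8`) are
#' artifact choices, exposed here; see the methods vignette for rationale.
#'
#' @param n_train_pos,n_train_neg training-group class counts.
#' @param n_internal,n_external validation-group sizes.
#' @param prevalence_internal,prevalence_external positive fractions of the
#'   validation groups (positives = `round(prevalence * n)`).
#' @param n_features number of features per tissue table.
#' @param n_informative number of planted "metastatic signature" features.
#' @param cross_tissue_rho lesion-node Pearson correlation of informative
#'   feature pairs across positive cases, in `[0, 1]`.
#' @param effect_size standardized mean difference (positive vs negative
#'   cases) of informative lesion features.
#' @param noise_sd residual noise standard deviation.
#' @param min_node_short_axis_mm minimum node short-axis diameter (mm); the
#'   short axis is the middle principal axis of the node ellipsoid.
#' @param vol_dim phantom grid size (voxels).
#' @param spacing phantom voxel spacing (mm).
#' @param seed master seed; all generation is a pure function of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_train_pos = 93, n_train_neg = 170,
                       n_internal = 74, n_external = 57,
                       prevalence_internal = 19 / 74,
                       prevalence_external = 14 / 57,
                       n_features = 500, n_informative = 20,
                       cross_tissue_rho = 0.95, effect_size = 0.8,
                       noise_sd = 1, min_node_short_axis_mm = 15,
                       vol_dim = c(64, 64, 48), spacing = c(1, 1, 1),
                       seed = 1) {
  n_train_pos <- assert_count(n_train_pos, "n_train_pos", min = 0L)
  n_train_neg <- assert_count(n_train_neg, "n_train_neg", min = 0L)
  n_internal <- assert_count(n_internal, "n_internal", min = 0L)
  n_external <- assert_count(n_external, "n_external", min = 0L)
  assert_scalar_number(prevalence_internal, "prevalence_internal", 0, 1)
  assert_scalar_number(prevalence_external, "prevalence_external", 0, 1)
  n_features <- assert_count(n_features, "n_features", min = 1L)
  n_informative <- assert_count(n_informative, "n_informative", min = 0L)
  if (n_informative > n_features)
    stop_config("n_informative must not exceed n_features")
  assert_scalar_number(cross_tissue_rho, "cross_tissue_rho", 0, 1)
  assert_scalar_number(effect_size, "effect_size")
  assert_scalar_number(noise_sd, "noise_sd", lower = .Machine$double.eps)
  assert_scalar_number(min_node_short_axis_mm, "min_node_short_axis_mm",
                       lower = 0)
  seed <- assert_count(seed, "seed")
  structure(list(n_train_pos = n_train_pos, n_train_neg = n_train_neg,
                 n_internal = n_internal, n_external = n_external,
                 prevalence_internal = prevalence_internal,
                 prevalence_external = prevalence_external,
                 n_features = n_features, n_informative = n_informative,
                 cross_tissue_rho = cross_tissue_rho,
                 effect_size = effect_size, noise_sd = noise_sd,
                 min_node_short_axis_mm = min_node_short_axis_mm,
                 vol_dim = as.integer(vol_dim), spacing = as.numeric(spacing),
                 seed = seed),
            class = "sim_config")
}

split_counts <- function(config) {
  n_int_pos <- round(config$prevalence_internal * config$n_internal)
  n_ext_pos <- round(config$prevalence_external * config$n_external)
  data.frame(split = c("train", "internal", "external"),
             n_pos = c(config$n_train_pos, n_int_pos, n_ext_pos),
             n_neg = c(config$n_train_neg, config$n_internal - n_int_pos,
                       config$n_external - n_ext_pos))
}

#' Simulate paired lesion/node feature tables
#'
#' Fast path around image extraction: draws feature tables directly from the
#' planted statistical model. Informative ("metastatic signature") lesion
#' features are mean-shifted by `effect_size` in positive cases and
#' correlate exactly `cross_tissue_rho` (in population) with their
#' same-named node features across positive cases; non-informative features
#' are independent noise in both tissues. Informative features share a
#' case-level latent factor (pairwise correlation 0.5 among them), mimicking
#' the strong mutual correlation of real radiomic signatures. Generation is
#' a pure function of `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `lesion` (data frame, all cases), `node` (data frame,
#'   positive cases only), and `labels` (data frame `case_id`, `split`,
#'   `label`). The informative feature names are attached as
#'   `attr(, "informative")`.
#' @export
simulate_feature_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_features
  feat_names <- sprintf("feat_%04d", seq_len(p))
  counts <- split_counts(config)
  withr::with_seed(derive_seed(config$seed, 0L), {
    informative <- sort(sample.int(p, config$n_informative))
    a2 <- min(0.5, config$cross_tissue_rho)  # latent-factor loading^2
    a <- sqrt(a2)
    b <- sqrt(1 - a2) * config$noise_sd
    v <- a2 + (1 - a2) * config$noise_sd^2   # informative feature variance
    rho_res <- if (a2 < 1) {
      (config$cross_tissue_rho * v - a2) / ((1 - a2) * config$noise_sd^2)
    } else 1
    rho_res <- min(1, max(-1, rho_res))
    lesion <- list(); node <- list(); labels <- NULL
    for (s in seq_len(nrow(counts))) {
      n_pos <- counts$n_pos[s]; n_neg <- counts$n_neg[s]
      n <- n_pos + n_neg
      if (n == 0L) next
      y <- c(rep(1L, n_pos), rep(0L, n_neg))
      ids <- sprintf("%s_%03d", counts$split[s], seq_len(n))
      g <- stats::rnorm(n)
      L <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
      e_inf <- matrix(stats::rnorm(n * length(informative)), n,
                      length(informative))
      L[, informative] <- config$effect_size * y + a * g + b * e_inf
      colnames(L) <- feat_names
      lesion[[counts$split[s]]] <-
        data.frame(case_id = ids, L, check.names = FALSE)
      if (n_pos > 0L) {
        Np <- matrix(stats::rnorm(n_pos * p, sd = config$noise_sd), n_pos, p)
        u <- matrix(stats::rnorm(n_pos * length(informative)), n_pos,
                    length(informative))
        f_inf <- rho_res * e_inf[seq_len(n_pos), , drop = FALSE] +
          sqrt(1 - rho_res^2) * u
        Np[, informative] <- config$effect_size + a * g[seq_len(n_pos)] +
          b * f_inf
        colnames(Np) <- feat_names
        node[[counts$split[s]]] <-
          data.frame(case_id = ids[seq_len(n_pos)], Np, check.names = FALSE)
      }
      labels <- rbind(labels, data.frame(case_id = ids,
                                         split = counts$split[s], label = y))
    }
  })
  out <- list(lesion = do.call(rbind, unname(lesion)),
              node = do.call(rbind, unname(node)),
              labels = labels)
  rownames(out$lesion) <- rownames(out$node) <- rownames(out$labels) <- NULL
  attr(out, "informative") <- feat_names[informative]
  out
}

# -- phantom image simulation -------------------------------------------------

# Gaussian random field: white noise smoothed to correlation length `ell`
# (mm), rescaled to unit variance.
grf <- function(dm, spacing, ell) {
  w <- array(stats::rnorm(prod(dm)), dim = dm)
  sm <- smooth_gaussian(w, ell, spacing)
  sm / stats::sd(sm)
}

ellipsoid_mask <- function(dm, spacing, center, semi) {
  co <- lapply(1:3, function(k) ((seq_len(dm[k]) - 1) * spacing[k] -
                                   center[k]) / semi[k])
  d2 <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  array(as.numeric(d2 <= 1), dim = dm)
}

# Sample a grid position such that an ellipsoid with semi-axes `semi` fits.
place_ellipsoid <- function(extent, semi, margin = 1) {
  lo <- semi + margin
  hi <- extent - semi - margin
  if (any(hi < lo)) stop_config(
    "voxel grid too small to contain a required structure (node short-axis ",
    "constraint cannot be met); increase vol_dim or spacing")
  stats::runif(3, lo, hi)
}

simulate_case <- function(id, label, config, shared_latent) {
  dm <- config$vol_dim
  sp <- config$spacing
  extent <- (dm - 1) * sp
  # case-level texture parameters; positives draw lesion and node texture
  # from the shared latent so extracted features correlate across tissues
  h <- if (label == 1L) shared_latent else stats::rnorm(1)
  amp_lesion <- 14 * exp(0.35 * (h + 0.2 * stats::rnorm(1))) *
    (1 + 0.4 * config$effect_size * label)
  ell_lesion <- 2 * exp(0.15 * h)
  lesion_semi <- sort(stats::runif(3, 5, 9), decreasing = TRUE)
  lesion_center <- place_ellipsoid(extent, lesion_semi, margin = 2)
  lesion_mask <- ellipsoid_mask(dm, sp, lesion_center, lesion_semi)

  t2_bg <- 360 + 25 * grf(dm, sp, 3)
  adc_bg <- 1400 + 90 * grf(dm, sp, 3)
  t2 <- t2_bg + lesion_mask * (-60 + amp_lesion * grf(dm, sp, ell_lesion))
  adc <- adc_bg + lesion_mask * (-650 + 0.45 * amp_lesion * grf(dm, sp, ell_lesion))

  node_masks <- list()
  if (label == 1L) {
    n_nodes <- sample(1:2, 1)
    for (k in seq_len(n_nodes)) {
      s_mid <- (config$min_node_short_axis_mm + stats::runif(1, 0, 5)) / 2
      s_long <- s_mid * stats::runif(1, 1.05, 1.4)
      s_least <- s_mid * stats::runif(1, 0.75, 0.98)
      semi <- sample(c(s_long, s_mid, s_least))  # random axis assignment
      center <- place_ellipsoid(extent, semi, margin = 1)
      nm <- ellipsoid_mask(dm, sp, center, semi)
      amp_node <- 14 * exp(0.35 * (h + 0.2 * stats::rnorm(1))) *
        (1 + 0.4 * config$effect_size)
      ell_node <- 2 * exp(0.15 * h)
      t2 <- t2 + nm * (-40 + amp_node * grf(dm, sp, ell_node))
      adc <- adc + nm * (-600 + 0.45 * amp_node * grf(dm, sp, ell_node))
      node_masks[[k]] <- image_volume(nm, spacing = sp, modality = "mask")
    }
  }
  bp_case(id = id, label = label,
          t2 = image_volume(t2, spacing = sp, modality = "T2"),
          adc = image_volume(adc, spacing = sp, modality = "ADC"),
          lesion_mask = image_volume(lesion_mask, spacing = sp,
                                     modality = "mask"),
          node_masks = node_masks)
}

#' Simulate a phantom image cohort
#'
#' Generates aligned T2 and ADC phantom volumes with a lesion mask per case
#' and, for PLNM-positive cases, one or two ellipsoidal node masks whose
#' short-axis diameter (middle principal axis) meets
#' `config$min_node_short_axis_mm`. Lesions have reduced ADC and
#' heterogeneous T2 texture (a Gaussian random field whose amplitude and
#' correlation length are case-level parameters); in positive cases lesion
#' and node texture parameters derive from a shared latent variable, so
#' extracted features exhibit cross-tissue correlation. Seed-deterministic.
#'
#' @param config a [sim_config()].
#' @param split which study split to generate (`"train"`, `"internal"`,
#'   `"external"`); sizes and prevalence come from `config`.
#' @return A `cohort`: list with `cases` (list of [bp_case()]) and `split`.
#' @export
simulate_cohort <- function(config, split = c("train", "internal", "external")) {
  stopifnot(inherits(config, "sim_config"))
  split <- match.arg(split)
  counts <- split_counts(config)
  row <- counts[counts$split == split, ]
  extent <- (config$vol_dim - 1) * config$spacing
  if (min(extent) < config$min_node_short_axis_mm + 4)
    stop_config("voxel grid too small to contain required node size: ",
                "need physical extent >= ", config$min_node_short_axis_mm + 4,
                " mm in every dimension")
  split_idx <- match(split, counts$split)
  cases <- withr::with_seed(derive_seed(config$seed, split_idx), {
    y <- c(rep(1L, row$n_pos), rep(0L, row$n_neg))
    lapply(seq_along(y), function(i) {
      simulate_case(sprintf("%s_%03d", split, i), y[i], config,
                    shared_latent = stats::rnorm(1))
    })
  })
  structure(list(cases = cases, split = split), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(x$cases, function(cs) cs$label, 0L)
  cat(sprintf("<cohort> %s: %d cases (%d PLNM-positive)\n", x$split,
              length(labs), sum(labs)))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cs in cohort$cases) {
    base <- file.path(dir, cs$id)
    write_volume(cs$t2, paste0(base, "_T2.nii.gz"))
    write_volume(cs$adc, paste0(base, "_ADC.nii.gz"))
    write_volume(cs$lesion_mask, paste0(base, "_lesion.nii.gz"),
                 datatype = "uint8")
    node_paths <- character(0)
    for (k in seq_along(cs$node_masks)) {
      pth <- paste0(base, sprintf("_node%d.nii.gz", k))
      write_volume(cs$node_masks[[k]], pth, datatype = "uint8")
      node_paths <- c(node_paths, basename(pth))
    }
    rows[[cs$id]] <- data.frame(
      case_id = cs$id, split = cohort$split, label = cs$label,
      t2 = basename(paste0(base, "_T2.nii.gz")),
      adc = basename(paste0(base, "_ADC.nii.gz")),
      lesion = basename(paste0(base, "_lesion.nii.gz")),
      nodes = paste(node_paths, collapse = ";"))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, unname(rows)), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV.
#' @return A `cohort`.
#' @export
read_cohort <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  cases <- lapply(seq_len(nrow(df)), function(i) {
    nd <- if (nzchar(df$nodes[i])) strsplit(df$nodes[i], ";")[[1]] else character(0)
    bp_case(id = df$case_id[i], label = df$label[i],
            t2 = read_volume(file.path(dir, df$t2[i]), "T2"),
            adc = read_volume(file.path(dir, df$adc[i]), "ADC"),
            lesion_mask = read_volume(file.path(dir, df$lesion[i]), "mask"),
            node_masks = lapply(nd, function(p)
              read_volume(file.path(dir, p), "mask")))
  })
  structure(list(cases = cases, split = df$split[1]), class = "cohort")
}
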