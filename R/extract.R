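# Assembly of the full radiomic feature vector per case: modality x VOI x
# filter-bank image x feature family, with canonical feature naming
# "<modality>_<tissue>_<image>_<class>_<feature>".

#' Extraction settings
#'
#' Bundles the extraction parameters. The defaults are the working settings
#' of the pipeline: bin width 25, intensity normalization to scale 100
#' (whole-image statistics), voxel-array shift of 300 for the energy-type
#' first-order features, a 10-voxel pad around each VOI's bounding box, and
#' resampling to 1 mm isotropic spacing.
#'
#' @param bin_width gray-level discretization bin width.
#' @param normalize_scale intensity normalization scale (standard deviation
#'   of the normalized image); `NULL` disables normalization.
#' @param normalize_masked use masked instead of whole-image statistics for
#'   normalization (default `FALSE`).
#' @param voxel_shift additive shift used by Energy/TotalEnergy/RMS.
#' @param pad bounding-box pad in voxels before filtering/cropping, so that
#'   filter supports do not truncate at the crop edge.
#' @param target_spacing isotropic resampling spacing in mm; `NULL` keeps the
#'   native grid.
#' @param gldm_alpha gray-level dependence tolerance.
#' @param node_policy how to aggregate features over multiple node masks:
#'   `"largest"` (default; the node with the largest voxel volume) or
#'   `"mean"` (average feature vectors over nodes).
#' @return An `extraction_settings` list.
#' @export
extraction_settings <- function(bin_width = 25, normalize_scale = 100,
                                normalize_masked = FALSE, voxel_shift = 300,
                                pad = 10, target_spacing = c(1, 1, 1),
                                gldm_alpha = 0,
                                node_policy = c("largest", "mean")) {
  node_policy <- match.arg(node_policy)
  structure(list(bin_width = bin_width, normalize_scale = normalize_scale,
                 normalize_masked = normalize_masked,
                 voxel_shift = voxel_shift, pad = pad,
                 target_spacing = target_spacing, gldm_alpha = gldm_alpha,
                 node_policy = node_policy),
            class = "extraction_settings")
}

#' Construct a patient case
#'
#' @param id case identifier (string).
#' @param label PLNM status: 1 = positive, 0 = negative.
#' @param t2 T2-weighted [image_volume()].
#' @param adc ADC [image_volume()] on the T2 grid (or resampled on use).
#' @param lesion_mask binary lesion mask ("VOI-1") on the T2 grid.
#' @param node_masks list of binary metastatic-node masks ("VOI-2");
#'   empty for negative cases.
#' @return A `bp_case` list.
#' @export
bp_case <- function(id, label, t2, adc, lesion_mask, node_masks = list()) {
  stopifnot(inherits(t2, "image_volume"), inherits(adc, "image_volume"))
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop_config("label must be 0 or 1")
  structure(list(id = as.character(id), label = label, t2 = t2, adc = adc,
                 lesion_mask = lesion_mask, node_masks = node_masks),
            class = "bp_case")
}

#' @export
print.bp_case <- function(x, ...) {
  cat(sprintf("<bp_case> %s: PLNM %s, %d node mask(s)\n", x$id,
              ifelse(x$label == 1, "positive", "negative"),
              length(x$node_masks)))
  invisible(x)
}

# Bounding-box crop of volume values and mask with pad, clipped to the grid.
crop_to_mask <- function(values, mask, pad) {
  d <- dim(values)
  idx <- arrayInd(which(mask > 0), d)
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, min(idx[, k]) - pad)
    hi <- min(d[k], max(idx[, k]) + pad)
    lo:hi
  })
  list(values = values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       mask = mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE])
}

texture_class_names <- c("glcm", "glrlm", "glszm", "ngtdm", "gldm")

# Features (first-order + 5 texture families) for one derived image. The
# mask neighbourhood context `ctx` is shared across the bank's images.
image_feature_block <- function(img_values, mask, spacing, settings,
                                ctx = NULL) {
  disc <- discretize(image_volume(img_values, spacing = spacing), mask,
                     bin_width = settings$bin_width)
  if (!is.null(ctx)) attr(disc, "mask_context") <- ctx
  fo <- first_order_features(image_volume(img_values, spacing = spacing), mask,
                             bin_width = settings$bin_width,
                             voxel_shift = settings$voxel_shift)
  blocks <- list(firstorder = fo,
                 glcm = glcm_features(disc),
                 glrlm = glrlm_features(disc),
                 glszm = glszm_features(disc),
                 ngtdm = ngtdm_features(disc),
                 gldm = gldm_features(disc, alpha = settings$gldm_alpha))
  out <- unlist(lapply(names(blocks), function(cl) {
    v <- blocks[[cl]]
    names(v) <- paste(cl, names(v), sep = "_")
    v
  }))
  out
}

resample_iso <- function(volume, spacing, interpolator) {
  if (is.null(spacing) || isTRUE(all.equal(volume$spacing, spacing)))
    return(volume)
  extent <- (dim(volume$values) - 1) * volume$spacing
  nd <- pmax(1L, as.integer(floor(extent / spacing)) + 1L)
  ref <- image_volume(array(0, dim = nd), spacing = spacing,
                      origin = volume$origin)
  resample_to_reference(volume, ref, interpolator = interpolator)
}

# Feature vector for a single (modality volume, mask) pair.
extract_modality_tissue <- function(volume, mask, settings, bank,
                                    modality, tissue) {
  mask_vol <- if (inherits(mask, "image_volume")) mask else
    image_volume(array(as.numeric(mask), dim(mask)), spacing = volume$spacing,
                 origin = volume$origin, modality = "mask")
  if (!is.null(settings$target_spacing)) {
    volume <- resample_iso(volume, settings$target_spacing, "bspline")
    mask_vol <- resample_iso(mask_vol, settings$target_spacing, "nearest")
  }
  m <- check_mask(mask_vol, volume)
  if (!is.null(settings$normalize_scale))
    volume <- normalize_intensity(volume,
                                  mask = if (settings$normalize_masked) m,
                                  scale = settings$normalize_scale)
  cr <- crop_to_mask(volume$values, m, settings$pad)
  base <- image_volume(cr$values, spacing = volume$spacing)
  images <- filter_bank(base, bank)
  shp <- shape_features(cr$mask, spacing = volume$spacing)
  names(shp) <- paste(modality, tissue, "original_shape", names(shp), sep = "_")
  ctx <- mask_context(cr$mask)
  blocks <- lapply(names(images), function(im) {
    b <- image_feature_block(images[[im]]$values, cr$mask, volume$spacing,
                             settings, ctx = ctx)
    names(b) <- paste(modality, tissue, im, names(b), sep = "_")
    b
  })
  c(shp, unlist(blocks))
}

#' Extract the full radiomic feature vector for one case and tissue
#'
#' Runs the whole per-VOI extraction: optional resampling to isotropic
#' spacing, intensity normalization, bounding-box crop (pad 10), the filter
#' bank, and all feature families per derived image, for both modalities
#' (T2 and ADC). With the full default bank this yields exactly
#' `2 x (14 + 93 + 19 x 93) = 3748` named features per VOI: per modality,
#' 14 shape features (original mask only) plus 18 first-order and 75 texture
#' features on the original and each of the 19 derived images.
#'
#' For `tissue = "node"` with several node masks the aggregation policy of
#' `settings$node_policy` applies (largest node by voxel volume, or the mean
#' feature vector over nodes).
#'
#' @param case a [bp_case()].
#' @param tissue `"tumor"` (lesion mask) or `"node"` (node masks).
#' @param bank a [bank_config()].
#' @param settings an [extraction_settings()].
#' @return Named numeric vector.
#' @export
extract_all <- function(case, tissue = c("tumor", "node"),
                        bank = bank_config(),
                        settings = extraction_settings()) {
  stopifnot(inherits(case, "bp_case"))
  tissue <- match.arg(tissue)
  if (is.null(case$t2) || is.null(case$adc))
    stop("case ", case$id, " is missing a modality volume (T2 and ADC required)")
  adc <- case$adc
  if (!identical(dim(adc$values), dim(case$t2$values)))
    adc <- resample_to_reference(adc, case$t2, "bspline")
  masks <- if (tissue == "tumor") list(case$lesion_mask) else case$node_masks
  if (tissue == "node" && length(masks) == 0L)
    stop("case ", case$id, " has no node masks")
  one_mask <- function(msk) {
    c(extract_modality_tissue(case$t2, msk, settings, bank, "T2", tissue),
      extract_modality_tissue(adc, msk, settings, bank, "ADC", tissue))
  }
  if (tissue == "tumor" || length(masks) == 1L) return(one_mask(masks[[1]]))
  if (settings$node_policy == "largest") {
    sizes <- vapply(masks, function(m)
      sum(if (inherits(m, "image_volume")) m$values else m), 0)
    return(one_mask(masks[[which.max(sizes)]]))
  }
  vecs <- lapply(masks, one_mask)
  Reduce(`+`, vecs) / length(vecs)
}

#' Extract feature tables for a whole cohort
#'
#' Lesion ("tumor") features for every case and node features for
#' PLNM-positive cases, as data frames with a `case_id` first column and
#' canonical feature names.
#'
#' @param cohort a `cohort` from [simulate_cohort()] or a list of
#'   [bp_case()]s.
#' @param bank a [bank_config()].
#' @param settings an [extraction_settings()].
#' @param verbose print per-case progress.
#' @return List with elements `lesion` (all cases), `node` (positive cases),
#'   and `labels` (data frame `case_id`, `label`).
#' @export
extract_cohort <- function(cohort, bank = bank_config(),
                           settings = extraction_settings(), verbose = FALSE) {
  cases <- if (inherits(cohort, "cohort")) cohort$cases else cohort
  lesion <- list()
  node <- list()
  labels <- data.frame(case_id = character(0), label = integer(0))
  for (cs in cases) {
    if (verbose) message("extracting case ", cs$id)
    lesion[[cs$id]] <- extract_all(cs, "tumor", bank, settings)
    if (cs$label == 1L && length(cs$node_masks) > 0L)
      node[[cs$id]] <- extract_all(cs, "node", bank, settings)
    labels <- rbind(labels, data.frame(case_id = cs$id, label = cs$label))
  }
  to_df <- function(lst, tissue) {
    if (length(lst) == 0L) return(NULL)
    m <- do.call(rbind, lst)
    df <- data.frame(case_id = names(lst), m, check.names = FALSE,
                     row.names = NULL)
    df
  }
  list(lesion = to_df(lesion, "tumor"), node = to_df(node, "node"),
       labels = labels)
}

#' Write / read a feature table as CSV
#'
#' First column `case_id`, remaining columns canonical feature names.
#'
#' @param table data frame as produced by [extract_cohort()] or
#'   [simulate_feature_tables()].
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
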