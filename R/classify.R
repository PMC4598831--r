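#' Train a random-forest pixel classifier
#'
#' Fits a 200-tree random forest with 4 candidate features per split on
#' sparsely annotated pixels (cell / non-cell), deterministic given `seed`.
#' The model is a probability forest; [classify_pixels()] thresholds the
#' tree-vote fraction at > 0.5 so an exact tie classifies as non-cell (false
#' positives pollute counts; false negatives are audited).
#'
#' @param features a `feature_stack` from [compute_pixel_features()].
#' @param labels a data frame with columns `index` (1-based linear voxel
#'   index into the stack) and `class` (1/`"cell"` or 0/`"non-cell"`); both
#'   classes must be present.
#' @param n_trees,features_per_split forest size and mtry; defaults 200 and 4.
#' @param parent_region optional label recording which parent region this
#'   model segments.
#' @param seed integer seed.
#' @return A `pixel_classifier`.
#' @export
train_pixel_classifier <- function(features, labels, n_trees = 200,
                                   features_per_split = 4,
                                   parent_region = NA_character_, seed = 1) {
  stopifnot(inherits(features, "feature_stack"))
  labels <- tibble::as_tibble(labels)
  cls <- as.character(labels$class)
  cls[cls %in% c("1", "TRUE")] <- "cell"
  cls[cls %in% c("0", "FALSE")] <- "non-cell"
  if (length(unique(cls)) < 2)
    stop("training labels contain a single class; both cell and non-cell ",
         "annotations are required", call. = FALSE)
  x <- features$values[labels$index, , drop = FALSE]
  fit <- ranger::ranger(
    x = x, y = factor(cls, levels = c("non-cell", "cell")),
    num.trees = n_trees, mtry = features_per_split,
    probability = TRUE, seed = as.integer(seed), num.threads = 1)
  structure(list(model = fit, feature_names = features$feature_names,
                 n_trees = n_trees, features_per_split = features_per_split,
                 parent_region = parent_region, seed = seed),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier> ", x$n_trees, " trees, ", x$features_per_split,
      " features/split", if (!is.na(x$parent_region))
        paste0(", parent ", x$parent_region), "\n", sep = "")
  invisible(x)
}

#' Classify every pixel of a volume as cell or non-cell
#'
#' Applies a trained classifier to a feature stack, producing a binary mask
#' on the source geometry: majority vote over trees, ties to non-cell.
#' Prediction is chunked over z-planes to bound memory.
#'
#' @param model a `pixel_classifier`.
#' @param features a `feature_stack` with the same feature layout the model
#'   was trained on.
#' @return A [binary_mask()].
#' @export
classify_pixels <- function(model, features) {
  stopifnot(inherits(model, "pixel_classifier"), inherits(features, "feature_stack"))
  if (!identical(model$feature_names, features$feature_names))
    stop("feature layout mismatch: model trained on [",
         paste(utils::head(model$feature_names, 3), collapse = ", "),
         ", ...] but stack provides [",
         paste(utils::head(features$feature_names, 3), collapse = ", "), ", ...]",
         call. = FALSE)
  n <- nrow(features$values)
  if (n == 0) return(binary_mask(array(integer(0), features$dims),
                                 features$spacing, features$origin))
  out <- integer(n)
  chunk <- max(1L, prod(features$dims[1:2]) * 8L)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(n, start + chunk - 1L)
    p <- stats::predict(model$model,
                        data = features$values[sel, , drop = FALSE],
                        num.threads = 1)$predictions
    out[sel] <- as.integer(p[, "cell"] > 0.5)
  }
  binary_mask(array(out, features$dims), features$spacing, features$origin)
}

#' Combine per-parent-region segmentations
#'
#' Each of the eight parent regions has its own classifier; only that model's
#' output counts inside its parent. `compose_parent_masks()` assembles one
#' mask in which every labeled voxel's call comes from exactly its parent's
#' model (background voxels are 0). `filter_centroids_by_parent()` applies
#' the same rule at centroid level (the pipeline's post-registration path):
#' centroids produced by model `p` survive only where the atlas parent at the
#' centroid is `p`; centroids in unlabeled background are dropped.
#'
#' @param masks named list of [binary_mask()]s, one per parent region, on the
#'   atlas geometry.
#' @param centroids_by_parent named list of `centroid_set`s, one per parent
#'   region model.
#' @param atlas a [brain_atlas()]; every parent with nonzero volume must have
#'   an entry.
#' @return A [binary_mask()], or a pooled `centroid_set`.
#' @export
compose_parent_masks <- function(masks, atlas) {
  pv <- parent_volume(atlas)
  parents <- setdiff(unique(as.vector(pv$values)), 0L)
  pnames <- levels(pv$parent_levels)[parents]
  missing_m <- setdiff(pnames, names(masks))
  if (length(missing_m))
    stop("no model/mask for parent region(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  out <- array(0L, dim(pv$values))
  for (p in pnames) {
    sel <- pv$values == match(p, levels(pv$parent_levels))
    out[sel] <- masks[[p]]$values[sel]
  }
  binary_mask(out, atlas$labels$spacing, atlas$labels$origin)
}

#' @rdname compose_parent_masks
#' @export
filter_centroids_by_parent <- function(centroids_by_parent, atlas) {
  pv <- parent_volume(atlas)
  present <- levels(pv$parent_levels)[setdiff(unique(as.vector(pv$values)), 0L)]
  missing_m <- setdiff(present, names(centroids_by_parent))
  if (length(missing_m))
    stop("no model output for parent region(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  kept <- purrr::imap(centroids_by_parent, function(pts, p) {
    if (!nrow(pts)) return(pts)
    at <- grid_value_at(pv, points_matrix(pts), outside = 0)
    pts[at == match(p, levels(pv$parent_levels)), , drop = FALSE]
  })
  as_centroid_set(dplyr::bind_rows(kept))
}

# label volume of parent-region codes (factor levels attached)
parent_volume <- function(atlas) {
  lev <- factor(atlas$regions$parent_region)
  lut <- integer(max(atlas$regions$region_id) + 1L) # index = label + 1
  lut[atlas$regions$region_id + 1L] <- as.integer(lev)
  v <- atlas$labels
  v$values <- array(lut[atlas$labels$values + 1L], dim(atlas$labels$values))
  v$parent_levels <- lev
  v
}
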