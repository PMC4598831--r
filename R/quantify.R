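#' Assign atlas regions to reference-space centroids
#'
#' Looks up the atlas label at each point's containing voxel (boundary rule:
#' the containing voxel's label decides). Points in unlabeled background or
#' outside the atlas bounding box get `region_id` 0, counted in the
#' `n_outside` attribute. Coronal splits declared in the region table (e.g.
#' anterior/posterior DS) are honoured.
#'
#' @param points a `centroid_set` with `space_tag == "reference"`.
#' @param atlas a [brain_atlas()].
#' @return The points with `region_id` and `region` columns; attribute
#'   `n_outside` counts points outside the atlas bounding box.
#' @export
assign_regions <- function(points, atlas) {
  if (any(points$space_tag != "reference"))
    stop("points must be in reference space before region assignment",
         call. = FALSE)
  atlas <- apply_coronal_splits(atlas)
  pm <- points_matrix(points)
  lab <- atlas$labels
  idx <- um_to_voxel(pm, lab)
  d <- dim(lab$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  rid <- rep(0L, nrow(points))
  if (any(inside))
    rid[inside] <- lab$values[idx[inside, , drop = FALSE]]
  out <- points
  out$region_id <- rid
  out$region <- c("background", atlas$regions$name)[
    match(rid, c(0L, atlas$regions$region_id))]
  attr(out, "n_outside") <- sum(!inside)
  attr(out, "atlas_split") <- atlas
  as_centroid_set(out)
}

#' Count input neurons per region and compute input percentages
#'
#' Counts assigned points per (brain, condition, region), including starter
#' regions, then computes each region's percent of inputs out of all labeled
#' neurons outside the starter-excluded regions: starter-region and
#' background rows carry counts but never enter a percent denominator, and
#' per brain the percents over non-starter regions sum to 100.
#'
#' @param points region-assigned points from [assign_regions()].
#' @param atlas a [brain_atlas()] (splits are applied to its region table).
#' @return A `region_count_table` tibble: `brain_id`, `condition`, `region`,
#'   `count`, `starter_excluded`, `percent` (NA for starter/background rows).
#' @export
count_by_region <- function(points, atlas) {
  if (!"region_id" %in% names(points))
    stop("points are not region-assigned; run assign_regions() first", call. = FALSE)
  atlas <- attr(points, "atlas_split") %||% apply_coronal_splits(atlas)
  regions <- atlas$regions
  counts <- points |>
    dplyr::count(.data$brain_id, .data$condition, .data$region_id, name = "count") |>
    # every named region appears for every brain, absent regions as 0
    tidyr::complete(
      tidyr::nesting(brain_id, condition),
      region_id = c(0L, regions$region_id), fill = list(count = 0L)) |>
    dplyr::mutate(
      region = c("background", regions$name)[
        match(.data$region_id, c(0L, regions$region_id))],
      starter_excluded = dplyr::coalesce(
        regions$starter_excluded[match(.data$region_id, regions$region_id)], FALSE))
  counts <- counts |>
    dplyr::group_by(.data$brain_id, .data$condition) |>
    dplyr::mutate(
      denom = sum(.data$count[!.data$starter_excluded & .data$region_id != 0L]),
      percent = dplyr::if_else(.data$starter_excluded | .data$region_id == 0L,
                               NA_real_, 100 * .data$count / .data$denom)) |>
    dplyr::ungroup()
  if (any(counts$denom == 0))
    stop("brain(s) with zero non-starter points: percents undefined for ",
         paste(unique(counts$brain_id[counts$denom == 0]), collapse = ", "),
         call. = FALSE)
  counts$denom <- NULL
  check_percent_sums(counts)
  structure(counts, class = c("region_count_table", class(counts)))
}

check_percent_sums <- function(table) {
  sums <- table |>
    dplyr::filter(!.data$starter_excluded, .data$region_id != 0L) |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::summarise(s = sum(.data$percent), .groups = "drop")
  stopifnot(all(abs(sums$s - 100) < 1e-9))
  invisible(table)
}

#' Per-condition input profiles (mean and s.e.m. across brains)
#'
#' Collapses a region-count table to per-condition, per-region mean percent
#' and standard error across brains (regions absent in a brain count as 0%,
#' which [count_by_region()] already guarantees). With a single brain the
#' s.e.m. is 0 by convention and flagged via `n_brains = 1`. Starter and
#' background rows are excluded.
#'
#' @param table a `region_count_table`.
#' @return A `condition_profiles` tibble: `condition`, `region`,
#'   `mean_percent`, `sem`, `n_brains`; attribute `replicates` holds the
#'   per-brain percent vectors (long tibble).
#' @export
build_condition_profiles <- function(table) {
  reps <- table |>
    dplyr::filter(!.data$starter_excluded, .data$region_id != 0L)
  prof <- reps |>
    dplyr::group_by(.data$condition, .data$region) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent),
      sem = if (dplyr::n() >= 2) stats::sd(.data$percent) / sqrt(dplyr::n()) else 0,
      n_brains = dplyr::n(), .groups = "drop")
  out <- structure(prof, class = c("condition_profiles", class(prof)))
  attr(out, "replicates") <- reps
  out
}

#' Subsample centroids for display
#'
#' Normalizes display density across conditions: draws `n_per_brain` points
#' without replacement from each of `n_brains` randomly chosen brains and
#' pools them (a brain with fewer points contributes all of them).
#' Deterministic given `seed`; never duplicates a point.
#'
#' @param points a pooled `centroid_set` (reference space).
#' @param n_per_brain points per brain, default 1500.
#' @param n_brains brains to pool, default 3.
#' @param seed integer seed.
#' @return A pooled `centroid_set`.
#' @export
subsample_for_display <- function(points, n_per_brain = 1500, n_brains = 3,
                                  seed = 1) {
  brains <- unique(points$brain_id)
  if (length(brains) == 0) stop("no brains to subsample", call. = FALSE)
  if (n_brains > length(brains))
    stop("requested ", n_brains, " brains but only ", length(brains),
         " available", call. = FALSE)
  with_seed(seed, {
    pick <- sample(brains, n_brains)
    pooled <- purrr::map(pick, function(b) {
      sub <- points[points$brain_id == b, , drop = FALSE]
      if (nrow(sub) > n_per_brain)
        sub <- sub[sample.int(nrow(sub), n_per_brain), , drop = FALSE]
      sub
    })
    as_centroid_set(dplyr::bind_rows(pooled))
  })
}

#' Chance fraction of a voxel subset
#'
#' The fraction of support voxels occupied by a region or voxel subset — the
#' "expected by chance" baseline for membership fractions. With
#' `support = "brain"` the support is all labeled, non-starter voxels; a
#' named region or group restricts the support (e.g. chance within the
#' nucleus accumbens).
#'
#' @param atlas a [brain_atlas()].
#' @param subset a region/group name (resolved by [region_group_ids()]) or a
#'   logical/integer array on the atlas grid (nonzero = member).
#' @param support `"brain"` or a region/group name.
#' @param clip_subset silently clip the subset to the support (default FALSE:
#'   a subset extending outside the support warns).
#' @return A fraction in `[0, 1]`.
#' @export
chance_fraction <- function(atlas, subset, support = "brain",
                            clip_subset = FALSE) {
  lab <- atlas$labels$values
  sup <- if (identical(support, "brain")) {
    lab != 0 & !(lab %in% starter_region_ids(atlas))
  } else {
    array(lab %in% region_group_ids(atlas, support), dim(lab))
  }
  if (!any(sup)) stop("empty support", call. = FALSE)
  sub <- if (is.character(subset)) {
    array(lab %in% region_group_ids(atlas, subset), dim(lab))
  } else {
    array(subset != 0, dim(lab))
  }
  if (!clip_subset && any(sub & !sup))
    warning("subset extends outside the support; fraction uses the overlap")
  sum(sub & sup) / sum(sup)
}
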