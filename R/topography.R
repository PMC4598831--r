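#' Section-wise center of mass of input positions
#'
#' Partitions the AP axis into contiguous coronal bins (default 400 um,
#' counted from the reference origin) and, per condition and bin, returns the
#' mean and s.e.m. of the in-plane (ML, DV) coordinates. Bins with no points
#' are absent; s.e.m. is `NA` for single-point bins.
#'
#' @param points a `centroid_set` in reference space.
#' @param bin_um coronal bin width, default 400.
#' @param origin_z_um AP origin of the binning, default 0.
#' @return A `com_series` tibble: `condition`, `bin`, `z_min_um`, `z_max_um`,
#'   `n`, `com_x_um`, `com_y_um`, `sem_x_um`, `sem_y_um`.
#' @export
center_of_mass_by_section <- function(points, bin_um = 400, origin_z_um = 0) {
  if (!nrow(points))
    return(structure(tibble::tibble(
      condition = character(0), bin = integer(0), z_min_um = numeric(0),
      z_max_um = numeric(0), n = integer(0), com_x_um = numeric(0),
      com_y_um = numeric(0), sem_x_um = numeric(0), sem_y_um = numeric(0)),
      class = c("com_series", "tbl_df", "tbl", "data.frame")))
  if (any(points$space_tag != "reference"))
    stop("points must be in reference space", call. = FALSE)
  out <- points |>
    dplyr::mutate(bin = floor((.data$z_um - origin_z_um) / bin_um)) |>
    dplyr::group_by(.data$condition, .data$bin) |>
    dplyr::summarise(
      z_min_um = origin_z_um + .data$bin[1] * bin_um,
      z_max_um = origin_z_um + (.data$bin[1] + 1) * bin_um,
      n = dplyr::n(),
      com_x_um = mean(.data$x_um), com_y_um = mean(.data$y_um),
      sem_x_um = if (dplyr::n() >= 2) sd(.data$x_um) / sqrt(dplyr::n()) else NA_real_,
      sem_y_um = if (dplyr::n() >= 2) sd(.data$y_um) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop")
  structure(out, class = c("com_series", class(out)))
}

#' Gaussian kernel density of pooled centroids on the reference grid
#'
#' Pools points (all neurons from all animals), histograms them on an
#' isotropic grid (default 20 um voxels) and convolves with a truncated
#' discrete 3D Gaussian. The 60-um "kernel size" is read as the FWHM by
#' default (sd = 60 / 2.355 ~ 25.5 um); set `kernel_is_fwhm = FALSE` to read
#' it as the sd. Total mass equals the point count up to boundary truncation.
#'
#' @param points a `centroid_set` in reference space.
#' @param geometry a [voxel_grid()] or [brain_atlas()] fixing the output
#'   grid's extent, or NULL to span the point cloud (plus a 3-kernel-sd pad).
#' @param voxel_um output voxel size, default 20.
#' @param kernel_um Gaussian kernel size, default 60.
#' @param kernel_is_fwhm interpret `kernel_um` as FWHM (default) or sd.
#' @return A `density_volume` (a [voxel_grid()]; attribute `n_points`).
#' @export
rasterize_density <- function(points, geometry = NULL, voxel_um = 20,
                              kernel_um = 60, kernel_is_fwhm = TRUE) {
  sd_um <- if (kernel_is_fwhm) kernel_um / (2 * sqrt(2 * log(2))) else kernel_um
  if (inherits(geometry, "brain_atlas")) geometry <- geometry$labels
  if (is.null(geometry)) {
    if (!nrow(points)) stop("cannot infer geometry from an empty point set",
                            call. = FALSE)
    pad <- 3 * sd_um
    pm <- points_matrix(points)
    org <- apply(pm, 2, min) - pad
    dims <- pmax(1, ceiling((apply(pm, 2, max) + pad - org) / voxel_um))
    geometry <- voxel_grid(array(0, dims), rep(voxel_um, 3), org)
  }
  d <- dim(geometry$values)
  spac <- rep_len(voxel_um, 3)
  grid <- voxel_grid(array(0, d), spac, geometry$origin)
  counts <- array(0, d)
  if (nrow(points)) {
    idx <- um_to_voxel(points_matrix(points), grid)
    inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    idx <- idx[inside, , drop = FALSE]
    if (nrow(idx)) {
      lin <- (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
      tab <- tabulate(lin, nbins = prod(d))
      counts <- array(tab, d)
    }
  }
  sig_vox <- sd_um / spac
  k1 <- lapply(sig_vox, function(s) gauss_kernel(s, 0))
  dens <- conv_sep3_cpp(counts, d, k1[[1]], k1[[2]], k1[[3]])
  out <- voxel_grid(dens, spac, grid$origin)
  class(out) <- c("density_volume", class(out))
  attr(out, "n_points") <- nrow(points)
  out
}

#' Detect density patches by local-maximum seeding and stepwise growth
#'
#' Seeds are 26-neighbourhood local maxima of the density (connected
#' equal-valued plateaus collapse to one seed), screened by a prominence
#' floor (`prominence_fraction` of the global maximum; raw local maxima on
#' smoothed point data are noise-dominated without it). Patches then grow in
#' synchronized one-voxel shells — expanding stepwise pixel-by-pixel — and a
#' voxel joins a patch iff its density is at least `stop_fraction` of that
#' patch's own peak (default reading; `stop_mode = "global"` stops at a
#' fraction of the global maximum instead) and no other patch has claimed it;
#' simultaneous claims go to the higher peak, then the lower patch id.
#' Deterministic.
#'
#' @param density a `density_volume` (nonnegative).
#' @param stop_fraction growth floor as a fraction of the peak, default 1/3.
#' @param prominence_fraction seed screen as a fraction of the global max,
#'   default 0.1.
#' @param stop_mode `"per_patch"` (default) or `"global"`.
#' @return A `patch_set`: tibble `patches` (`patch_id`, `peak_x_um`,
#'   `peak_y_um`, `peak_z_um`, `peak_density`, `n_vox`, `volume_um3`) plus
#'   attributes `labels` (label volume as [voxel_grid()]), `stop_fraction`,
#'   `prominence_fraction`, `stop_mode`.
#' @export
detect_patches <- function(density, stop_fraction = 1 / 3,
                           prominence_fraction = 0.1,
                           stop_mode = c("per_patch", "global")) {
  stop_mode <- match.arg(stop_mode)
  v <- density$values
  if (any(v < 0)) stop("density must be nonnegative", call. = FALSE)
  d <- dim(v)
  empty_patches <- tibble::tibble(
    patch_id = integer(0), peak_x_um = numeric(0), peak_y_um = numeric(0),
    peak_z_um = numeric(0), peak_density = numeric(0), n_vox = integer(0),
    volume_um3 = numeric(0))
  finish <- function(patches, labels) {
    out <- patches
    attr(out, "labels") <- voxel_grid(labels, density$spacing, density$origin)
    attr(out, "stop_fraction") <- stop_fraction
    attr(out, "prominence_fraction") <- prominence_fraction
    attr(out, "stop_mode") <- stop_mode
    class(out) <- c("patch_set", class(out))
    out
  }
  gmax <- max(v)
  if (gmax <= 0) return(finish(empty_patches, array(0L, d)))
  seeds <- local_maxima_cpp(v, d)
  seeds <- seeds[v[seeds] >= prominence_fraction * gmax]
  if (!length(seeds)) return(finish(empty_patches, array(0L, d)))
  peaks <- v[seeds]
  thr <- if (stop_mode == "per_patch") stop_fraction * peaks
  else rep(stop_fraction * gmax, length(seeds))
  lab <- grow_patches_cpp(v, d, as.integer(seeds), peaks, thr)
  idx <- cbind((seeds - 1L) %% d[1] + 1L,
               ((seeds - 1L) %/% d[1]) %% d[2] + 1L,
               (seeds - 1L) %/% (d[1] * d[2]) + 1L)
  pk_um <- voxel_to_um(idx, density)
  nvox <- tabulate(lab[lab > 0], nbins = length(seeds))
  patches <- tibble::tibble(
    patch_id = seq_along(seeds),
    peak_x_um = pk_um[, 1], peak_y_um = pk_um[, 2], peak_z_um = pk_um[, 3],
    peak_density = peaks, n_vox = nvox,
    volume_um3 = nvox * prod(density$spacing))
  finish(patches, array(lab, d))
}

#' Detect ventral patches from a pooled cohort
#'
#' The ventral-patch recipe: pool all (region-assigned) neurons from all
#' animals, keep those inside the enclosing region group (the ventral
#' striatum), estimate density on the atlas grid, and segment patches with
#' [detect_patches()]. Restricting the density to the enclosing region keeps
#' hot-spots of *ventral* input density from competing with unrelated dense
#' regions elsewhere in the brain, and the higher default prominence floor
#' (0.3 of the peak) sits above the uniform in-region background density, so
#' seeds are genuine hot-spots rather than counting noise.
#'
#' @param points region-assigned points (all brains pooled).
#' @param atlas a [brain_atlas()].
#' @param enclosing_region region-group name, default `"VS"`.
#' @param prominence_fraction seed floor, default 0.3.
#' @param ... passed to [detect_patches()].
#' @inheritParams rasterize_density
#' @return A `patch_set` (see [detect_patches()]).
#' @export
detect_ventral_patches <- function(points, atlas, enclosing_region = "VS",
                                   prominence_fraction = 0.3,
                                   kernel_um = 60, kernel_is_fwhm = TRUE, ...) {
  if (!"region_id" %in% names(points))
    stop("points are not region-assigned; run assign_regions() first", call. = FALSE)
  ids <- region_group_ids(atlas, enclosing_region)
  inside <- points[points$region_id %in% ids, , drop = FALSE]
  dens <- rasterize_density(inside, atlas, voxel_um = atlas$labels$spacing[1],
                            kernel_um = kernel_um,
                            kernel_is_fwhm = kernel_is_fwhm)
  detect_patches(dens, prominence_fraction = prominence_fraction, ...)
}

#' @export
glance.patch_set <- function(x, ...) {
  tibble::tibble(n_patches = nrow(x),
                 total_volume_um3 = sum(x$volume_um3),
                 max_peak_density = if (nrow(x)) max(x$peak_density) else NA_real_)
}

#' Write a patch set as a label volume plus JSON summary
#'
#' @param patches a `patch_set`.
#' @param label_path NIfTI path for the patch label volume.
#' @param summary_path JSON path for peaks/volumes/settings.
#' @return `label_path`, invisibly.
#' @export
write_patches <- function(patches, label_path, summary_path) {
  g <- attr(patches, "labels")
  g$values <- g$values + 0
  write_volume(g, label_path)
  jsonlite::write_json(
    list(patches = tibble::as_tibble(patches),
         stop_fraction = attr(patches, "stop_fraction"),
         prominence_fraction = attr(patches, "prominence_fraction"),
         stop_mode = attr(patches, "stop_mode")),
    summary_path, auto_unbox = FALSE, digits = NA)
  invisible(label_path)
}

#' Patch membership fractions per condition
#'
#' For each condition: the fraction of its (non-starter) input neurons inside
#' the enclosing region group (e.g. the ventral striatum), the fraction of
#' those in-region neurons lying inside any patch, per-patch shares (summing
#' to 1 over in-patch points), and the chance baselines from
#' [chance_fraction()] with supports `"brain"` and the enclosing region.
#' Membership is by containing voxel. Conditions with zero in-region points
#' report `NA` fractions, not 0.
#'
#' @param points region-assigned points (reference space, all conditions).
#' @param patches a `patch_set` on the atlas grid.
#' @param atlas a [brain_atlas()].
#' @param enclosing_region region-group name, default `"VS"`.
#' @return A list of tibbles: `fractions` (per condition) and `shares`
#'   (per condition x patch), plus `chance_brain` and `chance_region`
#'   baselines.
#' @export
patch_membership_fractions <- function(points, patches, atlas,
                                       enclosing_region = "VS") {
  ids <- region_group_ids(atlas, enclosing_region)
  lab_grid <- attr(patches, "labels")
  # audit (not enforce) patch containment in the enclosing region
  in_reg_vox <- array(atlas$labels$values %in% ids, dim(atlas$labels$values))
  n_outside <- sum(lab_grid$values > 0 & !in_reg_vox)
  starter <- starter_region_ids(atlas)
  pts <- points[points$region_id != 0 & !(points$region_id %in% starter), ,
                drop = FALSE]
  pts$in_region <- pts$region_id %in% ids
  pts$patch <- as.integer(grid_value_at(lab_grid, points_matrix(pts), outside = 0))
  fractions <- pts |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_in_region = mean(.data$in_region),
      n_in_region = sum(.data$in_region),
      frac_in_patches = if (sum(.data$in_region) > 0)
        sum(.data$patch > 0 & .data$in_region) / sum(.data$in_region)
      else NA_real_,
      .groups = "drop")
  shares <- pts |>
    dplyr::filter(.data$patch > 0) |>
    dplyr::count(.data$condition, .data$patch, name = "n_in_patch") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(share = .data$n_in_patch / sum(.data$n_in_patch)) |>
    dplyr::ungroup()
  list(fractions = fractions, shares = shares,
       chance_brain = chance_fraction(atlas, enclosing_region, "brain"),
       chance_region = chance_fraction(atlas, array(lab_grid$values > 0,
                                                    dim(lab_grid$values)),
                                       enclosing_region, clip_subset = TRUE),
       n_patch_voxels_outside_region = n_outside)
}
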