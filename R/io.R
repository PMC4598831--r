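#' Read and write 3D volumes
#'
#' Volumes are exchanged as NIfTI (`.nii`/`.nii.gz`, spacing carried in the
#' header) or as multi-page grayscale TIFF stacks (one page per z-plane) with
#' a JSON sidecar `<path>.json` holding `spacing` and `origin`. Spacing is
#' never guessed: a TIFF without a sidecar needs `spacing_override`.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param spacing_override optional length-3 spacing (um) taking precedence
#'   over file metadata.
#' @param grid a [voxel_grid()] to write.
#' @return `read_volume()` returns a [voxel_grid()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    v <- array(as.numeric(img), dim = dim(img)) # plain array, no NIfTI attrs
    if (length(dim(v)) != 3L)
      stop("expected a 3-dimensional volume, got ", length(dim(v)),
           " dimensions in ", path, call. = FALSE)
    spac <- spacing_override %||% (RNifti::pixdim(img) * 1000) # NIfTI mm -> um
    org <- attr(img, "origin_um") %||% c(0, 0, 0)
    voxel_grid(v, spacing = spac, origin = org)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2L)
      stop("expected grayscale 2D pages; got ", length(dim(pages[[1]])),
           "-dimensional page data in ", path, call. = FALSE)
    if (length(pages) < 2L && is.null(spacing_override) && !file.exists(paste0(path, ".json")))
      stop("single-page TIFF is 2-dimensional; a 3D stack is required", call. = FALSE)
    # pages were written as x-by-y matrices by write_volume
    v <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1]]), length(pages)))
    side <- paste0(path, ".json")
    meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
    spac <- spacing_override %||% meta$spacing
    if (is.null(spac))
      stop("no voxel spacing: TIFF has no sidecar ", basename(side),
           " and no spacing_override was given", call. = FALSE)
    voxel_grid(v, spacing = spac, origin = meta$origin %||% c(0, 0, 0))
  } else stop("unsupported volume format: .", ext, call. = FALSE)
}

#' @rdname read_volume
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(grid$values)
    RNifti::pixdim(img) <- grid$spacing / 1000 # um -> NIfTI mm
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    v <- grid$values
    lo <- min(v); hi <- max(v)
    if (lo < 0 || hi > 1)
      stop("TIFF output stores values in [0, 1]; rescale first or use NIfTI",
           call. = FALSE)
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(spacing = grid$spacing, origin = grid$origin),
                         paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  invisible(path)
}

centroid_cols <- c("x_um", "y_um", "z_um", "brain_id", "condition", "space_tag")

#' Read and write centroid tables
#'
#' Detected-cell centroids travel as tidy CSV with columns exactly
#' `x_um,y_um,z_um,brain_id,condition,space_tag[,region_id]`. One row is one
#' cell; a "centroid set" in this package is the sub-tibble of one
#' `(brain_id, condition)` pair, and pooling across brains is only meaningful
#' once `space_tag == "reference"`. Row order within a brain is preserved.
#'
#' @param path CSV path.
#' @param points a centroid tibble with the columns above.
#' @return `read_centroids()` returns a tibble of class `centroid_set`.
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(centroid_cols, names(df))
  if (length(miss))
    stop("centroid CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um) | !is.finite(df$z_um))
  if (length(bad))
    stop("non-finite coordinate at row ", bad[1], " of ", path, call. = FALSE)
  as_centroid_set(df)
}

#' @rdname read_centroids
#' @export
write_centroids <- function(points, path) {
  keep <- intersect(c(centroid_cols, "region_id"), names(points))
  readr::write_csv(points[, keep], path, progress = FALSE)
  invisible(path)
}

as_centroid_set <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("centroid_set", class(df))
  df
}

#' Construct a centroid set
#'
#' @param xyz n x 3 matrix of positions (um).
#' @param brain_id,condition,space_tag annotations (recycled).
#' @return A `centroid_set` tibble.
#' @export
centroid_set <- function(xyz, brain_id = "b1", condition = "cond",
                         space_tag = c("native", "reference")) {
  space_tag <- match.arg(space_tag)
  xyz <- rbind_mat(xyz)
  if (nrow(xyz) && any(!is.finite(xyz))) stop("all points must be finite", call. = FALSE)
  as_centroid_set(tibble::tibble(
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    brain_id = rep_len(brain_id, nrow(xyz)),
    condition = rep_len(condition, nrow(xyz)),
    space_tag = rep_len(space_tag, nrow(xyz))))
}

points_matrix <- function(points) cbind(points$x_um, points$y_um, points$z_um)

#' Read and write atlases
#'
#' The label volume is NIfTI; the region table (plus region groups) is JSON.
#' Reading validates the atlas invariants: every nonzero label present in the
#' volume must appear in the table.
#'
#' @param label_path NIfTI path of the integer label volume.
#' @param regions_path JSON path of the region table.
#' @param atlas a [brain_atlas()] to write.
#' @return `read_atlas()` returns a validated [brain_atlas()].
#' @export
read_atlas <- function(label_path, regions_path) {
  lab <- read_volume(label_path)
  lab$values <- round(lab$values)
  storage.mode(lab$values) <- "integer"
  meta <- jsonlite::read_json(regions_path, simplifyVector = TRUE)
  regions <- tibble::as_tibble(meta$regions)
  groups <- lapply(meta$groups %||% list(), unlist)
  brain_atlas(lab, regions, groups)
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, label_path, regions_path) {
  g <- atlas$labels
  g$values <- g$values + 0 # integer -> double for NIfTI
  write_volume(g, label_path)
  jsonlite::write_json(list(regions = atlas$regions, groups = atlas$groups),
                       regions_path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(label_path)
}

#' Run configuration
#'
#' One object holding the seed plus every stage parameter, with defaults equal
#' to the acquisition/analysis constants the pipeline is built around:
#' 1.04 x 1.04 x 5.25 um acquisition voxels, 20 um reference spacing, feature
#' radii (0.7, 1.6, 5) px, 200-tree / mtry-4 forest, component filters
#' (2.5-50 um diameter, 2 consecutive slices, circularity > 0.1), 32 MI bins,
#' 400-um coronal bins, 60-um density kernel, 1/3 patch stop fraction, and the
#' configurable starter-exclusion list (the A10rv carve-out is honoured by
#' editing `starter_regions`). Round-trips losslessly through YAML.
#'
#' @param ... overrides of the defaults.
#' @param path YAML path.
#' @param config a `run_config` to write.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    acquisition_spacing_um = c(1.04, 1.04, 5.25),
    reference_spacing_um = 20,
    feature_radii_px = c(0.7, 1.6, 5),
    rf_trees = 200L,
    rf_features_per_split = 4L,
    filter_d_min_um = 2.5,
    filter_d_max_um = 50,
    filter_min_z_slices = 2L,
    filter_circ_min = 0.1,
    mi_bins = 32L,
    register_levels = 3L,
    com_bin_um = 400,
    density_voxel_um = 20,
    density_kernel_um = 60,
    density_kernel_is_fwhm = TRUE,
    patch_stop_fraction = 1 / 3,
    patch_stop_mode = "per_patch",
    patch_prominence_fraction = 0.1,
    subsample_n_per_brain = 1500L,
    subsample_n_brains = 3L,
    bregma_z_um = 0,
    ds_split_bregma_mm = -0.9,
    starter_regions = c("VTA", "SNc", "SNr", "RRF")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
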