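#' Labeled atlas: region volume plus region table
#'
#' An atlas couples a 3D integer label volume (0 = background) on a
#' [voxel_grid()] geometry with a region table and optional declarative
#' region groups (e.g. `VS = c("VS_core", "VS_medial_shell", "VS_lateral_shell")`
#' for hierarchy roll-ups). Every nonzero label in the volume must have a row
#' in the table; `starter_excluded` flags regions around dopamine cell bodies
#' (VTA/SNc/SNr/RRF analogues) whose counts are dropped from every
#' input-percentage denominator. A region may carry `coronal_split_um`, a
#' reference-space z (um) at which it is split into anterior/posterior
#' sub-regions (the anterior DS / posterior DS split at Bregma -0.9 mm).
#'
#' @param labels a [voxel_grid()] whose values are integer region labels.
#' @param regions a data frame with columns `region_id`, `name`,
#'   `parent_region`, `starter_excluded` and optionally `coronal_split_um`.
#' @param groups optional named list of character vectors of region names.
#' @return An object of class `brain_atlas`.
#' @export
brain_atlas <- function(labels, regions, groups = list()) {
  stopifnot(inherits(labels, "voxel_grid"))
  v <- labels$values
  if (any(v != round(v))) stop("label volume must be integer-valued", call. = FALSE)
  storage.mode(labels$values) <- "integer"
  regions <- tibble::as_tibble(regions)
  need <- c("region_id", "name", "parent_region", "starter_excluded")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stop("region table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"coronal_split_um" %in% names(regions)) regions$coronal_split_um <- NA_real_
  if (anyDuplicated(regions$region_id)) stop("region_ids must be unique", call. = FALSE)
  present <- setdiff(unique(as.integer(labels$values)), 0L)
  unknown <- setdiff(present, regions$region_id)
  if (length(unknown))
    stop("unknown label ", paste(unknown, collapse = ", "),
         " present in volume but absent from region table", call. = FALSE)
  structure(list(labels = labels, regions = regions, groups = groups),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat("<brain_atlas> ", nrow(x$regions), " regions on ",
      paste(dim(x$labels$values), collapse = " x "), " grid (",
      sum(x$regions$starter_excluded), " starter-excluded)\n", sep = "")
  invisible(x)
}

starter_region_ids <- function(atlas)
  atlas$regions$region_id[atlas$regions$starter_excluded]

region_id_of <- function(atlas, names) {
  id <- atlas$regions$region_id[match(names, atlas$regions$name)]
  if (anyNA(id)) stop("unknown region name(s): ",
                      paste(names[is.na(id)], collapse = ", "), call. = FALSE)
  id
}

#' Resolve a region group to region ids
#'
#' A group name from `atlas$groups`, a region name, or a vector of region
#' names all resolve to the matching region ids.
#'
#' @param atlas a [brain_atlas()].
#' @param group a group name, region name, or character vector of region names.
#' @return Integer vector of region ids.
#' @export
region_group_ids <- function(atlas, group) {
  if (length(group) == 1 && group %in% names(atlas$groups))
    group <- atlas$groups[[group]]
  region_id_of(atlas, group)
}

#' Materialize coronal splits of atlas regions
#'
#' Regions with a non-missing `coronal_split_um` are replaced by two regions,
#' `<name>_anterior` (voxel centres with z strictly anterior to the plane) and
#' `<name>_posterior`, inheriting the parent and starter flag. Used to split
#' the dorsal striatum into an anterior DS and a posterior (tail) DS at a
#' configured Bregma plane.
#'
#' @param atlas a [brain_atlas()].
#' @return A [brain_atlas()] with splits applied (unchanged if none defined).
#' @export
apply_coronal_splits <- function(atlas) {
  rs <- atlas$regions
  todo <- which(!is.na(rs$coronal_split_um))
  if (!length(todo)) return(atlas)
  lab <- atlas$labels
  next_id <- max(rs$region_id) + 1L
  zs <- voxel_to_um(cbind(1, 1, seq_len(dim(lab$values)[3])), lab)[, 3]
  for (i in todo) {
    rid <- rs$region_id[i]
    split_z <- rs$coronal_split_um[i]
    post_id <- next_id; next_id <- next_id + 1L
    post_planes <- which(zs >= split_z)
    if (length(post_planes)) {
      sub <- lab$values[, , post_planes, drop = FALSE]
      sub[sub == rid] <- post_id
      lab$values[, , post_planes] <- sub
    }
    base <- rs[i, ]
    rs$name[i] <- paste0(base$name, "_anterior")
    rs$coronal_split_um[i] <- NA_real_
    post_row <- base
    post_row$region_id <- post_id
    post_row$name <- paste0(base$name, "_posterior")
    post_row$coronal_split_um <- NA_real_
    rs <- dplyr::bind_rows(rs, post_row)
    # keep group memberships pointing at both halves
    atlas$groups <- lapply(atlas$groups, function(g)
      if (base$name %in% g) c(setdiff(g, base$name), rs$name[i], post_row$name) else g)
  }
  brain_atlas(lab, rs, atlas$groups)
}

#' Convert a Bregma coordinate to reference-space z
#'
#' The reference AP axis (z) increases posteriorly; Bregma itself sits at a
#' configurable reference z. `Bregma -0.9 mm` is 900 um posterior to that
#' offset.
#'
#' @param bregma_mm Bregma coordinate in mm (negative = posterior).
#' @param bregma_z_um reference-space z of Bregma, in um.
#' @return Reference-space z in um.
#' @export
bregma_to_z_um <- function(bregma_mm, bregma_z_um = 0) {
  bregma_z_um - bregma_mm * 1000
}
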