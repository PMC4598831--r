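#' Extract 3D connected components and their centroids
#'
#' Collapses all 26-connected sets of cell pixels into components (each cell
#' is present at multiple z positions, so collapse is 3D) and measures, per
#' component: voxel count, physical volume, intensity-unweighted centroid
#' (mean of voxel centres, um), the longest run of consecutive occupied
#' z-planes, and — on the component's maximum-area z-slice — area and
#' perimeter. The perimeter estimator is the exposed-edge count: the number
#' of 4-neighbour pixel edges between component and non-component pixels,
#' times the pixel size (a 1 x n line of pixels has perimeter `2n + 2`
#' pixel edges).
#'
#' @param mask a [binary_mask()].
#' @return A tibble with one row per component (columns `component_id`,
#'   `n_vox`, `volume_um3`, `x_um`, `y_um`, `z_um`, `diameter_um`, `z_span`,
#'   `max_slice_area_um2`, `max_slice_perimeter_um`, `circularity`), with the
#'   label volume as attribute `labels`. An empty mask gives zero rows.
#' @export
extract_components <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"))
  d <- dim(mask$values)
  sp <- mask$spacing
  lab <- label_components_cpp(mask$values != 0, d)
  idx <- which(lab != 0)
  empty <- tibble::tibble(component_id = integer(0), n_vox = integer(0),
                          volume_um3 = numeric(0), x_um = numeric(0),
                          y_um = numeric(0), z_um = numeric(0),
                          diameter_um = numeric(0), z_span = integer(0),
                          max_slice_area_um2 = numeric(0),
                          max_slice_perimeter_um = numeric(0),
                          circularity = numeric(0))
  if (!length(idx)) {
    attr(empty, "labels") <- lab
    return(empty)
  }
  ids <- lab[idx]
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  by_id <- split(seq_along(idx), ids)
  vox_vol <- prod(sp)
  rows <- purrr::map(by_id, function(sel) {
    ii <- i[sel]; jj <- j[sel]; kk <- k[sel]
    n <- length(sel)
    ctr <- c(mean(ii - 0.5) * sp[1], mean(jj - 0.5) * sp[2],
             mean(kk - 0.5) * sp[3]) + mask$origin
    zs <- sort(unique(kk))
    runs <- split(zs, cumsum(c(1L, diff(zs) != 1L)))
    z_span <- max(lengths(runs))
    areas <- table(kk)
    kmax <- as.integer(names(areas)[which.max(areas)])
    in_slice <- kk == kmax
    si <- ii[in_slice]; sj <- jj[in_slice]
    occ <- matrix(FALSE, max(si) - min(si) + 3L, max(sj) - min(sj) + 3L)
    occ[cbind(si - min(si) + 2L, sj - min(sj) + 2L)] <- TRUE
    edges <- sum(occ & !rbind(occ[-1, ], FALSE)) +
      sum(occ & !rbind(FALSE, occ[-nrow(occ), ])) +
      sum(occ & !cbind(occ[, -1], FALSE)) +
      sum(occ & !cbind(FALSE, occ[, -ncol(occ)]))
    area <- sum(in_slice) * sp[1] * sp[2]
    perim <- edges * mean(sp[1:2])
    vol <- n * vox_vol
    tibble::tibble(
      n_vox = n, volume_um3 = vol,
      x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
      diameter_um = 2 * (3 * vol / (4 * pi))^(1 / 3),
      z_span = z_span,
      max_slice_area_um2 = area, max_slice_perimeter_um = perim,
      circularity = 4 * pi * area / perim^2)
  })
  out <- dplyr::bind_rows(rows, .id = "component_id")
  out$component_id <- as.integer(out$component_id)
  out <- dplyr::arrange(out, .data$component_id)
  attr(out, "labels") <- lab
  out
}

#' Filter components by size, slice consecutiveness and shape
#'
#' Keeps a component iff its equivalent-sphere diameter lies in
#' `[d_min, d_max]`, it spans at least `min_z_slices` consecutive z-planes,
#' and its circularity `4*pi*A/P^2` (maximum-area slice) exceeds `circ_min`
#' — noise reduction by requiring a reasonable diameter range, presence in
#' consecutive images, and a reasonable shape. Survivor centroids are
#' returned as a centroid set; an audit table records which rule(s) each
#' rejected component failed.
#'
#' @param components the tibble from [extract_components()].
#' @param d_min_um,d_max_um diameter bounds (um), defaults 2.5 and 50.
#' @param min_z_slices minimum consecutive z-planes, default 2.
#' @param circ_min circularity floor, default 0.1 (strict inequality).
#' @param brain_id,condition annotations for the resulting centroid set.
#' @return A `centroid_set` of surviving centroids (space tag `"native"`),
#'   with attribute `audit`: per-component pass/fail flags.
#' @export
filter_components <- function(components, d_min_um = 2.5, d_max_um = 50,
                              min_z_slices = 2, circ_min = 0.1,
                              brain_id = "b1", condition = "cond") {
  audit <- tibble::tibble(
    component_id = components$component_id,
    fail_diameter = components$diameter_um < d_min_um |
      components$diameter_um > d_max_um,
    fail_z_span = components$z_span < min_z_slices,
    fail_circularity = !(components$circularity > circ_min))
  keep <- !(audit$fail_diameter | audit$fail_z_span | audit$fail_circularity)
  audit$kept <- keep
  out <- centroid_set(cbind(components$x_um, components$y_um,
                            components$z_um)[keep, , drop = FALSE],
                      brain_id = brain_id, condition = condition,
                      space_tag = "native")
  attr(out, "audit") <- audit
  out
}

#' Detect cells in a volume with a trained classifier
#'
#' Convenience chain: features, pixel classification, 3D component collapse,
#' and the standard filters.
#'
#' @param grid a [voxel_grid()].
#' @param model a `pixel_classifier`.
#' @param radii feature radii (px).
#' @param ... passed to [filter_components()].
#' @return A `centroid_set` (attributes `audit` and `mask`).
#' @export
detect_cells <- function(grid, model, radii = c(0.7, 1.6, 5), ...) {
  fs <- compute_pixel_features(grid, radii)
  mask <- classify_pixels(model, fs)
  comp <- extract_components(mask)
  out <- filter_components(comp, ...)
  attr(out, "mask") <- mask
  out
}
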