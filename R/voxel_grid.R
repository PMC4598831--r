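#' 3D intensity raster with physical geometry
#'
#' A `voxel_grid` is the carrier for images, masks and density volumes: a 3D
#' numeric array plus a physical voxel spacing and origin, all in micrometres.
#' Axis order is fixed as (x = medio-lateral, y = dorso-ventral,
#' z = antero-posterior, increasing posteriorly). The physical position of the
#' *centre* of 0-based voxel `(i, j, k)` is `origin + (c(i, j, k) + 0.5) * spacing`
#' (half-voxel centre convention); R's 1-based indices are converted
#' internally. All point/voxel conversions in the package go through
#' [voxel_to_um()] and [um_to_voxel()].
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, micrometres per voxel along (x, y, z);
#'   all components must be positive.
#' @param origin numeric length-3, physical position (um) of the grid corner.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(1.04, 1.04, 5.25))
#' dim(g$values)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("voxel_grid values must be 3-dimensional, got ", length(dim(values)),
         " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers", call. = FALSE)
  if (any(dim(values) <= 0)) stop("all grid dimensions must be positive", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") um, origin (", paste(signif(x$origin, 4), collapse = ", "), ") um\n",
      sep = "")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

grid_extent_um <- function(grid) dim(grid$values) * grid$spacing

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Convert voxel indices to physical coordinates and back
#'
#' `voxel_to_um()` maps 1-based voxel indices to the physical (um) position of
#' the voxel centre; `um_to_voxel()` maps physical points to the 1-based index
#' of the containing voxel. These two functions are the only place the
#' half-voxel centre convention lives.
#'
#' @param idx integer matrix (n x 3) or vector of 1-based voxel indices.
#' @param pts numeric matrix (n x 3) or vector of physical points (um).
#' @param grid a [voxel_grid()] (an atlas label grid works too).
#' @return A numeric (or integer) n x 3 matrix.
#' @export
voxel_to_um <- function(idx, grid) {
  idx <- rbind_mat(idx)
  sweep(sweep(idx - 0.5, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' @rdname voxel_to_um
#' @export
um_to_voxel <- function(pts, grid) {
  pts <- rbind_mat(pts)
  idx <- floor(sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`)) + 1
  storage.mode(idx) <- "integer"
  idx
}

rbind_mat <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

# label (or value) lookup at physical points; outside the grid -> `outside`
grid_value_at <- function(grid, pts, outside = 0) {
  idx <- um_to_voxel(pts, grid)
  d <- dim(grid$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(idx))
  if (any(inside))
    out[inside] <- grid$values[cbind(idx[inside, 1], idx[inside, 2], idx[inside, 3])]
  out
}

#' Binary mask on a voxel grid
#'
#' Wraps a 0/1 volume on the same geometry as its source grid; every pixel is
#' classified as 1 (cell) or 0 (non-cell).
#'
#' @param values 3D array coercible to 0/1.
#' @inheritParams voxel_grid
#' @return A `binary_mask` (also a `voxel_grid`).
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  v <- as.array(values)
  if (!all(v %in% c(0, 1, NA)))
    stop("binary_mask values must be 0 or 1", call. = FALSE)
  storage.mode(v) <- "integer"
  g <- voxel_grid(v, spacing, origin)
  class(g) <- c("binary_mask", class(g))
  g
}

#' Block-average downsampling to a coarser reference grid
#'
#' Averages input voxels into output bins so the output spacing matches a
#' target, as when stitched acquisitions are downsized to the 20-um reference
#' grid. Per axis, the number of output samples is `round(extent / target)`
#' and each input voxel is averaged into the bin containing its centre, so the
#' physical extent is preserved exactly (a 14,000-um stitched field at a 20-um
#' target gives 700 samples of exactly 20 um).
#'
#' @param grid a [voxel_grid()].
#' @param target_spacing target spacing in um (scalar or length 3), default 20.
#' @return A coarser [voxel_grid()].
#' @export
downsample_to_reference_grid <- function(grid, target_spacing = 20) {
  target <- rep_len(as.numeric(target_spacing), 3)
  if (any(target < grid$spacing - 1e-9))
    stop("target spacing ", paste(target, collapse = ","),
         " is finer than source spacing; upsampling is not supported", call. = FALSE)
  d <- dim(grid$values)
  extent <- d * grid$spacing
  nd <- pmax(1L, as.integer(round(extent / target)))
  v <- grid$values
  binmean_axis <- function(a, axis, nin, nout) {
    if (nout == nin) return(a)
    da <- dim(a)
    # bin of each input voxel centre
    grp <- pmin(nout, floor((seq_len(nin) - 0.5) * nout / nin) + 1L)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = da[axis])
    ms <- rowsum(m, grp, reorder = TRUE)
    cnt <- as.vector(rowsum(rep(1, nin), grp, reorder = TRUE))
    ms <- ms / cnt
    out <- array(ms, dim = c(nout, da[setdiff(1:3, axis)]))
    aperm(out, order(perm))
  }
  for (ax in 1:3) v <- binmean_axis(v, ax, d[ax], nd[ax])
  voxel_grid(v, spacing = extent / nd, origin = grid$origin)
}
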