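#' Mutual information between two volumes
#'
#' Shannon mutual information (nats) of the joint intensity histogram, with
#' `bins` equal-width bins spanning each image's own min-max range. Always
#' >= 0; `mutual_information(x, x)` equals the entropy of x's marginal
#' histogram.
#'
#' @param a,b [voxel_grid()]s on identical geometry.
#' @param bins histogram bins per image, default 32.
#' @return MI in nats.
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (!same_geometry(a, b))
    stop("volumes must share geometry for mutual information", call. = FALSE)
  mi_raw(as.vector(a$values), as.vector(b$values), bins)
}

bin_index <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(1L, length(x)))
  pmin(bins, floor((x - lo) / (hi - lo) * bins) + 1L)
}

mi_raw <- function(x, y, bins = 32) {
  bx <- bin_index(x, bins); by <- bin_index(y, bins)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / length(x)
  jm <- matrix(joint, bins, bins)
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log(jm[nz] / (px[row(jm)[nz]] * py[col(jm)[nz]])))
}

resample_to <- function(moving, reference, tform, fill = NULL) {
  inv <- invert_affine(tform)
  fill <- fill %||% min(moving$values)
  v <- affine_resample_cpp(moving$values, dim(moving$values), moving$spacing,
                           moving$origin, dim(reference$values),
                           reference$spacing, reference$origin,
                           inv$A, inv$t, fill)
  voxel_grid(v, reference$spacing, reference$origin)
}

#' Affine registration by mutual-information maximization
#'
#' Estimates the native-to-reference affine transform (12 parameters:
#' translation, rotation, log-scale, shear) that maximizes the mutual
#' information between the resampled moving volume and the reference, by
#' coarse-to-fine Nelder-Mead over a 3-level block-averaged pyramid with
#' seeded multi-start at the coarsest level. Rotation is taken about the
#' volume centre. Deterministic given `seed`.
#'
#' @param moving,reference [voxel_grid()]s on comparable physical scales.
#' @param levels pyramid levels, default 3 (downsampling factors 4, 2, 1).
#' @param bins MI histogram bins, default 32.
#' @param n_starts random restarts at the coarsest level, default 8.
#' @param max_shift_um translation magnitude (um) of the random starts;
#'   default 12 reference voxels.
#' @param seed integer seed.
#' @return An [affine_transform()] with attributes `mi` (final MI) and
#'   `converged`.
#' @export
register_affine <- function(moving, reference, levels = 3, bins = 32,
                            n_starts = 8, max_shift_um = NULL, seed = 1) {
  ctr <- reference$origin + grid_extent_um(reference) / 2
  max_shift <- max_shift_um %||% (12 * max(reference$spacing))
  # parameter vector: shift (units of 10 um), rot deg, 100*log-scale, 100*shear
  par_to_tform <- function(p) {
    t0 <- affine_from_params(shift_um = p[1:3] * 10, rot_deg = p[4:6],
                             scale = exp(p[7:9] / 100), shear = p[10:12] / 100)
    # recentre: rotate/scale about the reference centre
    affine_transform(t0$A, t0$t + ctr - as.vector(t0$A %*% ctr))
  }
  pyramid <- function(g, f) if (f == 1) g else
    downsample_to_reference_grid(g, target_spacing = g$spacing * f)
  # the objective binds per-level constants (reference bin indices, moving
  # range) and evaluates resampling + joint histogram + MI in one fused call
  make_objective <- function(mv, rf, stride = 1L) {
    ref_bin <- bin_index(as.vector(rf$values), bins)
    mlo <- min(mv$values); mhi <- max(mv$values)
    function(p) {
      tf <- try(par_to_tform(p), silent = TRUE)
      if (inherits(tf, "try-error")) return(1e6)
      inv <- invert_affine(tf)
      -mi_affine_cpp(mv$values, dim(mv$values), mv$spacing, mv$origin,
                     dim(rf$values), rf$spacing, rf$origin, inv$A, inv$t,
                     mlo, ref_bin, mlo, mhi, as.integer(bins),
                     as.integer(stride))
    }
  }
  factors <- rev(2^(seq_len(levels) - 1))  # e.g. 4, 2, 1
  # sanity: volumes must overlap at initialization
  olo <- pmax(moving$origin, reference$origin)
  ohi <- pmin(moving$origin + grid_extent_um(moving),
              reference$origin + grid_extent_um(reference))
  if (any(ohi <= olo))
    stop("moving and reference volumes do not overlap physically: moving ",
         "extent [", paste(signif(grid_extent_um(moving), 4), collapse = ","),
         "] um vs reference [",
         paste(signif(grid_extent_um(reference), 4), collapse = ","), "] um",
         call. = FALSE)
  best <- NULL
  with_seed(seed, {
    obj <- make_objective(pyramid(moving, factors[1]),
                          pyramid(reference, factors[1]))
    starts <- c(list(rep(0, 12)), lapply(seq_len(n_starts), function(i) {
      c(runif(3, -max_shift, max_shift) / 10, runif(3, -9, 9), rep(0, 6))
    }))
    fits <- lapply(starts, function(p0)
      stats::optim(p0, obj, method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-8)))
    ranked <- order(vapply(fits, `[[`, 0, "value"))
    # carry the three best coarse optima into the mid level, then keep one
    f2 <- factors[min(2, length(factors))]
    obj2 <- make_objective(pyramid(moving, f2), pyramid(reference, f2))
    refits <- lapply(fits[ranked[seq_len(min(3, length(ranked)))]], function(ft)
      stats::optim(ft$par, obj2, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-8)))
    best <- refits[[which.min(vapply(refits, `[[`, 0, "value"))]]
    # Nelder-Mead restart (fresh simplex) at the mid level: 12-parameter
    # simplexes collapse before converging; a restart recovers polish cheaply
    best <- stats::optim(best$par, obj2, method = "Nelder-Mead",
                         control = list(maxit = 300, reltol = 1e-9))
    for (f in factors[-seq_len(min(2, length(factors)))]) {
      # finest level: every-other-voxel sampling — the deterministic sample
      # set keeps the objective smooth while quartering the histogram cost
      objf <- make_objective(pyramid(moving, f), pyramid(reference, f),
                             stride = 2L)
      best <- stats::optim(best$par, objf, method = "Nelder-Mead",
                           control = list(maxit = 250, reltol = 1e-8))
      best <- stats::optim(best$par, objf, method = "Nelder-Mead",
                           control = list(maxit = 150, reltol = 1e-8))
    }
  })
  out <- par_to_tform(best$par)
  attr(out, "mi") <- -best$value
  attr(out, "converged") <- best$convergence == 0
  out
}

#' Average registered volumes into a reference template
#'
#' Voxelwise mean of volumes already on the reference geometry (the synthetic
#' stand-in for an averaged multi-brain reference space).
#'
#' @param grids list of [voxel_grid()]s with identical geometry.
#' @return A [voxel_grid()].
#' @export
average_reference <- function(grids) {
  stopifnot(length(grids) >= 1)
  g1 <- grids[[1]]
  for (g in grids[-1]) if (!same_geometry(g1, g))
    stop("all volumes must share geometry", call. = FALSE)
  acc <- Reduce(`+`, lapply(grids, `[[`, "values"))
  voxel_grid(acc / length(grids), g1$spacing, g1$origin)
}

#' Deformation field on the reference grid
#'
#' Per-voxel displacement vectors (um) on a reference-geometry grid; this
#' package does not fit deformable registrations — a field produced
#' externally (e.g. by a B-spline registration) is accepted as input and
#' applied after the affine.
#'
#' @param dx,dy,dz 3D arrays of displacement components (um).
#' @param spacing,origin reference geometry.
#' @return A `deformation_field`.
#' @export
deformation_field <- function(dx, dy, dz, spacing, origin = c(0, 0, 0)) {
  stopifnot(identical(dim(dx), dim(dy)), identical(dim(dx), dim(dz)))
  if (any(!is.finite(dx)) || any(!is.finite(dy)) || any(!is.finite(dz)))
    stop("deformation field must be finite everywhere", call. = FALSE)
  structure(list(dx = voxel_grid(dx, spacing, origin),
                 dy = voxel_grid(dy, spacing, origin),
                 dz = voxel_grid(dz, spacing, origin)),
            class = "deformation_field")
}

# vectorized trilinear interpolation of one component at physical points;
# outside the grid support -> NA
interp_component <- function(grid, pts) {
  d <- dim(grid$values)
  cc <- sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`) - 0.5
  i0 <- floor(cc)
  fr <- cc - i0
  ok <- i0[, 1] >= 0 & i0[, 1] < d[1] - 1 &
    i0[, 2] >= 0 & i0[, 2] < d[2] - 1 &
    i0[, 3] >= 0 & i0[, 3] < d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1 # to 1-based corner
  fr <- fr[ok, , drop = FALSE]
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * grid$values[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

#' Map centroids from native to reference space
#'
#' Applies the affine, then (optionally) a trilinear-interpolated deformation
#' field, and sets `space_tag` to `"reference"`. Points that leave the
#' deformation-field support are dropped (default policy) with an audit
#' count, or clamped to their affine position.
#'
#' @param points a `centroid_set` in native space.
#' @param tform an [affine_transform()].
#' @param field optional `deformation_field`.
#' @param outside `"drop"` (default) or `"clamp"`.
#' @return A `centroid_set` in reference space; attribute `n_dropped` counts
#'   audited drops.
#' @export
transform_points <- function(points, tform, field = NULL,
                             outside = c("drop", "clamp")) {
  outside <- match.arg(outside)
  if (any(points$space_tag != "native"))
    stop("points must be in native space", call. = FALSE)
  xyz <- apply_affine_mat(tform, points_matrix(points))
  n_dropped <- 0L
  if (!is.null(field) && nrow(xyz)) {
    disp <- cbind(interp_component(field$dx, xyz),
                  interp_component(field$dy, xyz),
                  interp_component(field$dz, xyz))
    bad <- !stats::complete.cases(disp)
    if (outside == "drop") {
      n_dropped <- sum(bad)
      keep <- !bad
      xyz <- (xyz + ifelse(is.na(disp), 0, disp))[keep, , drop = FALSE]
      points <- points[keep, , drop = FALSE]
    } else {
      disp[is.na(disp)] <- 0
      xyz <- xyz + disp
    }
  }
  out <- points
  out$x_um <- xyz[, 1]; out$y_um <- xyz[, 2]; out$z_um <- xyz[, 3]
  out$space_tag <- "reference"
  attr(out, "n_dropped") <- n_dropped
  as_centroid_set(out)
}
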