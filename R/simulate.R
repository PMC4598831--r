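#' Optics specification for simulated light-sheet volumes
#'
#' Defaults mirror the acquisition geometry the pipeline is built around:
#' ~1.04 um in-plane pixels and a 5.25 um z step (so voxels are not quite
#' isotropic). Cells are rendered as Gaussian-blurred spheres: soma-only
#' granularity, not full morphologies.
#'
#' @param spacing_um voxel spacing (x, y, z) in um.
#' @param radius_range_um cell radius drawn uniformly from this range
#'   (default 5-7.5 um, i.e. 10-15 um somata, which span at least two 5.25-um
#'   z-steps); support must lie in (0, 50].
#' @param peak cell intensity above background before blurring.
#' @param background constant background level.
#' @param noise_sd additive Gaussian noise sd (0 = off).
#' @param poisson_scale if non-NULL, intensities are Poisson-resampled at this
#'   photon scale (counts = `rpois(v * scale) / scale`).
#' @param blur_sd_um isotropic optical blur sd in um.
#' @return An `optics_spec` list.
#' @export
optics_spec <- function(spacing_um = c(1.04, 1.04, 5.25),
                        radius_range_um = c(5, 7.5),
                        peak = 1, background = 0.1,
                        noise_sd = 0.05, poisson_scale = NULL,
                        blur_sd_um = 2) {
  r <- sort(as.numeric(radius_range_um))
  if (r[1] <= 0 || r[2] > 50)
    stop("cell radius support must lie in (0, 50] um", call. = FALSE)
  structure(list(spacing_um = rep_len(as.numeric(spacing_um), 3),
                 radius_range_um = r, peak = peak, background = background,
                 noise_sd = noise_sd, poisson_scale = poisson_scale,
                 blur_sd_um = blur_sd_um),
            class = "optics_spec")
}

# radial profile of a unit ball of radius R convolved with an isotropic
# Gaussian of sd sigma, evaluated at distance d from the centre (value 1 at
# the centre of a large ball)
blurred_ball_profile <- function(d, R, sigma) {
  if (sigma <= 0) return(as.numeric(d <= R))
  s2 <- sigma * sqrt(2)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  small <- d < 1e-9
  d2 <- ifelse(small, 1e-9, d)
  out <- 0.5 * (erf((R + d2) / s2) + erf((R - d2) / s2)) -
    sigma / (d2 * sqrt(2 * pi)) *
    (exp(-(R - d2)^2 / (2 * sigma^2)) - exp(-(R + d2)^2 / (2 * sigma^2)))
  centre <- erf(R / s2) - R * sqrt(2 / pi) / sigma * exp(-R^2 / (2 * sigma^2))
  ifelse(small, centre, out)
}

#' Simulate a light-sheet volume with planted cells
#'
#' Places `n_cells` sphere centres with a minimum pairwise separation
#' (default twice the maximum radius), renders each as a blurred sphere
#' (closed-form radial profile of a ball convolved with a Gaussian) on a
#' constant background, and adds noise. Returns the volume together with the
#' exact planted centres as ground truth. Deterministic given `seed`.
#'
#' @param n_cells number of cells to plant (>= 0).
#' @param optics an [optics_spec()].
#' @param dims volume shape in voxels, default `c(256, 256, 64)`.
#' @param atlas optional [brain_atlas()]; when supplied, cell centres are
#'   restricted to positions whose atlas label is nonzero (geometries must
#'   overlap physically).
#' @param min_separation_um minimum centre separation; the default,
#'   `2 * max(radius_range_um) + 4 * blur_sd_um`, keeps the blurred masks of
#'   neighbouring cells disjoint (rabies labeling is sparse; splitting
#'   touching cells is out of scope).
#' @param seed integer seed.
#' @return A list with `volume` (a [voxel_grid()]) and `truth` (a tibble of
#'   centres and radii, also a `centroid_set`).
#' @export
simulate_brain_volume <- function(n_cells, optics = optics_spec(),
                                  dims = c(256, 256, 64), atlas = NULL,
                                  min_separation_um = NULL, seed = NULL) {
  stopifnot(n_cells >= 0)
  dims <- as.integer(rep_len(dims, 3))
  spacing <- optics$spacing_um
  extent <- dims * spacing
  rmax <- optics$radius_range_um[2]
  minsep <- min_separation_um %||% (2 * rmax + 4 * optics$blur_sd_um)
  margin <- rmax + 3 * optics$blur_sd_um
  with_seed(seed, {
    centres <- matrix(numeric(0), 0, 3)
    if (n_cells > 0) {
      tries <- 0L; max_tries <- 200L * n_cells
      while (nrow(centres) < n_cells) {
        if (tries >= max_tries)
          stop("could not place ", n_cells, " cells at separation >= ",
               signif(minsep, 3), " um after ", max_tries, " attempts",
               call. = FALSE)
        tries <- tries + 1L
        cand <- runif(3, margin, extent - margin)
        if (!is.null(atlas) && grid_value_at(atlas$labels, cand) == 0) next
        if (nrow(centres) == 0 ||
            min(sqrt(colSums((t(centres) - cand)^2))) >= minsep)
          centres <- rbind(centres, cand)
      }
    }
    radii <- if (n_cells > 0)
      runif(n_cells, optics$radius_range_um[1], optics$radius_range_um[2])
    else numeric(0)
    v <- array(optics$background, dims)
    if (n_cells > 0) {
      win <- ceiling((rmax + 4 * optics$blur_sd_um) / spacing)
      for (c_i in seq_len(n_cells)) {
        ctr <- centres[c_i, ]
        cvox <- um_to_voxel(ctr, voxel_grid(v, spacing))[1, ]
        lo <- pmax(1L, cvox - win); hi <- pmin(dims, cvox + win)
        ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
        xs <- (ii - 0.5) * spacing[1] - ctr[1]
        ys <- (jj - 0.5) * spacing[2] - ctr[2]
        zs <- (kk - 0.5) * spacing[3] - ctr[3]
        d <- sqrt(outer(outer(xs^2, ys^2, `+`), zs^2, `+`))
        v[ii, jj, kk] <- v[ii, jj, kk] +
          optics$peak * blurred_ball_profile(d, radii[c_i], optics$blur_sd_um)
      }
    }
    if (!is.null(optics$poisson_scale))
      v <- array(rpois(length(v), pmax(v, 0) * optics$poisson_scale) /
                   optics$poisson_scale, dims)
    if (optics$noise_sd > 0)
      v <- v + array(rnorm(length(v), 0, optics$noise_sd), dims)
  })
  truth <- centroid_set(centres, brain_id = "sim", condition = "sim")
  truth$radius_um <- radii
  list(volume = voxel_grid(v, spacing), truth = truth)
}

#' Ground-truth voxel mask and training labels for a simulated volume
#'
#' `ground_truth_mask()` marks every voxel whose centre lies within a planted
#' cell's radius (the hard sphere, before optical blur). `truth_training_labels()`
#' draws sparse pixel annotations the way a human annotator would: `n_cell`
#' pixels from clear cell interiors (within `core_margin_um` inside the
#' radius) and `n_non` pixels from clear background (at least
#' `bg_margin_um` outside any radius), leaving the ambiguous blurred shell
#' unlabeled — so the learned boundary lands in the shell, at or just outside
#' the true radius.
#'
#' @param sim result of [simulate_brain_volume()].
#' @param core_margin_um interior margin for cell labels, default 1.
#' @param bg_margin_um exclusion margin for background labels, default 2.
#' @param n_cell,n_non label counts.
#' @param seed integer seed.
#' @return `ground_truth_mask()`: a [binary_mask()]; `truth_training_labels()`:
#'   a tibble with `index` and `class` usable by [train_pixel_classifier()].
#' @export
ground_truth_mask <- function(sim, core_margin_um = 0) {
  grid <- sim$volume
  d <- dim(grid$values)
  m <- array(0L, d)
  tr <- sim$truth
  for (r in seq_len(nrow(tr))) {
    ctr <- c(tr$x_um[r], tr$y_um[r], tr$z_um[r])
    rad <- tr$radius_um[r] - core_margin_um
    if (rad <= 0) next
    lo <- pmax(1L, um_to_voxel(ctr - rad - 1, grid)[1, ])
    hi <- pmin(d, um_to_voxel(ctr + rad + 1, grid)[1, ])
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    xs <- (ii - 0.5) * grid$spacing[1] - ctr[1]
    ys <- (jj - 0.5) * grid$spacing[2] - ctr[2]
    zs <- (kk - 0.5) * grid$spacing[3] - ctr[3]
    dist <- sqrt(outer(outer(xs^2, ys^2, `+`), zs^2, `+`))
    m[ii, jj, kk] <- pmax(m[ii, jj, kk], as.integer(dist <= rad))
  }
  binary_mask(m, grid$spacing, grid$origin)
}

#' @rdname ground_truth_mask
#' @export
truth_training_labels <- function(sim, n_cell = 2000, n_non = 6000,
                                  core_margin_um = 1, bg_margin_um = 2,
                                  seed = 1) {
  core <- ground_truth_mask(sim, core_margin_um = core_margin_um)
  dilated <- ground_truth_mask(sim, core_margin_um = -bg_margin_um)
  cell_pool <- which(core$values == 1L)
  bg_pool <- which(dilated$values == 0L)
  with_seed(seed, tibble::tibble(
    index = c(sample(cell_pool, min(n_cell, length(cell_pool))),
              sample(bg_pool, min(n_non, length(bg_pool)))),
    class = rep(c("cell", "non-cell"),
                c(min(n_cell, length(cell_pool)),
                  min(n_non, length(bg_pool))))))
}

#' Cohort specification for multi-brain, multi-condition simulation
#'
#' Defines the statistical structure of a simulated tracing cohort: per
#' condition, the expected fraction of (non-starter) input neurons per region;
#' per brain, counts are multinomial around Dirichlet-jittered proportions.
#' Optional per-brain uniform draws move one region's proportion within a
#' range with the difference absorbed by a sink region (used to vary the
#' ventral-striatum fraction between brains), and `patch_spec` plants
#' truncated-Gaussian hot-spots inside designated regions.
#'
#' @param conditions character vector of condition labels.
#' @param n_brains brains per condition.
#' @param n_points points (labeled neurons) per brain; scalar or
#'   `c(lo, hi)` range sampled per brain.
#' @param props named list (one per condition) of named numeric vectors of
#'   region proportions over non-starter regions; each must sum to 1 (1e-9).
#' @param kappa Dirichlet concentration for between-brain proportion jitter;
#'   `Inf` disables it.
#' @param brain_draws optional tibble with columns
#'   `condition, region, sink, lo, hi`: that brain's `region` proportion is
#'   drawn uniformly in `[lo, hi]`, compensated in `sink`.
#' @param patch_spec optional tibble with columns
#'   `region, x_um, y_um, z_um, sd_um` and one weight column per condition
#'   named `w_<condition>` (all weights in `[0, 1]`; per region they are the
#'   probability that a point of that region comes from that patch's
#'   truncated Gaussian).
#' @param scatter_sd_um sd of a per-brain rigid jitter applied to all points.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(conditions, n_brains, n_points, props,
                        kappa = Inf, brain_draws = NULL, patch_spec = NULL,
                        scatter_sd_um = 0) {
  stopifnot(length(conditions) >= 1, n_brains >= 1)
  if (!all(conditions %in% names(props)))
    stop("props must name every condition", call. = FALSE)
  for (cn in conditions) {
    s <- sum(props[[cn]])
    if (abs(s - 1) > 1e-9)
      stop("proportions for condition ", cn, " sum to ", s, ", not 1", call. = FALSE)
  }
  if (!is.null(patch_spec)) {
    wcols <- grep("^w_", names(patch_spec), value = TRUE)
    w <- unlist(patch_spec[wcols])
    if (any(w < 0 | w > 1)) stop("patch weights must lie in [0, 1]", call. = FALSE)
  }
  structure(list(conditions = conditions, n_brains = as.integer(n_brains),
                 n_points = n_points, props = props, kappa = kappa,
                 brain_draws = brain_draws, patch_spec = patch_spec,
                 scatter_sd_um = scatter_sd_um),
            class = "cohort_spec")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-12))
  g / sum(g)
}

#' Simulate a centroid cohort on an atlas
#'
#' Per brain: proportions are the condition's, modified by any per-brain
#' draws, then Dirichlet-jittered; region counts are multinomial (counts sum
#' to the brain's point count exactly); within a region, points are uniform
#' over region voxels except in patch regions, where the configured weight of
#' points comes from truncated Gaussians at the patch centres. Points are
#' generated directly in reference space. Deterministic given `seed`.
#'
#' @param atlas a [brain_atlas()]; every region named in the spec must exist
#'   and have at least one voxel.
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A `centroid_set` tibble (all brains, with `from_patch` ground-truth
#'   column) with attribute `truth`: a tibble of the per-brain realized
#'   proportions and counts per region.
#' @export
simulate_centroid_cohort <- function(atlas, spec, seed = NULL) {
  all_regions <- unique(unlist(lapply(spec$props, names)))
  rid <- region_id_of(atlas, all_regions) # errors on unknown regions
  for (i in seq_along(all_regions))
    if (!any(atlas$labels$values == rid[i]))
      stop("region ", all_regions[i], " has zero voxels", call. = FALSE)
  patch <- spec$patch_spec
  out <- vector("list", length(spec$conditions) * spec$n_brains)
  truth <- vector("list", length(out))
  seeds <- child_seeds(seed, length(out))
  n_i <- 0L
  for (cond in spec$conditions) {
    p_cond <- spec$props[[cond]]
    for (b in seq_len(spec$n_brains)) {
      n_i <- n_i + 1L
      brain <- sprintf("%s_b%d", cond, b)
      res <- with_seed(seeds[[n_i]], {
        p <- p_cond
        bd <- spec$brain_draws
        if (!is.null(bd)) {
          bd_c <- bd[bd$condition == cond, , drop = FALSE]
          for (r in seq_len(nrow(bd_c))) {
            drawn <- runif(1, bd_c$lo[r], bd_c$hi[r])
            delta <- drawn - p[[bd_c$region[r]]]
            p[[bd_c$region[r]]] <- drawn
            p[[bd_c$sink[r]]] <- p[[bd_c$sink[r]]] - delta
          }
        }
        if (is.finite(spec$kappa)) p <- setNames(rdirichlet1(spec$kappa * p), names(p))
        n_pts <- if (length(spec$n_points) == 2)
          sample(spec$n_points[1]:spec$n_points[2], 1) else spec$n_points
        counts <- as.vector(rmultinom(1, n_pts, p))
        names(counts) <- names(p)
        pts <- vector("list", length(counts))
        fp <- vector("list", length(counts))
        for (ri in seq_along(counts)) {
          nr <- counts[ri]
          if (nr == 0) { pts[[ri]] <- matrix(0, 0, 3); fp[[ri]] <- integer(0); next }
          rname <- names(counts)[ri]
          r_id <- region_id_of(atlas, rname)
          prow <- if (!is.null(patch)) which(patch$region == rname) else integer(0)
          if (length(prow)) {
            wts <- vapply(prow, function(k) patch[[paste0("w_", cond)]][k], 0)
            src <- sample.int(length(prow) + 1L, nr, replace = TRUE,
                              prob = c(wts, max(0, 1 - sum(wts))))
            xy <- matrix(NA_real_, nr, 3)
            unif <- src == length(prow) + 1L
            if (any(unif)) xy[unif, ] <- sample_in_region(atlas, r_id, sum(unif))
            for (k in seq_along(prow)) {
              sel <- which(src == k)
              if (!length(sel)) next
              ctr <- c(patch$x_um[prow[k]], patch$y_um[prow[k]], patch$z_um[prow[k]])
              sd_p <- patch$sd_um[prow[k]]
              got <- 0L
              while (got < length(sel)) {
                cand <- matrix(rnorm(3 * 4 * (length(sel) - got), 0, sd_p),
                               ncol = 3, byrow = TRUE)
                cand <- sweep(cand, 2, ctr, `+`)
                keep <- grid_value_at(atlas$labels, cand) == r_id
                cand <- cand[keep, , drop = FALSE]
                take <- min(nrow(cand), length(sel) - got)
                if (take > 0) {
                  xy[sel[(got + 1):(got + take)], ] <- cand[seq_len(take), , drop = FALSE]
                  got <- got + take
                }
              }
            }
            pts[[ri]] <- xy
            fp[[ri]] <- ifelse(src <= length(prow), prow[pmin(src, length(prow))], NA_integer_)
          } else {
            pts[[ri]] <- sample_in_region(atlas, r_id, nr)
            fp[[ri]] <- rep(NA_integer_, nr)
          }
        }
        xyz <- do.call(rbind, pts)
        if (spec$scatter_sd_um > 0)
          xyz <- sweep(xyz, 2, rnorm(3, 0, spec$scatter_sd_um), `+`)
        cs <- centroid_set(xyz, brain_id = brain, condition = cond,
                           space_tag = "reference")
        cs$from_patch <- unlist(fp)
        list(points = cs,
             truth = tibble::tibble(brain_id = brain, condition = cond,
                                    region = names(counts), prob = unname(p),
                                    count = unname(counts)))
      })
      out[[n_i]] <- res$points
      truth[[n_i]] <- res$truth
    }
  }
  pts <- as_centroid_set(dplyr::bind_rows(out))
  attr(pts, "truth") <- dplyr::bind_rows(truth)
  pts
}

#' Paper-like default cohort specification
#'
#' Eight conditions (VS, DS, TS, GP, Amy, OFC, mPFC, lHb; 4 brains x 5,000
#' points each by default). The seven canonical conditions share one
#' proportion profile in which each brain's total ventral-striatum fraction is
#' drawn uniformly in [0.12, 0.20] (the draw moves the medial-shell analogue,
#' compensated in cortex, so it acts as between-brain variability rather than
#' a between-condition difference). The TS-like outlier condition has a fixed
#' VS fraction of 0.05 with the deficit moved to elevated GP/STh/ZI — so the
#' planted differential regions are exactly the VS medial shell, GP, STh and
#' ZI analogues. Five density hot-spots (3 in the medial shell, 1 in the
#' core, 1 in the lateral shell) receive ~21% of each canonical condition's
#' VS points; the TS-like condition has patch weight 0.
#'
#' @param atlas a [brain_atlas()] from [make_toy_atlas()] (default layout).
#' @param n_brains brains per condition, default 4.
#' @param n_points points per brain, default 5000.
#' @param kappa Dirichlet between-brain concentration, default 2000.
#' @param patch_sd_um patch Gaussian sd, default 50 um.
#' @param seed seed for deterministic patch-centre placement.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(atlas, n_brains = 4, n_points = 5000,
                                kappa = 2000, patch_sd_um = 50, seed = 1) {
  canonical <- c(cortex = 0.38, VS_core = 0.02, VS_medial_shell = 0.12,
                 VS_lateral_shell = 0.02, DS = 0.12, TS = 0.04, GP = 0.04,
                 EP = 0.02, STh = 0.03, ZI = 0.04, LH = 0.04, OT = 0.03,
                 DR = 0.02, Amy = 0.06, lHb = 0.02)
  stopifnot(abs(sum(canonical) - 1) < 1e-12)
  ts <- canonical
  ts["VS_medial_shell"] <- 0.01   # VS total 0.05
  ts["GP"] <- 0.08; ts["STh"] <- 0.06; ts["ZI"] <- 0.08
  stopifnot(abs(sum(ts) - 1) < 1e-12)
  conds <- c("VS", "DS", "TS", "GP", "Amy", "OFC", "mPFC", "lHb")
  props <- setNames(lapply(conds, function(cn)
    if (cn == "TS") ts else canonical), conds)
  draws <- tidyr::expand_grid(condition = setdiff(conds, "TS")) |>
    dplyr::mutate(region = "VS_medial_shell", sink = "cortex",
                  lo = 0.08, hi = 0.16)
  centres <- rbind(
    place_patch_centers(atlas, "VS_medial_shell", 3, patch_sd_um, seed),
    place_patch_centers(atlas, "VS_core", 1, patch_sd_um, seed + 1),
    place_patch_centers(atlas, "VS_lateral_shell", 1, patch_sd_um, seed + 2))
  patch <- tibble::tibble(
    region = c(rep("VS_medial_shell", 3), "VS_core", "VS_lateral_shell"),
    x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
    sd_um = patch_sd_um)
  for (cn in conds) {
    patch[[paste0("w_", cn)]] <- if (cn == "TS") 0 else
      c(0.08, 0.07, 0.06, 0.21, 0.21)
  }
  cohort_spec(conds, n_brains = n_brains, n_points = n_points, props = props,
              kappa = kappa, brain_draws = draws, patch_spec = patch)
}

#' Place patch centres inside a region
#'
#' Seeded sampling of `k` region voxel centres with pairwise separation of at
#' least `4 * sd_um` where the region allows it (best effort after bounded
#' retries).
#'
#' @param atlas a [brain_atlas()].
#' @param region region name.
#' @param k number of centres.
#' @param sd_um patch sd used to derive the separation target.
#' @param seed integer seed.
#' @return A `k` x 3 matrix of positions (um).
#' @export
place_patch_centers <- function(atlas, region, k, sd_um, seed = 1) {
  r_id <- region_id_of(atlas, region)
  with_seed(seed, {
    best <- NULL; best_sep <- -Inf
    for (try in 1:200) {
      cand <- sample_in_region(atlas, r_id, k)
      sep <- if (k == 1) Inf else min(stats::dist(cand))
      if (sep > best_sep) { best <- cand; best_sep <- sep }
      if (best_sep >= 4 * sd_um) break
    }
    best
  })
}

#' Apply a random misalignment to a grid or point set
#'
#' Draws an affine transform with per-axis uniform shift, rotation and
#' relative scale of the given magnitudes, applies it, and returns both the
#' transformed object and the exact transform used (mapping original
#' coordinates to transformed coordinates) — the registration fixture.
#'
#' @param x a [voxel_grid()] or a `centroid_set`.
#' @param shift_um,rot_deg,scale magnitude of each component; draws are
#'   uniform in `[-m, m]` (scale: `1 + U(-m, m)`). A scale magnitude reaching
#'   -1 (scale 0) errors.
#' @param seed integer seed.
#' @return A list with `object` (transformed) and `transform`
#'   (an [affine_transform()]).
#' @export
apply_random_misalignment <- function(x, shift_um = 0, rot_deg = 0, scale = 0,
                                      seed = NULL) {
  stopifnot(is.finite(shift_um), is.finite(rot_deg), is.finite(scale))
  tform <- with_seed(seed, {
    sc <- 1 + runif(3, -scale, scale)
    if (any(sc == 0)) stop("drawn scale of 0 is singular", call. = FALSE)
    affine_from_params(shift_um = runif(3, -shift_um, shift_um),
                       rot_deg = runif(3, -rot_deg, rot_deg),
                       scale = sc)
  })
  if (inherits(x, "voxel_grid")) {
    inv <- invert_affine(tform)
    v <- affine_resample_cpp(x$values, dim(x$values), x$spacing, x$origin,
                             dim(x$values), x$spacing, x$origin,
                             inv$A, inv$t, fill = min(x$values))
    list(object = voxel_grid(v, x$spacing, x$origin), transform = tform)
  } else {
    xyz <- apply_affine_mat(tform, points_matrix(x))
    out <- x
    out$x_um <- xyz[, 1]; out$y_um <- xyz[, 2]; out$z_um <- xyz[, 3]
    list(object = out, transform = tform)
  }
}
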