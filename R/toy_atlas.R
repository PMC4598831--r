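#' Default toy-atlas region layout
#'
#' A desk-scale substitute for a manually drawn atlas: analogues of the
#' ventral striatum (core, medial shell, lateral shell), dorsal striatum (with
#' an anterior/posterior split plane), tail of striatum, globus pallidus,
#' entopeduncular nucleus, subthalamic nucleus, zona incerta, lateral
#' hypothalamus, olfactory tubercle, cortex, amygdala, lateral habenula,
#' dorsal raphe, and the four starter regions (VTA, SNc, SNr, RRF), each with
#' a parent among eight coarse divisions, a target volume fraction, and a seed
#' position in normalized (ML, DV, AP) coordinates (DV increases ventrally,
#' AP increases posteriorly).
#'
#' @return A tibble with one row per region.
#' @export
default_region_layout <- function() {
  tibble::tribble(
    ~name,              ~parent,        ~fraction, ~starter_excluded, ~px,  ~py,  ~pz,  ~split_frac,
    "cortex",           "Cortex",       0.28,  FALSE, 0.50, 0.12, 0.30, NA,
    "VS_core",          "Striatum",     0.020, FALSE, 0.42, 0.72, 0.22, NA,
    "VS_medial_shell",  "Striatum",     0.030, FALSE, 0.28, 0.80, 0.18, NA,
    "VS_lateral_shell", "Striatum",     0.020, FALSE, 0.62, 0.82, 0.26, NA,
    "OT",               "Striatum",     0.020, FALSE, 0.44, 0.95, 0.24, NA,
    "DS",               "Striatum",     0.100, FALSE, 0.58, 0.42, 0.38, 0.5,
    "TS",               "Striatum",     0.040, FALSE, 0.80, 0.50, 0.62, NA,
    "GP",               "Pallidum",     0.030, FALSE, 0.68, 0.62, 0.48, NA,
    "EP",               "Pallidum",     0.015, FALSE, 0.60, 0.58, 0.60, NA,
    "STh",              "Hypothalamus", 0.020, FALSE, 0.55, 0.74, 0.64, NA,
    "ZI",               "Hypothalamus", 0.025, FALSE, 0.50, 0.58, 0.60, NA,
    "LH",               "Hypothalamus", 0.030, FALSE, 0.42, 0.74, 0.54, NA,
    "Amy",              "Amygdala",     0.040, FALSE, 0.84, 0.78, 0.54, NA,
    "lHb",              "Thalamus",     0.010, FALSE, 0.50, 0.30, 0.55, NA,
    "DR",               "Hindbrain",    0.015, FALSE, 0.50, 0.48, 0.88, NA,
    "VTA",              "Midbrain",     0.020, TRUE,  0.44, 0.66, 0.72, NA,
    "SNc",              "Midbrain",     0.020, TRUE,  0.60, 0.64, 0.72, NA,
    "SNr",              "Midbrain",     0.015, TRUE,  0.66, 0.72, 0.76, NA,
    "RRF",              "Midbrain",     0.010, TRUE,  0.54, 0.60, 0.82, NA
  )
}

#' Generate a contiguous toy atlas
#'
#' Carves a label volume into contiguous regions by budgeted multi-source
#' breadth-first growth from seed sites: each region claims one 6-connected
#' voxel per round-robin cycle until its voxel budget (`fraction` x grid size)
#' is used up, so achieved volume fractions match the requested ones up to
#' blocking between neighbours. Deterministic given `seed` (seed sites are
#' jittered around the layout positions). Remaining voxels stay background
#' (label 0).
#'
#' @param region_layout a layout tibble like [default_region_layout()]:
#'   columns `name`, `parent`, `fraction`, `starter_excluded`, optional seed
#'   positions `px, py, pz` (normalized 0-1) and `split_frac` (coronal split
#'   plane as a fraction of the AP extent).
#' @param dims grid shape, default `c(64, 64, 64)`.
#' @param spacing_um voxel spacing (um), default 20 (isotropic reference grid);
#'   the default 64^3 x 20 um grid is a 1.28-mm cube so the full pipeline runs
#'   in minutes; pass `dims = c(700, 600, 350)` for the full-size reference
#'   preset.
#' @param seed integer seed.
#' @return A [brain_atlas()] with a `VS` region group
#'   (core + medial shell + lateral shell) when those regions are present.
#' @export
make_toy_atlas <- function(region_layout = default_region_layout(),
                           dims = c(64, 64, 64), spacing_um = 20, seed = 1) {
  layout <- tibble::as_tibble(region_layout)
  if (!nrow(layout)) stop("empty region layout", call. = FALSE)
  if (sum(layout$fraction) > 1 + 1e-9)
    stop("region volume fractions sum to ", sum(layout$fraction), " > 1", call. = FALSE)
  dims <- as.integer(rep_len(dims, 3))
  if (any(dims <= 0)) stop("grid must be nonempty", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing_um), 3)
  nvox <- prod(dims)
  has_pos <- all(c("px", "py", "pz") %in% names(layout))
  with_seed(seed, {
    if (has_pos) {
      pos <- cbind(layout$px, layout$py, layout$pz)
      idx <- round(sweep(pos, 2, dims - 1, `*`)) + 1 +
        matrix(sample(-1:1, 3 * nrow(layout), replace = TRUE), ncol = 3)
      idx <- pmin(pmax(idx, 1), matrix(dims, nrow(layout), 3, byrow = TRUE))
    } else {
      idx <- cbind(sample(dims[1], nrow(layout), replace = TRUE),
                   sample(dims[2], nrow(layout), replace = TRUE),
                   sample(dims[3], nrow(layout), replace = TRUE))
    }
    # de-duplicate seed voxels deterministically
    lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
    while (anyDuplicated(lin)) {
      d <- which(duplicated(lin))
      lin[d] <- (lin[d] %% nvox) + 1
    }
    budgets <- pmax(1L, as.integer(round(layout$fraction * nvox)))
    lab <- grow_regions_budgeted_cpp(dims, as.integer(lin), budgets)
  })
  grid <- voxel_grid(array(lab, dims), spacing = spacing)
  z_extent <- dims[3] * spacing[3]
  split_um <- if ("split_frac" %in% names(layout))
    layout$split_frac * z_extent else rep(NA_real_, nrow(layout))
  regions <- tibble::tibble(
    region_id = seq_len(nrow(layout)),
    name = layout$name,
    parent_region = layout$parent,
    starter_excluded = layout$starter_excluded,
    coronal_split_um = split_um)
  vs <- intersect(c("VS_core", "VS_medial_shell", "VS_lateral_shell"), layout$name)
  groups <- if (length(vs) == 3) list(VS = vs) else list()
  brain_atlas(grid, regions, groups)
}

# uniform positions (um) inside a region's voxels
sample_in_region <- function(atlas, region_id, n) {
  vox <- which(atlas$labels$values == region_id)
  if (!length(vox)) stop("region ", region_id, " has zero voxels", call. = FALSE)
  d <- dim(atlas$labels$values)
  pick <- vox[sample.int(length(vox), n, replace = TRUE)]
  idx <- cbind((pick - 1) %% d[1] + 1,
               ((pick - 1) %/% d[1]) %% d[2] + 1,
               (pick - 1) %/% (d[1] * d[2]) + 1)
  ctr <- voxel_to_um(idx, atlas$labels)
  ctr + matrix(runif(3 * n, -0.5, 0.5), ncol = 3) %*% diag(atlas$labels$spacing)
}
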