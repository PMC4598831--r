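utils::globalVariables(c("brain_id", "condition"))

#' One-way ANOVA of input percentages per region
#'
#' Classical fixed-effects one-way ANOVA (per-brain percent replicates across
#' conditions) for each region, via `stats::oneway.test(var.equal = TRUE)`.
#' Optionally screens to the `top_n` most prominent regions first (ranked by
#' the maximum condition-mean percent, the rule used to pick the main input
#' areas) and/or removes conditions before testing (the leave-one-out
#' re-test).
#'
#' @param profiles a `condition_profiles` object (its `replicates` attribute
#'   carries the per-brain values), or a `region_count_table`.
#' @param regions optional character vector restricting the tested regions.
#' @param top_n optional prominence screen: keep the `top_n` regions by max
#'   condition-mean percent before testing.
#' @param exclude_conditions conditions to drop before testing.
#' @return A tibble: `region`, `statistic` (F), `p.value`, `df1`, `df2`.
#' @export
anova_by_region <- function(profiles, regions = NULL, top_n = NULL,
                            exclude_conditions = NULL) {
  reps <- if (inherits(profiles, "condition_profiles"))
    attr(profiles, "replicates") else
      dplyr::filter(profiles, !.data$starter_excluded, .data$region_id != 0L)
  if (!is.null(exclude_conditions))
    reps <- dplyr::filter(reps, !.data$condition %in% exclude_conditions)
  if (length(unique(reps$condition)) < 2)
    stop("ANOVA needs at least 2 conditions", call. = FALSE)
  if (!is.null(regions)) reps <- dplyr::filter(reps, .data$region %in% regions)
  if (!is.null(top_n)) {
    prom <- reps |>
      dplyr::group_by(.data$condition, .data$region) |>
      dplyr::summarise(m = mean(.data$percent), .groups = "drop") |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(prominence = max(.data$m), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$prominence))
    reps <- dplyr::filter(reps, .data$region %in% prom$region[seq_len(min(top_n, nrow(prom)))])
  }
  out <- reps |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(df, key) {
      groups <- split(df$percent, df$condition)
      within_var <- sum(vapply(groups, function(g)
        sum((g - mean(g))^2), 0))
      means <- vapply(groups, mean, 0)
      if (within_var == 0) {
        if (max(means) - min(means) > 0)
          stop("region ", key$region, ": zero within-group variance with ",
               "unequal means (infinite F); check for degenerate replicates",
               call. = FALSE)
        return(tibble::tibble(statistic = 0, p.value = 1,
                              df1 = length(groups) - 1,
                              df2 = length(df$percent) - length(groups)))
      }
      ft <- stats::oneway.test(percent ~ condition, data = df, var.equal = TRUE)
      tibble::tibble(statistic = unname(ft$statistic),
                     p.value = unname(ft$p.value),
                     df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("region_anova", class(out)))
}

#' @export
tidy.region_anova <- function(x, ...) tibble::as_tibble(unclass(x))

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorts the p-values ascending and rejects the i-th smallest iff
#' `p(i) <= 1 - (1 - alpha)^(1/(m - i + 1))` *and* all smaller-ranked
#' hypotheses were rejected (step-down stopping). Returns the per-rank
#' Sidak-adjusted thresholds alongside the decisions.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha familywise significance level, default 0.05.
#' @return A tibble in the input order: `p.value`, `rank`, `threshold`,
#'   `reject`.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  rk <- integer(m); rk[ord] <- seq_len(m)
  thr_sorted <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  pass <- p[ord] <= thr_sorted
  reject_sorted <- cumprod(pass) == 1 # step-down: stop at first failure
  tibble::tibble(p.value = p, rank = rk, threshold = thr_sorted[rk],
                 reject = reject_sorted[rk])
}

#' Familywise error of the ANOVA + Holm-Sidak pipeline under a global null
#'
#' Monte-Carlo calibration: simulates cohorts in which every condition shares
#' one region-proportion vector (counts multinomial per brain, percents over
#' all regions), applies the one-way F test per region and the Holm-Sidak
#' step-down, and reports the fraction of replicates with at least one
#' rejection. The F statistic is computed by the closed-form sums-of-squares
#' identity, vectorized across replicates; it is algebraically the statistic
#' [anova_by_region()] computes (asserted by the test suite).
#'
#' @param n_reps simulation replicates, default 10000.
#' @param n_conditions,n_brains cohort shape, defaults 8 and 4.
#' @param n_regions regions tested, default 20.
#' @param n_points points per brain, default 5000.
#' @param alpha familywise level, default 0.05.
#' @param props optional shared proportion vector (length `n_regions`);
#'   default equal.
#' @param seed integer seed.
#' @return A list: `fwe` (familywise error rate), `mc_se` (its Monte-Carlo
#'   standard error), `n_reps`.
#' @export
holm_sidak_fwe_sim <- function(n_reps = 10000, n_conditions = 8, n_brains = 4,
                               n_regions = 20, n_points = 5000, alpha = 0.05,
                               props = NULL, seed = 1) {
  p <- props %||% rep(1 / n_regions, n_regions)
  stopifnot(length(p) == n_regions, abs(sum(p) - 1) < 1e-9)
  nb <- n_conditions * n_brains
  with_seed(seed, {
    any_reject <- logical(n_reps)
    thr <- 1 - (1 - alpha)^(1 / (n_regions - seq_len(n_regions) + 1))
    for (r in seq_len(n_reps)) {
      counts <- rmultinom(nb, n_points, p) # regions x brains
      pct <- 100 * sweep(counts, 2, colSums(counts), `/`)
      # closed-form balanced one-way F per region (row)
      gm <- array(pct, c(n_regions, n_brains, n_conditions))
      cmn <- apply(gm, c(1, 3), mean)
      grand <- rowMeans(cmn)
      ssb <- n_brains * rowSums((cmn - grand)^2)
      ssw <- rowSums((gm - aperm(array(cmn, c(n_regions, n_conditions, n_brains)),
                                 c(1, 3, 2)))^2)
      f <- (ssb / (n_conditions - 1)) / (ssw / (nb - n_conditions))
      pv <- stats::pf(f, n_conditions - 1, nb - n_conditions, lower.tail = FALSE)
      ps <- sort(pv)
      any_reject[r] <- ps[1] <= thr[1]
    }
    fwe <- mean(any_reject)
    list(fwe = fwe, mc_se = sqrt(fwe * (1 - fwe) / n_reps), n_reps = n_reps)
  })
}

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided, equal-variance Student's t (Welch available via
#' `var_equal = FALSE`). Errors on groups smaller than 2 or a degenerate
#' zero pooled variance.
#'
#' @param a,b numeric replicate vectors, each of length >= 2.
#' @param var_equal pooled-variance Student's t (default) vs Welch.
#' @return A tibble: `statistic` (t), `p.value`, `df`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 replicates", call. = FALSE)
  if (var(a) + var(b) == 0) {
    if (mean(a) == mean(b))
      return(tibble::tibble(statistic = 0, p.value = 1,
                            df = length(a) + length(b) - 2))
    stop("zero pooled variance with unequal means: t is undefined", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic), p.value = tt$p.value,
                 df = unname(tt$parameter))
}

#' Pairwise Pearson correlation of condition profiles
#'
#' Pearson r between the condition-mean percent vectors over a shared region
#' list. Regions with zero variance across both of a pair's vectors are
#' excluded pairwise (audited); fewer than 2 usable regions is an error.
#'
#' @param profiles a `condition_profiles` object.
#' @return A `correlation_matrix`: symmetric, unit diagonal, entries in
#'   `[-1, 1]`; attribute `excluded` audits pairwise exclusions.
#' @export
correlation_matrix <- function(profiles) {
  wide <- profiles |>
    dplyr::select("condition", "region", "mean_percent") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_percent")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$region
  conds <- colnames(m)
  k <- length(conds)
  r <- diag(1, k); dimnames(r) <- list(conds, conds)
  excluded <- tibble::tibble(condition_a = character(0),
                             condition_b = character(0), region = character(0))
  # a region is unusable across the whole matrix if it never varies
  row_const <- apply(m, 1, function(v) stats::sd(v) == 0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    # pairwise: drop regions constant within this pair *and* globally constant
    use <- !(row_const & m[, i] == m[, j])
    if (any(!use))
      excluded <- dplyr::bind_rows(excluded, tibble::tibble(
        condition_a = conds[i], condition_b = conds[j],
        region = rownames(m)[!use]))
    if (sum(use) < 2)
      stop("fewer than 2 regions with variance for pair ", conds[i], "/",
           conds[j], call. = FALSE)
    r[i, j] <- r[j, i] <- stats::cor(m[use, i], m[use, j])
  }
  structure(r, class = "correlation_matrix", excluded = excluded)
}

#' @export
tidy.correlation_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame.table(m, responseName = "r")) |>
    dplyr::rename(condition_a = "Var1", condition_b = "Var2")
}

#' Average-linkage hierarchical clustering of conditions
#'
#' Agglomerative UPGMA clustering on the distance `d = 1 - r` derived from a
#' correlation matrix (the standard transform of a correlation "distance").
#' Ties are broken deterministically by lexicographic label order (labels are
#' sorted before clustering).
#'
#' @param m a `correlation_matrix`.
#' @return A `condition_dendrogram` wrapping the `hclust` result: fields
#'   `merge`, `height`, `order`, `labels`.
#' @export
hierarchical_cluster <- function(m) {
  stopifnot(inherits(m, "correlation_matrix"))
  lab <- sort(colnames(m))
  d <- as.dist(1 - unclass(m)[lab, lab])
  hc <- stats::hclust(d, method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "condition_dendrogram")
}

#' @export
print.condition_dendrogram <- function(x, ...) {
  cat("<condition_dendrogram> ", length(x$labels), " leaves, merge heights ",
      paste(signif(x$height, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.condition_dendrogram <- function(x, ...) {
  tibble::tibble(step = seq_along(x$height),
                 left = x$merge[, 1], right = x$merge[, 2],
                 height = x$height)
}

#' The leaf that joins the clustering tree last
#'
#' The outgroup: the singleton absorbed at the final (or latest possible)
#' merge — used to check that an outlier condition separates from the rest.
#'
#' @param dend a `condition_dendrogram`.
#' @return A condition label, or `NA` if the final merge joins two
#'   non-singleton clusters.
#' @export
outgroup_label <- function(dend) {
  last <- dend$merge[nrow(dend$merge), ]
  singles <- last[last < 0]
  if (length(singles) == 0) return(NA_character_)
  dend$labels[-singles[1]]
}

#' Export a dendrogram as Newick
#'
#' @param dend a `condition_dendrogram`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_newick <- function(dend, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export", call. = FALSE)
  ape::write.tree(ape::as.phylo(dend$hclust), file = path)
  invisible(path)
}

#' Reciprocity comparison of input fractions
#'
#' For each condition, compares the percent of inputs from its reciprocal
#' region (region-based mode: the injection-site's brain region; mask-based
#' mode: an arbitrary voxel mask such as a labeled infection site) across its
#' own brains against the same percent in the pooled brains of all other
#' conditions, by two-sample t-test.
#'
#' @param table a `region_count_table` (region mode), or region-assigned
#'   points (mask mode).
#' @param mapping named list: condition -> region/group name (region mode) or
#'   condition -> logical/integer array on the atlas grid (mask mode).
#' @param atlas required in mask mode (and to resolve groups in region mode).
#' @return A tibble: `condition`, `own_mean`, `others_mean`, `statistic`,
#'   `p.value`.
#' @export
reciprocity_compare <- function(table, mapping, atlas = NULL) {
  conds <- names(mapping)
  if (length(unique(table$condition)) < 2)
    stop("reciprocity comparison needs at least 2 conditions", call. = FALSE)
  per_brain_fraction <- function(target) {
    if (is.character(target)) {
      ids <- region_group_ids(atlas, target)
      nm <- atlas$regions$name[match(ids, atlas$regions$region_id)]
      # include split halves of any matched region
      nm <- unique(c(nm, paste0(nm, "_anterior"), paste0(nm, "_posterior")))
      sel <- table |>
        dplyr::filter(!.data$starter_excluded, .data$region_id != 0L) |>
        dplyr::group_by(.data$brain_id, .data$condition) |>
        dplyr::summarise(frac = sum(.data$percent[.data$region %in% nm]),
                         .groups = "drop")
      if (all(sel$frac == 0)) stop("mapping to empty region: ",
                                   paste(target, collapse = ","), call. = FALSE)
      sel
    } else {
      stopifnot(!is.null(atlas), inherits(table, "centroid_set"))
      mask_grid <- atlas$labels
      mask_grid$values <- array(as.integer(target != 0), dim(mask_grid$values))
      pts <- table
      lab <- pts$region_id
      keep <- lab != 0 & !(lab %in% starter_region_ids(atlas))
      pts <- pts[keep, , drop = FALSE]
      inmask <- grid_value_at(mask_grid, points_matrix(pts), outside = 0) != 0
      tibble::tibble(brain_id = pts$brain_id, condition = pts$condition,
                     inmask = inmask) |>
        dplyr::group_by(.data$brain_id, .data$condition) |>
        dplyr::summarise(frac = 100 * mean(.data$inmask), .groups = "drop")
    }
  }
  purrr::map_dfr(conds, function(cn) {
    fr <- per_brain_fraction(mapping[[cn]])
    own <- fr$frac[fr$condition == cn]
    oth <- fr$frac[fr$condition != cn]
    tt <- two_sample_ttest(own, oth)
    tibble::tibble(condition = cn, own_mean = mean(own),
                   others_mean = mean(oth),
                   statistic = tt$statistic, p.value = tt$p.value)
  })
}
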