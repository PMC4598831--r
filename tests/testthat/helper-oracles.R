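# Independent oracles used across tests: deliberately naive implementations
# that never share code with the package internals.

# brute-force 26-connected flood fill; returns component count and a label
# array, visiting voxels in linear order
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1) %% d[1] + 1
      j <- ((v - 1) %/% d[1]) %% d[2] + 1
      k <- (v - 1) %/% (d[1] * d[2]) + 1
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        w <- (kk - 1) * d[1] * d[2] + (jj - 1) * d[1] + ii
        if (mask[w] != 0 && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  list(n = nxt, labels = lab)
}

# textbook UPGMA on a distance matrix with labels; returns successive merge
# heights (sorted clusters tracked as label sets) — independent of hclust
upgma_oracle <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  dm <- d
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    n <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dd <- mean(dm[clusters[[i]], clusters[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merges <- c(merges, list(sort(c(unlist(clusters[[best[1]]]),
                                    unlist(clusters[[best[2]]])))))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# dense 2D convolution by direct summation with reflective boundary
dense_conv2_oracle <- function(m, kern2d) {
  kr <- (nrow(kern2d) - 1) / 2
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (a in -kr:kr) for (b in -kr:kr)
      acc <- acc + kern2d[a + kr + 1, b + kr + 1] *
        m[reflect(i + a, nrow(m)), reflect(j + b, ncol(m))]
    out[i, j] <- acc
  }
  out
}

# brute-force synchronized multi-source growth for patch segmentation:
# per round, every unclaimed 26-neighbour of a patch with density above that
# patch's threshold is claimed; conflicts by higher peak then lower id
grow_patches_oracle <- function(dens, seeds, peaks, thresholds) {
  d <- dim(dens)
  lab <- array(0L, d)
  lab[seeds] <- seq_along(seeds)
  repeat {
    claims <- list()
    for (v in which(lab != 0)) {
      p <- lab[v]
      i <- (v - 1) %% d[1] + 1
      j <- ((v - 1) %/% d[1]) %% d[2] + 1
      k <- (v - 1) %/% (d[1] * d[2]) + 1
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        w <- (kk - 1) * d[1] * d[2] + (jj - 1) * d[1] + ii
        if (lab[w] != 0 || dens[w] < thresholds[p]) next
        cur <- claims[[as.character(w)]]
        if (is.null(cur) || peaks[p] > peaks[cur] ||
            (peaks[p] == peaks[cur] && p < cur))
          claims[[as.character(w)]] <- p
      }
    }
    if (!length(claims)) break
    for (w in names(claims)) lab[as.integer(w)] <- claims[[w]]
  }
  lab
}

# greedy nearest-neighbour matching of detected vs true points within radius
match_points <- function(det, tru, radius_um = 10) {
  if (nrow(det) == 0 || nrow(tru) == 0)
    return(list(recall = 0, precision = if (nrow(det) == 0) 1 else 0))
  cross <- sqrt(outer(rowSums(det^2), rep(1, nrow(tru))) +
                  outer(rep(1, nrow(det)), rowSums(tru^2)) - 2 * det %*% t(tru))
  list(recall = mean(apply(cross, 2, min) <= radius_um),
       precision = mean(apply(cross, 1, min) <= radius_um))
}

# assemble a region_count_table-shaped tibble directly from a count matrix
# (regions x brains), bypassing spatial simulation
counts_to_table <- function(counts, conditions, regions,
                            starter = rep(FALSE, length(regions))) {
  stopifnot(nrow(counts) == length(regions), ncol(counts) == length(conditions))
  out <- tibble::tibble(
    brain_id = rep(colnames(counts), each = length(regions)),
    condition = rep(conditions, each = length(regions)),
    region_id = rep(seq_along(regions), ncol(counts)),
    region = rep(regions, ncol(counts)),
    count = as.vector(counts),
    starter_excluded = rep(starter, ncol(counts)))
  out |>
    dplyr::group_by(brain_id) |>
    dplyr::mutate(percent = ifelse(starter_excluded, NA,
                                   100 * count / sum(count[!starter_excluded]))) |>
    dplyr::ungroup()
}
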