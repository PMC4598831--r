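test_that("the feature bank yields 18 values per pixel with sane responses", {
  g <- voxel_grid(array(runif(32 * 32 * 2), c(32, 32, 2)), c(1, 1, 5.25))
  fs <- compute_pixel_features(g)
  expect_equal(ncol(fs$values), 18L)
  expect_equal(length(fs$feature_names), 18L)

  # constant image: gradient-type features 0, Gaussian = the constant
  gc <- voxel_grid(array(7, c(24, 24, 2)), c(1, 1, 5.25))
  fc <- compute_pixel_features(gc)
  expect_true(all(abs(fc$values[, grep("^gaussian", fc$feature_names)] - 7) < 1e-9))
  for (fam in c("gradient_magnitude", "laplacian_of_gaussian",
                "difference_of_gaussians", "structure_tensor_eig"))
    expect_true(all(abs(fc$values[, grep(fam, fc$feature_names)]) < 1e-9),
                label = fam)

  # oversized radius errors
  expect_error(compute_pixel_features(gc, radii = 50), "extent")
})

test_that("the Gaussian feature of an impulse matches dense 2D convolution", {
  v <- array(0, c(31, 31, 1))
  v[16, 16, 1] <- 1
  g <- voxel_grid(v, c(1, 1, 1))
  fs <- compute_pixel_features(g, radii = 1.6)
  got <- matrix(fs$values[, "gaussian_r1.6"], 31, 31)
  k1 <- inputmap:::gauss_kernel(1.6)
  oracle <- dense_conv2_oracle(v[, , 1], outer(k1, k1))
  expect_equal(got, oracle, tolerance = 1e-12)
  # centre response is the squared discrete-Gaussian peak (separable impulse)
  expect_equal(got[16, 16], k1[(length(k1) + 1) / 2]^2, tolerance = 1e-12)
})

test_that("classifier training enforces the forest configuration", {
  # linearly separable toy problem
  g <- voxel_grid(array(rep(c(0, 1), each = 128), c(16, 16, 1)), c(1, 1, 1))
  fs <- compute_pixel_features(g, radii = 0.7)
  labs <- tibble::tibble(index = c(1:40, 217:256),
                         class = rep(c("non-cell", "cell"), each = 40))
  mod <- train_pixel_classifier(fs, labs, seed = 1)
  expect_equal(mod$n_trees, 200)
  expect_equal(mod$features_per_split, 4)
  expect_equal(mod$model$num.trees, 200)
  expect_equal(mod$model$mtry, 4)
  pred <- classify_pixels(mod, fs)
  expect_true(all(pred$values[labs$index[1:40]] == 0))
  expect_true(all(pred$values[labs$index[41:80]] == 1))

  # same data + seed -> identical predictions
  mod2 <- train_pixel_classifier(fs, labs, seed = 1)
  expect_identical(classify_pixels(mod2, fs)$values, pred$values)

  # single-class labels refused
  expect_error(train_pixel_classifier(fs, labs[1:40, ]), "single class")
  # feature layout mismatch refused
  fs2 <- compute_pixel_features(g, radii = 1.6)
  expect_error(classify_pixels(mod, fs2), "mismatch")
})

test_that("a trained model transfers to a new volume from the same optics", {
  opt <- optics_spec()
  train_sim <- simulate_brain_volume(40, opt, dims = c(96, 96, 24), seed = 21)
  fs_train <- compute_pixel_features(train_sim$volume)
  mod <- train_pixel_classifier(fs_train, truth_training_labels(train_sim, seed = 1),
                                seed = 2)
  test_sim <- simulate_brain_volume(40, opt, dims = c(96, 96, 24), seed = 22)
  fs_test <- compute_pixel_features(test_sim$volume)
  mask <- classify_pixels(mod, fs_test)
  tm <- ground_truth_mask(test_sim)
  tp <- sum(mask$values == 1 & tm$values == 1)
  fp <- sum(mask$values == 1 & tm$values == 0)
  fn <- sum(mask$values == 0 & tm$values == 1)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.9)

  # an all-background volume under the same model stays nearly empty
  bg_sim <- simulate_brain_volume(0, opt, dims = c(96, 96, 24), seed = 23)
  bg_mask <- classify_pixels(mod, compute_pixel_features(bg_sim$volume))
  expect_lt(mean(bg_mask$values), 0.01)
})

test_that("per-parent-region model selection retains only the local model", {
  at <- test_atlas
  d <- dim(at$labels$values)
  all1 <- binary_mask(array(1L, d), at$labels$spacing)
  all0 <- binary_mask(array(0L, d), at$labels$spacing)
  parents <- unique(at$regions$parent_region)
  # models that disagree everywhere: one says all-cell, the rest all-background
  masks <- setNames(c(list(all1), rep(list(all0), length(parents) - 1)), parents)
  comp <- compose_parent_masks(masks, at)
  pv <- inputmap:::parent_volume(at)
  sel <- pv$values == match(parents[1], levels(pv$parent_levels))
  expect_true(all(comp$values[sel] == 1L))
  expect_true(all(comp$values[!sel] == 0L))
  # the composite partitions all non-background voxels exactly once
  expect_equal(sum(sel) + sum(comp$values == 0L & pv$values != 0L) +
                 sum(pv$values == 0L), prod(d))

  # centroid-level: a centroid in unlabeled background is excluded
  bgv <- which(at$labels$values == 0)[1]
  bgidx <- cbind((bgv - 1) %% d[1] + 1, ((bgv - 1) %/% d[1]) %% d[2] + 1,
                 (bgv - 1) %/% (d[1] * d[2]) + 1)
  bgpt <- centroid_set(voxel_to_um(bgidx, at$labels))
  kept <- filter_centroids_by_parent(
    setNames(rep(list(bgpt), length(parents)), parents), at)
  expect_equal(nrow(kept), 0)

  # missing parent model errors with the parent name
  expect_error(compose_parent_masks(masks[-1], at), parents[1])
})

test_that("3D collapse matches a brute-force flood fill", {
  # two disjoint 3x3x3 cubes -> centroids at the cube centres
  m <- array(0L, c(12, 8, 8))
  m[2:4, 2:4, 2:4] <- 1L
  m[8:10, 5:7, 4:6] <- 1L
  mask <- binary_mask(m, c(1, 1, 1))
  comp <- extract_components(mask)
  expect_equal(nrow(comp), 2)
  expect_equal(comp$x_um, c(2.5, 8.5))
  expect_equal(comp$y_um, c(2.5, 5.5))
  expect_equal(comp$z_um, c(2.5, 4.5))
  expect_equal(comp$n_vox, c(27L, 27L))

  # two cubes touching only at a corner form one 26-connected component
  m2 <- array(0L, c(8, 8, 8))
  m2[1:3, 1:3, 1:3] <- 1L
  m2[4:6, 4:6, 4:6] <- 1L
  comp2 <- extract_components(binary_mask(m2, c(1, 1, 1)))
  expect_equal(nrow(comp2), 1)

  # random masks agree with the oracle in count and membership
  withr::with_seed(9, {
    for (i in 1:5) {
      mr <- array(as.integer(runif(16^3) < 0.25), c(16, 16, 16))
      got <- extract_components(binary_mask(mr, c(1, 1, 1)))
      oracle <- flood_fill_oracle(mr)
      expect_equal(nrow(got), oracle$n)
    }
  })

  # empty mask -> empty list
  expect_equal(nrow(extract_components(binary_mask(array(0L, c(4, 4, 4)),
                                                   c(1, 1, 1)))), 0)
})

test_that("component filters implement the diameter/slice/shape rules", {
  sp <- c(1.04, 1.04, 5.25)
  # single-voxel component: too small and single-slice
  m <- array(0L, c(20, 40, 6)); m[3, 3, 3] <- 1L
  comp <- extract_components(binary_mask(m, sp))
  out <- filter_components(comp)
  aud <- attr(out, "audit")
  expect_equal(nrow(out), 0)
  expect_true(aud$fail_diameter && aud$fail_z_span)

  # in-plane 1x30 line: circularity 4*pi*A/P^2 below 0.1 via the
  # exposed-edge perimeter (oracle: pixel walk -> 62 edges)
  m2 <- array(0L, c(20, 40, 6)); m2[5, 4:33, 2:3] <- 1L
  comp2 <- extract_components(binary_mask(m2, sp))
  occ <- m2[, , 2]
  edges <- 0
  for (i in 1:20) for (j in 1:40) if (occ[i, j] == 1) {
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + dd[1]; jj <- j + dd[2]
      if (ii < 1 || ii > 20 || jj < 1 || jj > 40 || occ[ii, jj] == 0)
        edges <- edges + 1
    }
  }
  expect_equal(edges, 62)
  circ_oracle <- 4 * pi * (30 * sp[1] * sp[2]) / (62 * mean(sp[1:2]))^2
  expect_equal(comp2$circularity, circ_oracle, tolerance = 1e-12)
  expect_lt(comp2$circularity, 0.1)
  out2 <- filter_components(comp2)
  expect_equal(nrow(out2), 0)
  expect_true(attr(out2, "audit")$fail_circularity)

  # a blurred 10-um sphere spanning 2 z-steps is retained
  opt <- optics_spec(radius_range_um = c(5, 5), noise_sd = 0)
  sim <- simulate_brain_volume(1, opt, dims = c(48, 48, 12), seed = 31)
  comp3 <- extract_components(ground_truth_mask(sim, core_margin_um = -1))
  expect_gte(comp3$z_span[1], 2)
  out3 <- filter_components(comp3)
  expect_equal(nrow(out3), 1)
})

test_that("relaxing any single filter threshold never shrinks the survivors", {
  withr::with_seed(41, {
    comp <- tibble::tibble(
      component_id = 1:200, n_vox = sample(1:60, 200, TRUE),
      volume_um3 = runif(200, 1, 4000),
      x_um = runif(200), y_um = runif(200), z_um = runif(200),
      diameter_um = runif(200, 0.5, 60), z_span = sample(1:5, 200, TRUE),
      max_slice_area_um2 = runif(200), max_slice_perimeter_um = runif(200),
      circularity = runif(200, 0, 1))
    base <- nrow(filter_components(comp))
    expect_gte(nrow(filter_components(comp, d_min_um = 1)), base)
    expect_gte(nrow(filter_components(comp, d_max_um = 80)), base)
    expect_gte(nrow(filter_components(comp, min_z_slices = 1)), base)
    expect_gte(nrow(filter_components(comp, circ_min = 0.05)), base)
  })
})
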