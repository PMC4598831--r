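test_that("section-wise centers of mass are exact on constructed points", {
  # symmetric cloud about (300, 400) in one 400-um bin
  sym <- rbind(c(250, 350, 100), c(350, 450, 150), c(250, 450, 120),
               c(350, 350, 180))
  cs <- centroid_set(sym, space_tag = "reference")
  com <- center_of_mass_by_section(cs)
  expect_equal(nrow(com), 1)
  expect_equal(com$com_x_um, 300)
  expect_equal(com$com_y_um, 400)
  expect_equal(com$n, 4L)

  # {(1,1), (3,3)}: COM (2,2), s.e.m. (1,1)
  two <- centroid_set(rbind(c(1, 1, 10), c(3, 3, 20)), space_tag = "reference")
  com2 <- center_of_mass_by_section(two)
  expect_equal(c(com2$com_x_um, com2$com_y_um), c(2, 2))
  expect_equal(c(com2$sem_x_um, com2$sem_y_um), c(1, 1))

  # empty input -> empty series; single point -> NA s.e.m., bin present
  expect_equal(nrow(center_of_mass_by_section(centroid_set(matrix(0, 0, 3)))), 0)
  one <- center_of_mass_by_section(centroid_set(matrix(c(5, 5, 5), 1),
                                                space_tag = "reference"))
  expect_equal(one$n, 1L)
  expect_true(is.na(one$sem_x_um))

  # bins with no points are absent, not zero-filled
  gap <- centroid_set(rbind(c(0, 0, 100), c(0, 0, 1300)),
                      space_tag = "reference")
  comg <- center_of_mass_by_section(gap)
  expect_equal(sort(comg$bin), c(0, 3))
})

test_that("the union COM is the count-weighted mean of part COMs", {
  withr::with_seed(21, {
    a <- matrix(runif(30, 0, 399), ncol = 3); a[, 3] <- runif(10, 0, 399)
    b <- matrix(runif(60, 0, 399), ncol = 3); b[, 3] <- runif(20, 0, 399)
  })
  ca <- center_of_mass_by_section(centroid_set(a, space_tag = "reference"))
  cb <- center_of_mass_by_section(centroid_set(b, space_tag = "reference"))
  cu <- center_of_mass_by_section(centroid_set(rbind(a, b),
                                               space_tag = "reference"))
  expect_equal(cu$com_x_um,
               (ca$n * ca$com_x_um + cb$n * cb$com_x_um) / (ca$n + cb$n),
               tolerance = 1e-12)
})

test_that("cohorts offset dorso-laterally separate in per-bin COMs", {
  at <- test_atlas
  sp <- cohort_spec(c("near", "far"), n_brains = 1, n_points = 4000,
                    props = list(near = c(cortex = 1), far = c(cortex = 1)))
  pts <- simulate_centroid_cohort(at, sp, seed = 22)
  delta <- c(60, 40, 0)
  shifted <- pts
  sel <- shifted$condition == "far"
  shifted$x_um[sel] <- shifted$x_um[sel] + delta[1]
  shifted$y_um[sel] <- shifted$y_um[sel] + delta[2]
  com <- center_of_mass_by_section(shifted)
  joint <- merge(com[com$condition == "near", ], com[com$condition == "far", ],
                 by = "bin")
  joint <- joint[joint$n.x >= 50 & joint$n.y >= 50, ]
  dx <- joint$com_x_um.y - joint$com_x_um.x
  se <- sqrt(joint$sem_x_um.x^2 + joint$sem_x_um.y^2)
  expect_true(all(abs(dx - delta[1]) < 3 * se + 1e-9))
})

test_that("density rasterization conserves mass and is linear", {
  geom <- voxel_grid(array(0, c(48, 48, 48)), rep(20, 3))
  empty <- rasterize_density(centroid_set(matrix(0, 0, 3),
                                          space_tag = "reference"), geom)
  expect_true(all(empty$values == 0))

  pt <- centroid_set(matrix(c(480, 480, 480), 1), space_tag = "reference")
  d1 <- rasterize_density(pt, geom)
  expect_equal(sum(d1$values), 1, tolerance = 0.01)
  peak <- which(d1$values == max(d1$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), um_to_voxel(c(480, 480, 480), d1)[1, ])

  # independent oracle: the discrete separable kernel stamped at the voxel
  k <- inputmap:::gauss_kernel(60 / (2 * sqrt(2 * log(2))) / 20, 0)
  oracle_peak <- max(k)^3
  expect_equal(max(d1$values), oracle_peak, tolerance = 1e-12)

  # two points in one voxel: exactly twice the single-point field
  pt2 <- centroid_set(rbind(c(480, 480, 480), c(481, 482, 483)),
                      space_tag = "reference")
  d2 <- rasterize_density(pt2, geom)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)

  # translation by whole voxels shifts the field exactly
  pt3 <- centroid_set(matrix(c(480 + 40, 480, 480), 1), space_tag = "reference")
  d3 <- rasterize_density(pt3, geom)
  expect_equal(d3$values[3:48, , ], d1$values[1:46, , ], tolerance = 1e-12)
})

test_that("patch growth matches the analytic Gaussian isocontour", {
  geom <- voxel_grid(array(0, c(64, 64, 64)), rep(20, 3))
  pt <- centroid_set(matrix(c(640, 640, 640), 1), space_tag = "reference")
  dens <- rasterize_density(pt, geom)
  ps <- detect_patches(dens)
  expect_equal(nrow(ps), 1)
  sd_um <- 60 / (2 * sqrt(2 * log(2)))
  r_iso <- sd_um * sqrt(2 * log(3)) # density falls to 1/3 peak here
  v_expect <- 4 / 3 * pi * r_iso^3 / prod(dens$spacing)
  # member count within ~1-voxel shell of the analytic ball
  shell <- 4 / 3 * pi * ((r_iso + 20)^3 - max(0, r_iso - 20)^3) / 8000
  expect_lt(abs(ps$n_vox - v_expect), shell)
  # peak at the centre of the voxel containing the planted point
  expect_equal(c(ps$peak_x_um, ps$peak_y_um, ps$peak_z_um),
               as.vector(voxel_to_um(um_to_voxel(c(640, 640, 640), dens), dens)))
})

test_that("distant blobs give disjoint patches; overlapping blobs split", {
  geom <- voxel_grid(array(0, c(64, 64, 32)), rep(20, 3))
  sd_um <- 60 / (2 * sqrt(2 * log(2)))
  far <- centroid_set(rbind(matrix(rep(c(300, 300, 300), 10), ncol = 3, byrow = TRUE),
                            matrix(rep(c(1000, 1000, 300), 10), ncol = 3, byrow = TRUE)),
                      space_tag = "reference")
  psf <- detect_patches(rasterize_density(far, geom))
  expect_equal(nrow(psf), 2)
  labf <- attr(psf, "labels")$values
  expect_equal(sort(unique(labf[labf > 0])), c(1L, 2L))
  for (p in 1:2) {
    pk <- um_to_voxel(c(psf$peak_x_um[p], psf$peak_y_um[p], psf$peak_z_um[p]),
                      attr(psf, "labels"))
    expect_equal(labf[pk], p)
  }

  # overlapping blobs (separation 3.5 sigma, still sharing mass above the
  # growth floor): two patches, every claimed voxel in exactly one, matching
  # the brute-force simultaneous-growth oracle
  near <- centroid_set(rbind(matrix(rep(c(600, 600, 300), 12), ncol = 3, byrow = TRUE),
                             matrix(rep(c(600 + 3.5 * sd_um, 600, 300), 10),
                                    ncol = 3, byrow = TRUE)),
                       space_tag = "reference")
  dn <- rasterize_density(near, geom)
  psn <- detect_patches(dn, prominence_fraction = 0.05)
  expect_equal(nrow(psn), 2)
  labn <- attr(psn, "labels")$values
  seed_idx <- vapply(1:2, function(p) {
    pk <- um_to_voxel(c(psn$peak_x_um[p], psn$peak_y_um[p], psn$peak_z_um[p]),
                      dn)
    (pk[3] - 1) * 64 * 64 + (pk[2] - 1) * 64 + pk[1]
  }, 0)
  oracle <- grow_patches_oracle(dn$values, seed_idx, psn$peak_density,
                                psn$peak_density / 3)
  expect_equal(as.vector(labn), as.vector(oracle))
})

test_that("patch ids are stable only through the documented tie-break", {
  # two equal peaks: claims resolve by lower patch id on the shared boundary
  d <- array(0, c(21, 5, 5))
  d[6, 3, 3] <- 1; d[16, 3, 3] <- 1
  d[2:20, 3, 3] <- pmax(d[2:20, 3, 3], 0.5)
  dens <- voxel_grid(d, rep(20, 3))
  class(dens) <- c("density_volume", class(dens))
  ps <- detect_patches(dens, stop_fraction = 1 / 3)
  expect_equal(nrow(ps), 2)
  lab <- attr(ps, "labels")$values
  # the midpoint voxel is equidistant; documented tie-break gives patch 1
  expect_equal(lab[11, 3, 3], 1L)
})

test_that("patch membership fractions recover generator structure", {
  at <- test_atlas
  sp <- default_cohort_spec(at, n_brains = 2, n_points = 4000)
  pts <- simulate_centroid_cohort(at, sp, seed = 31)
  ap <- assign_regions(pts, at)
  ps <- detect_ventral_patches(ap, at)
  pm <- patch_membership_fractions(ap, ps, at)
  fr <- pm$fractions
  # canonical conditions sit near their drawn VS fractions, TS near 0.05
  expect_lt(abs(fr$frac_in_region[fr$condition == "TS"] - 0.05), 0.02)
  expect_true(all(fr$frac_in_region[fr$condition != "TS"] > 0.08))
  # canonical in-patch fraction well above the TS (patch-free) condition
  ts_in <- fr$frac_in_patches[fr$condition == "TS"]
  can_in <- fr$frac_in_patches[fr$condition == "VS"]
  expect_gt(can_in, ts_in)
  expect_gt(can_in, pm$chance_region)
  # per-patch shares sum to 1 within condition
  sums <- tapply(pm$shares$share, pm$shares$condition, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # all points inside one patch (within the VS group) -> fraction 1, share 1
  lab <- attr(ps, "labels")
  vs_ids <- region_group_ids(at, "VS")
  vox <- which(lab$values > 0 & at$labels$values %in% vs_ids)[1]
  dd <- dim(lab$values)
  idx <- cbind((vox - 1) %% dd[1] + 1, ((vox - 1) %/% dd[1]) %% dd[2] + 1,
               (vox - 1) %/% (dd[1] * dd[2]) + 1)
  inpt <- centroid_set(voxel_to_um(idx, lab)[rep(1, 5), ],
                       space_tag = "reference")
  inpt <- assign_regions(inpt, at)
  pm1 <- patch_membership_fractions(inpt, ps, at)
  expect_equal(pm1$fractions$frac_in_patches, 1)
  expect_equal(pm1$shares$share, 1)
})
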