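# Shared fixtures built once per test run.

test_atlas <- make_toy_atlas(seed = 1)

# smooth intensity phantom on the atlas for registration tests
make_phantom <- function(atlas = test_atlas, seed = 5) {
  v <- atlas$labels$values
  ints <- withr::with_seed(seed, c(0, runif(nrow(atlas$regions), 0.2, 1)))
  ph <- array(ints[v + 1], dim(v))
  k <- inputmap:::gauss_kernel(1.5)
  ph <- inputmap:::conv_sep3_cpp(ph, dim(ph), k, k, k)
  voxel_grid(ph, atlas$labels$spacing, atlas$labels$origin)
}

test_phantom <- make_phantom()

# rotation angle (deg) of the closest rotation to a linear map
rotation_angle_deg <- function(A) {
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
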