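gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) {
    k <- -x / sigma^2 * g
    return(k - mean(k)) # exact zero sum
  }
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

# slice-wise separable 2D convolution of a 3D volume
conv2d_stack <- function(v, kx, ky) {
  conv_sep3_cpp(v, dim(v), kx, ky, 1)
}

feature_families <- c("gaussian", "laplacian_of_gaussian",
                      "gradient_magnitude", "difference_of_gaussians",
                      "structure_tensor_eig", "hessian_eig")

#' Per-pixel filter-bank features for cell classification
#'
#' Computes six feature families (Gaussian smoothing, Laplacian of Gaussian,
#' Gaussian gradient magnitude, difference of Gaussians, largest-magnitude
#' structure-tensor eigenvalue, largest-magnitude Hessian eigenvalue) at each
#' of the given radii — 6 x 3 = 18 values per pixel under the defaults.
#' Operators are 2D, applied slice by slice (segmentation is trained on
#' individual images and collapsed to 3D afterwards). Conventions: DoG is
#' `G(sigma) - G(1.6 sigma)`; the structure tensor uses gradients at
#' `sigma / 2` smoothed at `sigma`; eigenvalue families contribute the single
#' largest-magnitude eigenvalue so the printed feature count of 18 holds.
#'
#' @param grid a [voxel_grid()].
#' @param radii filter radii in pixels, default `c(0.7, 1.6, 5)`.
#' @return A `feature_stack`: a matrix of one row per voxel and one named
#'   column per (family, radius), plus the source geometry.
#' @export
compute_pixel_features <- function(grid, radii = c(0.7, 1.6, 5)) {
  stopifnot(inherits(grid, "voxel_grid"), all(radii > 0))
  v <- grid$values
  d <- dim(v)
  if (prod(d) == 0) stop("grid is empty", call. = FALSE)
  for (s in radii)
    if (2 * ceiling(3.5 * s) + 1 > 2 * min(d[1], d[2]))
      stop("radius ", s, " px exceeds the in-plane image extent", call. = FALSE)
  nfeat <- length(feature_families) * length(radii)
  out <- matrix(NA_real_, prod(d), nfeat)
  cn <- character(nfeat)
  col <- 0L
  for (s in radii) {
    g0 <- gauss_kernel(s, 0); g1 <- gauss_kernel(s, 1); g2 <- gauss_kernel(s, 2)
    gs <- conv2d_stack(v, g0, g0)
    gx <- conv2d_stack(v, g1, g0)
    gy <- conv2d_stack(v, g0, g1)
    gxx <- conv2d_stack(v, g2, g0)
    gyy <- conv2d_stack(v, g0, g2)
    gxy <- conv2d_stack(v, g1, g1)
    # structure tensor: gradients at inner scale s/2, tensor smoothed at s
    si <- s / 2
    h1 <- gauss_kernel(si, 1); h0 <- gauss_kernel(si, 0)
    jx <- conv2d_stack(v, h1, h0)
    jy <- conv2d_stack(v, h0, h1)
    jxx <- conv2d_stack(jx * jx, g0, g0)
    jyy <- conv2d_stack(jy * jy, g0, g0)
    jxy <- conv2d_stack(jx * jy, g0, g0)
    eig_max_mag <- function(a, b, c) {
      tr <- (a + c) / 2
      rad <- sqrt(((a - c) / 2)^2 + b^2)
      e1 <- tr + rad; e2 <- tr - rad
      ifelse(abs(e1) >= abs(e2), e1, e2)
    }
    st <- (jxx + jyy) / 2 + sqrt(((jxx - jyy) / 2)^2 + jxy^2) # PSD: top eig
    he <- eig_max_mag(gxx, gyy, gxy)
    gl <- gauss_kernel(1.6 * s, 0)
    dog <- gs - conv2d_stack(v, gl, gl)
    vals <- list(gaussian = gs, laplacian_of_gaussian = gxx + gyy,
                 gradient_magnitude = sqrt(gx^2 + gy^2),
                 difference_of_gaussians = dog,
                 structure_tensor_eig = st, hessian_eig = he)
    for (fam in feature_families) {
      col <- col + 1L
      out[, col] <- as.vector(vals[[fam]])
      cn[col] <- sprintf("%s_r%g", fam, s)
    }
  }
  colnames(out) <- cn
  structure(list(values = out, feature_names = cn, dims = d,
                 spacing = grid$spacing, origin = grid$origin),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("<feature_stack> ", ncol(x$values), " features x ",
      paste(x$dims, collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}
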