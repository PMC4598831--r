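#' Affine transform between native and reference space
#'
#' Maps native-space physical points (um) to reference space as
#' `p_ref = A %*% p_native + t`. The linear part must be invertible; the type
#' is closed under composition and inversion.
#'
#' @param A 3 x 3 linear part.
#' @param t length-3 translation (um).
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  t <- as.numeric(t)
  if (length(t) != 3 || any(!is.finite(A)) || any(!is.finite(t)))
    stop("affine transform parts must be finite", call. = FALSE)
  if (abs(det(A)) <= 1e-12)
    stop("linear part is singular (|det| <= 1e-12)", call. = FALSE)
  structure(list(A = A, t = t), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> det =", signif(det(x$A), 4),
      " t = (", paste(signif(x$t, 5), collapse = ", "), ") um\n")
  invisible(x)
}

#' Compose and invert affine transforms
#'
#' `compose_affine(b, a)` applies `a` first, then `b`.
#'
#' @param a,b [affine_transform()] objects.
#' @return An [affine_transform()].
#' @export
compose_affine <- function(b, a) {
  affine_transform(b$A %*% a$A, as.vector(b$A %*% a$t) + b$t)
}

#' @rdname compose_affine
#' @export
invert_affine <- function(a) {
  Ainv <- solve(a$A)
  affine_transform(Ainv, -as.vector(Ainv %*% a$t))
}

apply_affine_mat <- function(tform, pts) {
  sweep(pts %*% t(tform$A), 2, tform$t, `+`)
}

# build A = Rz Ry Rx * diag(scale) * shear from 12 parameters
affine_from_params <- function(shift_um = c(0, 0, 0), rot_deg = c(0, 0, 0),
                               scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  if (any(scale == 0)) stop("scale of 0 is singular", call. = FALSE)
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  affine_transform(Rz %*% Ry %*% Rx %*% diag(scale) %*% Sh, shift_um)
}

#' Serialize an affine transform to JSON
#'
#' Row-major matrix, translation, and the space direction, as a small JSON
#' file.
#'
#' @param tform an [affine_transform()].
#' @param path JSON path.
#' @return `read_affine()` returns an [affine_transform()].
#' @export
write_affine <- function(tform, path) {
  jsonlite::write_json(
    list(matrix_row_major = as.vector(t(tform$A)), translation_um = tform$t,
         from = "native", to = "reference"),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(m$matrix_row_major, 3, 3, byrow = TRUE), m$translation_um)
}

#' @export
tidy.affine_transform <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("A[", rep(1:3, each = 3), ",", rep(1:3, 3), "]"),
             paste0("t[", 1:3, "]")),
    estimate = c(as.vector(t(x$A)), x$t))
}
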