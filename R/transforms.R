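#' Planar affine alignment transforms
#'
#' Each serial section carries an invertible planar affine transform mapping
#' section-local pixel coordinates to global slide coordinates (micrometres).
#' Shortlisted ROI coordinates are translated to the global frame and the
#' inverse transform recovers local coordinates on neighboring sections, so
#' the same physical location can be revisited on every section.
#'
#' The transform is \code{global = A \%*\% local + t} with
#' \code{A = matrix(c(a, c, b, d), 2, 2)}; the six coefficients follow the
#' conventional \code{(a, b, tx, c, d, ty)} row-major order.
#'
#' @param a,b,c,d Linear part coefficients.
#' @param tx,ty Translation (global units, micrometres by convention).
#' @return An object of class \code{affine2d}.
#' @examples
#' tr <- affine2d(tx = 5, ty = -2)
#' to_global(c(1, 1), tr)
#' @export
affine2d <- function(a = 1, b = 0, tx = 0, c = 0, d = 1, ty = 0) {
  A <- matrix(c(a, c, b, d), 2L, 2L)
  det <- a * d - b * c
  if (!is.finite(det) || abs(det) < 1e-12)
    stop("singular transform: determinant is zero", call. = FALSE)
  structure(list(A = A, t = c(tx, ty)), class = "affine2d")
}

#' @describeIn affine2d Uniform scaling transform (e.g. pixel size in um/px).
#' @param s Scale factor.
#' @export
affine2d_scale <- function(s) affine2d(a = s, d = s)

#' @rdname affine2d
#' @param x An \code{affine2d} object.
#' @export
invert.affine2d <- function(x) {
  Ai <- solve(x$A)
  ti <- -Ai %*% x$t
  structure(list(A = Ai, t = as.vector(ti)), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d: [a b; c d] =", x$A[1, 1], x$A[1, 2], ";",
      x$A[2, 1], x$A[2, 2], " t =", x$t[1], x$t[2], "\n")
  invisible(x)
}

invert <- function(x) UseMethod("invert")

apply_affine <- function(pts, A, t) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  sweep(pts %*% t(A), 2L, -t)
}

#' Map points between section-local and global coordinates
#'
#' @param pts Numeric vector of length 2 or an n x 2 matrix of (x, y) points.
#' @param transform An [affine2d()] transform for the section.
#' @return Points in the other frame, same shape as the input.
#' @export
to_global <- function(pts, transform) {
  stopifnot(inherits(transform, "affine2d"))
  vec <- is.null(dim(pts))
  out <- apply_affine(pts, transform$A, transform$t)
  if (vec) drop(out) else out
}

#' @rdname to_global
#' @export
to_local <- function(pts, transform) {
  to_global(pts, invert.affine2d(transform))
}

#' Read or write per-section transforms as a JSON sidecar
#'
#' The sidecar is a JSON array with one object per section holding the six
#' affine coefficients \code{a, b, tx, c, d, ty}.
#'
#' @param transforms List of [affine2d()] objects, one per section.
#' @param path File path.
#' @export
write_transforms <- function(transforms, path) {
  rows <- lapply(transforms, function(tr) {
    list(a = tr$A[1, 1], b = tr$A[1, 2], tx = tr$t[1],
         c = tr$A[2, 1], d = tr$A[2, 2], ty = tr$t[2])
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(rows, function(r)
    affine2d(a = r$a, b = r$b, tx = r$tx, c = r$c, d = r$d, ty = r$ty))
}
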