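#' Affine transformation matrix
#'
#' A 2-D affine transform in homogeneous coordinates,
#' `[[a1, a2, a3], [a4, a5, a6], [0, 0, 1]]`, acting on column vectors
#' `(x, y, 1)'`. Throughout the package the transform maps output
#' coordinates to source coordinates (inverse mapping for resampling).
#'
#' @param params numeric length-6 vector `(a1..a6)`, or a 3x3 matrix whose
#'   last row is `(0, 0, 1)`.
#' @return object of class `c("affine_matrix", "transform2d")`.
#' @export
affine_matrix <- function(params = c(1, 0, 0, 0, 1, 0)) {
  if (is.matrix(params)) {
    if (!all(dim(params) == c(3L, 3L)) ||
        max(abs(params[3, ] - c(0, 0, 1))) > 1e-12) {
      stop("a 3x3 affine matrix must have last row (0, 0, 1)", call. = FALSE)
    }
    params <- c(params[1, ], params[2, ])
  }
  if (length(params) != 6L || !all(is.finite(params))) {
    stop("affine parameters must be 6 finite numbers", call. = FALSE)
  }
  structure(list(params = as.numeric(params)),
            class = c("affine_matrix", "transform2d"))
}

#' Euclidean (rigid-body) transformation
#'
#' The 3-parameter restriction of the affine transform to rotation plus
#' translation: `[[cos t, -sin t, e1], [sin t, cos t, e2], [0, 0, 1]]`.
#'
#' @param theta rotation in radians, wrapped to `(-pi, pi]`.
#' @param e1 x-translation in pixels.
#' @param e2 y-translation in pixels.
#' @return object of class `c("euclidean_matrix", "transform2d")`.
#' @export
euclidean_matrix <- function(theta = 0, e1 = 0, e2 = 0) {
  if (!all(is.finite(c(theta, e1, e2)))) stop("parameters must be finite", call. = FALSE)
  theta <- ((theta + pi) %% (2 * pi)) - pi
  if (theta == -pi) theta <- pi
  structure(list(theta = theta, e1 = e1, e2 = e2),
            class = c("euclidean_matrix", "transform2d"))
}

#' @export
as.matrix.affine_matrix <- function(x, ...) {
  p <- x$params
  matrix(c(p[1], p[2], p[3], p[4], p[5], p[6], 0, 0, 1), 3L, 3L, byrow = TRUE)
}

#' @export
as.matrix.euclidean_matrix <- function(x, ...) {
  matrix(c(cos(x$theta), -sin(x$theta), x$e1,
           sin(x$theta),  cos(x$theta), x$e2,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

# 6-parameter row (a1..a6) for the C++ kernels
transform_params6 <- function(x) {
  m <- as.matrix(x)
  c(m[1, ], m[2, ])
}

#' Apply a 2-D transform to points
#'
#' @param transform an `affine_matrix`, `euclidean_matrix`, or plain 3x3
#'   matrix.
#' @param pts `n x 2` matrix of `(x, y)` coordinates (0-based pixel units).
#' @return `n x 2` matrix of transformed coordinates.
#' @export
transform_points <- function(transform, pts) {
  m <- if (is.matrix(transform)) transform else as.matrix(transform)
  pts <- rbind(t(pts), 1)
  out <- m %*% pts
  t(out[1:2, , drop = FALSE])
}

#' @export
print.affine_matrix <- function(x, ...) {
  cat("<affine_matrix>\n"); print(as.matrix(x)); invisible(x)
}

#' @export
print.euclidean_matrix <- function(x, ...) {
  cat(sprintf("<euclidean_matrix> theta=%.6g rad, e1=%.6g px, e2=%.6g px\n",
              x$theta, x$e1, x$e2))
  invisible(x)
}

# determinant of the 2x2 linear part
linear_det <- function(x) {
  m <- as.matrix(x)
  m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
}

transform_to_list <- function(x) {
  list(model = if (inherits(x, "euclidean_matrix")) "euclidean" else "affine",
       matrix = as.vector(t(as.matrix(x))))  # row-major 3x3
}

transform_from_list <- function(l) {
  m <- matrix(unlist(l$matrix), 3L, 3L, byrow = TRUE)
  if (identical(l$model, "euclidean")) {
    euclidean_matrix(atan2(m[2, 1], m[1, 1]), m[1, 3], m[2, 3])
  } else {
    affine_matrix(m)
  }
}

#' Serialize transforms to JSON
#'
#' Transforms are stored row-major as 3x3 matrices together with a model tag
#' (`"affine"` or `"euclidean"`).
#'
#' @param transforms a single transform or a list of transforms.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path) {
  if (inherits(transforms, "transform2d")) transforms <- list(transforms)
  jsonlite::write_json(lapply(transforms, transform_to_list), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read transforms written by [write_transforms()]
#' @param path JSON path.
#' @return list of transforms.
#' @export
read_transforms <- function(path) {
  lapply(jsonlite::read_json(path), transform_from_list)
}
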