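#' Neck cutting plane
#'
#' The physician-style cutting plane separating the aneurysm sac from its
#' parent vessel, encoded as a point (the neck-curve centroid, mm) and a
#' unit normal pointing from the vessel toward the sac dome.
#'
#' @param point numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3 unit vector; its norm must be 1 within
#'   `1e-9` (a non-unit vector of positive length is normalized with a
#'   warning only when `normalize = TRUE`).
#' @param normalize if `TRUE`, rescale `normal` to unit length.
#' @return an object of class `neck_plane`.
#' @export
neck_plane <- function(point, normal, normalize = FALSE) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("point and normal must have length 3")
  if (!all(is.finite(c(point, normal)))) stop("non-finite plane parameters")
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be non-zero")
  if (normalize) normal <- normal / nn
  else if (abs(nn - 1) > 1e-9)
    stop(sprintf("plane normal must be unit length (|n| = %.12g)", nn))
  structure(list(point = point, normal = normal), class = "neck_plane")
}

#' @export
print.neck_plane <- function(x, ...) {
  cat(sprintf("neck_plane: point (%.4g, %.4g, %.4g) mm, normal (%.4g, %.4g, %.4g)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Read a neck plane from JSON
#'
#' Expects `{"point": [x,y,z], "normal": [nx,ny,nz]}` in millimetres.
#'
#' @param path path to a JSON file.
#' @return a [neck_plane()].
#' @export
read_neck_plane <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$point) || is.null(obj$normal))
    stop(sprintf("'%s' must contain 'point' and 'normal'", path))
  neck_plane(obj$point, obj$normal)
}

#' Write a neck plane to JSON
#'
#' @param plane a [neck_plane()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_neck_plane <- function(plane, path) {
  jsonlite::write_json(list(point = plane$point, normal = plane$normal),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# Signed perpendicular distances of mesh vertices to a plane (mm).
plane_distances <- function(vertices, plane) {
  as.vector(sweep(vertices, 2, plane$point) %*% plane$normal)
}
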