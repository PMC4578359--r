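#' Aneurysm perpendicular height
#'
#' Maximum signed perpendicular distance from the neck plane to the sac
#' surface — the distance from the plane to the aneurysmal dome apex.
#'
#' @param sac sac [triangle_mesh()] (the part of the surface on the side
#'   the plane normal points to).
#' @param plane the [neck_plane()].
#' @return perpendicular height h (mm).
#' @export
compute_height <- function(sac, plane) {
  if (!inherits(sac, "triangle_mesh") || nrow(sac$vertices) == 0L)
    stop("sac mesh is empty")
  h <- max(plane_distances(sac$vertices, plane))
  if (h <= 0) stop("sac on wrong side of plane (flip the plane normal?)")
  h
}

#' Aneurysm neck diameter
#'
#' Effective circular diameter of the neck outline: `2 * sqrt(A / pi)`
#' where `A` is the polygon area of the closed neck curve. Exact for a
#' circular neck and robust to irregular outlines.
#'
#' @param neck_curve ordered closed planar polyline (matrix, mm), e.g. the
#'   `neck_curve` of [split_at_plane()].
#' @return neck diameter D_n (mm).
#' @export
compute_neck_diameter <- function(neck_curve) {
  neck_curve <- as.matrix(neck_curve)
  if (nrow(neck_curve) < 3L) stop("neck curve must have at least 3 vertices")
  a <- polygon_area(neck_curve)
  if (a <= 0) stop("degenerate neck curve (zero enclosed area)")
  2 * sqrt(a / pi)
}

#' Aspect ratio
#'
#' Aneurysm aspect ratio: perpendicular height divided by neck diameter.
#'
#' @param h perpendicular height (mm), positive.
#' @param D_n neck diameter (mm), positive.
#' @return dimensionless aspect ratio `h / D_n`.
#' @export
compute_AR <- function(h, D_n) {
  if (!is.finite(h) || h <= 0) stop("height must be positive")
  if (!is.finite(D_n) || D_n <= 0) stop("neck diameter must be positive")
  h / D_n
}

#' Aneurysm sac volume
#'
#' Volume enclosed by the sac surface capped at the neck plane, computed by
#' the divergence-theorem sum over signed tetrahedra. Face orientation is
#' repaired (by global sign) before integration.
#'
#' @param sac sac [triangle_mesh()] with a single boundary loop (the neck).
#' @param plane the [neck_plane()] (used for validation of the boundary).
#' @return sac volume V_A (mm^3).
#' @export
compute_sac_volume <- function(sac, plane) {
  if (!inherits(sac, "triangle_mesh") || nrow(sac$faces) == 0L)
    stop("sac mesh is empty")
  loops <- boundary_loops(sac)
  if (length(loops) != 1L)
    stop(sprintf("sac must have exactly one boundary loop (found %d)",
                 length(loops)))
  curve <- sac$vertices[loops[[1]], , drop = FALSE]
  if (!missing(plane) && !is.null(plane)) {
    if (max(abs(plane_distances(curve, plane))) > 1e-6)
      stop("sac boundary loop does not lie on the neck plane")
  }
  capped <- cap_opening(sac, curve)
  if (!is_watertight(capped))
    stop("capped sac is not watertight; cannot integrate volume")
  v <- abs(mesh_volume(capped))
  if (v <= 0) stop("sac volume is not positive")
  v
}

#' Full morphometry of an aneurysm model
#'
#' Splits the mesh at the neck plane and computes the morphological
#' parameters: perpendicular height h, neck diameter D_n, aspect ratio
#' AR = h / D_n, sac volume V_A, and the neck-curve centroid (the centre
#' used by the graded scaling transform).
#'
#' @param mesh combined aneurysm + parent-vessel [triangle_mesh()].
#' @param plane the [neck_plane()].
#' @return list of class `aneurysm_morphometry` with elements `h`, `D_n`,
#'   `AR`, `V_A` (mm, mm, unitless, mm^3) and `neck_centroid` (mm).
#' @export
morphometry <- function(mesh, plane) {
  parts <- split_at_plane(mesh, plane)
  h <- compute_height(parts$sac, plane)
  dn <- compute_neck_diameter(parts$neck_curve)
  structure(list(h = h,
                 D_n = dn,
                 AR = compute_AR(h, dn),
                 V_A = compute_sac_volume(parts$sac, plane),
                 neck_centroid = polygon_centroid(parts$neck_curve)),
            class = "aneurysm_morphometry")
}

#' @export
print.aneurysm_morphometry <- function(x, ...) {
  cat(sprintf(paste0("aneurysm morphometry:\n  height h      %8.4f mm\n",
                     "  neck D_n      %8.4f mm\n  aspect ratio  %8.4f\n",
                     "  sac volume    %8.4f mm^3\n"),
              x$h, x$D_n, x$AR, x$V_A))
  invisible(x)
}
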