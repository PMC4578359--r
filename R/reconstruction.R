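#' Reconstruct the pre-aneurysm parent vessel
#'
#' Builds the hypothetical vessel before aneurysm formation by removing
#' the sac at the neck plane and closing the neck opening with a flat
#' planar cap (deterministic fan triangulation). The vessel lateral
#' surface below the plane and the inlet/outlet boundary loops are left
#' bit-identical, so with-aneurysm and pre-aneurysm flow conditions remain
#' comparable. Optional Laplacian smoothing is restricted to the cap
#' vertices and their one-ring neighbourhood.
#'
#' @param mesh combined aneurysm + vessel [triangle_mesh()].
#' @param plane the [neck_plane()].
#' @param smooth_iterations number of Laplacian smoothing passes over the
#'   cap region (default 0: the cap stays exactly planar).
#' @return the reconstructed vessel [triangle_mesh()].
#' @export
make_pre_aneurysm <- function(mesh, plane, smooth_iterations = 0L) {
  parts <- split_at_plane(mesh, plane)
  out <- cap_opening(parts$vessel, parts$neck_curve)
  if (smooth_iterations > 0L) {
    out <- smooth_region(out, cap_region_vertices(out, parts$neck_curve),
                         iterations = smooth_iterations)
  }
  out
}

# Vertex indices of the cap (loop + centroid) and their one-ring.
cap_region_vertices <- function(mesh, neck_curve) {
  v <- mesh$vertices
  sel <- logical(nrow(v))
  for (i in seq_len(nrow(neck_curve))) {
    d2 <- (v[, 1] - neck_curve[i, 1])^2 + (v[, 2] - neck_curve[i, 2])^2 +
      (v[, 3] - neck_curve[i, 3])^2
    sel[which.min(d2)] <- TRUE
  }
  sel[nrow(v)] <- TRUE                      # fan centroid (appended last)
  e <- directed_edges(mesh)
  ring <- unique(c(e[sel[e[, 1]], 2], e[sel[e[, 2]], 1]))
  sel[ring] <- TRUE
  which(sel)
}

smooth_region <- function(mesh, region, iterations = 1L) {
  e <- directed_edges(mesh)
  nbr <- split(e[, 2], e[, 1])
  bnd <- unique(unlist(boundary_loops(mesh)))
  region <- setdiff(region, bnd)            # never move inlet/outlet rims
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    upd <- v
    for (i in region) {
      nb <- nbr[[as.character(i)]]
      if (length(nb) > 0L) upd[i, ] <- colMeans(v[nb, , drop = FALSE])
    }
    v <- upd
  }
  mesh$vertices <- v
  mesh
}
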