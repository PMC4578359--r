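#' Triangle surface mesh
#'
#' Indexed triangle surface in millimetre coordinates: the geometric
#' substrate for all neck-plane, morphometry and scaling operations.
#' Vertices carrying an optional tag record whether they belong to the
#' aneurysm sac, the parent vessel, or the neck curve.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param tags optional character vector, one of `"sac"`, `"vessel"`,
#'   `"neck"` (or `NA`) per vertex.
#' @param validate if `TRUE`, check finiteness and index ranges and drop
#'   degenerate (zero-area) faces.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `tags`.
#' @export
triangle_mesh <- function(vertices, faces, tags = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!is.null(tags) && length(tags) != nrow(vertices))
    stop("tags must have one entry per vertex")
  m <- structure(list(vertices = vertices, faces = faces, tags = tags),
                 class = "triangle_mesh")
  if (validate) m <- validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L) stop("mesh has no vertices")
  if (!all(is.finite(v))) stop("mesh has non-finite coordinates")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
    a <- face_areas(mesh)
    if (any(a == 0)) {
      mesh$faces <- f[a > 0, , drop = FALSE]
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  bl <- tryCatch(length(boundary_loops(x)), error = function(e) NA_integer_)
  if (!is.na(bl)) {
    cat(if (bl == 0L) ", watertight" else sprintf(", %d boundary loop(s)", bl))
  }
  cat("\n")
  invisible(x)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  cross3(v[f[, 2], , drop = FALSE] - p1, v[f[, 3], , drop = FALSE] - p1)
}

face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(numeric(0))
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return total triangle area (mm^2).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume of a mesh
#'
#' Divergence-theorem sum of signed tetrahedra spanned by each face and the
#' origin. Positive for a watertight mesh with outward-oriented faces.
#'
#' @param mesh a [triangle_mesh()].
#' @return signed volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1 * cross3(p2, p3)) / 6
}

directed_edges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent orientation).
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  e <- directed_edges(mesh)
  dkey <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dkey)) return(FALSE)      # inconsistent orientation
  ukey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(ukey) == 2L)
}

#' Boundary loops of an open mesh
#'
#' Boundary edges (edges used by exactly one face) chained into closed
#' loops, each returned as an ordered vector of vertex indices.
#'
#' @param mesh a [triangle_mesh()].
#' @return list of integer vectors, one per closed boundary loop.
#' @export
boundary_loops <- function(mesh) {
  e <- directed_edges(mesh)
  ukey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ukey)
  bnd <- e[cnt[ukey] == 1L, , drop = FALSE]
  if (nrow(bnd) == 0L) return(list())
  chain_segments(bnd, what = "boundary")
}

# Chain a set of directed or undirected segments (2-column index matrix)
# into closed loops; errors if any endpoint is not of degree 2.
chain_segments <- function(seg, what = "intersection") {
  nxt <- split(seq_len(nrow(seg)), seg[, 1])
  prv <- split(seq_len(nrow(seg)), seg[, 2])
  deg <- table(c(seg[, 1], seg[, 2]))
  if (any(deg != 2L))
    stop(sprintf("open %s curve: %d endpoint(s) of odd degree",
                 what, sum(deg != 2L)))
  used <- rep(FALSE, nrow(seg))
  loops <- list()
  repeat {
    start <- which(!used)[1]
    if (is.na(start)) break
    loop <- integer(0)
    i <- start
    v <- seg[i, 1]
    repeat {
      used[i] <- TRUE
      loop <- c(loop, v)
      v <- if (seg[i, 1] == v) seg[i, 2] else seg[i, 1]
      cand <- c(nxt[[as.character(v)]], prv[[as.character(v)]])
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      i <- cand[1]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Merge duplicate vertices
#'
#' Collapses vertices closer than `tol` (on a rounding grid) to a single
#' vertex and remaps faces; reconstructs shared topology from STL triangle
#' soup deterministically.
#'
#' @param mesh a [triangle_mesh()].
#' @param tol merge tolerance (mm), default `1e-6`.
#' @return a [triangle_mesh()] with unique vertices.
#' @export
merge_duplicate_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3)
  tags <- if (!is.null(mesh$tags)) mesh$tags[first] else NULL
  triangle_mesh(newv, newf, tags = tags, validate = TRUE)
}

# Extract the sub-mesh spanned by a subset of faces, compacting vertex
# indices. `extra_tags` optionally overrides tags by original vertex index.
submesh <- function(vertices, faces, tags = NULL) {
  ids <- sort(unique(as.vector(faces)))
  map <- integer(nrow(vertices))
  map[ids] <- seq_along(ids)
  triangle_mesh(vertices[ids, , drop = FALSE],
                matrix(map[faces], ncol = 3),
                tags = if (!is.null(tags)) tags[ids] else NULL,
                validate = FALSE)
}
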