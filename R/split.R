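#' Split a mesh at the neck plane
#'
#' Separates the aneurysm sac from the parent vessel along a cutting plane.
#' Faces straddling the plane are split by exact linear interpolation along
#' their edges; every vertex so created is projected onto the plane, and
#' the union of the two parts reproduces the input surface area. Vertices
#' lying on the plane (|signed distance| below `on_tol`) are assigned to
#' the vessel side and tagged `"neck"` — the graded scaling transform
#' applies strictly above the plane, so the neck curve must remain with the
#' unscaled part.
#'
#' @param mesh a [triangle_mesh()].
#' @param plane a [neck_plane()]; the sac is the side the normal points to.
#' @param on_tol on-plane tolerance in mm (default `1e-9`).
#' @return list with elements `sac` and `vessel` ([triangle_mesh()]s) and
#'   `neck_curve`, an ordered closed polyline (matrix, one row per vertex,
#'   first vertex not repeated) lying on the plane.
#' @export
split_at_plane <- function(mesh, plane, on_tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- plane_distances(v, plane)
  side <- integer(nrow(v))
  side[d > on_tol] <- 1L
  side[d < -on_tol] <- -1L

  s <- matrix(side[f], ncol = 3)
  smax <- pmax(s[, 1], s[, 2], s[, 3])
  smin <- pmin(s[, 1], s[, 2], s[, 3])
  straddle <- smax == 1L & smin == -1L
  if (!any(straddle)) {
    if (all(smax <= 0L) || all(smin >= 0L))
      stop("no intersection: the plane does not cut the mesh")
    stop("no intersection: the plane only touches the mesh at vertices/edges")
  }
  if (!any(smin == 1L) || !any(smax == -1L))
    stop("no intersection: the plane does not cut the mesh transversally")

  sac_faces <- f[!straddle & smax == 1L & smin >= 0L, , drop = FALSE]
  ves_faces <- f[!straddle & !(smax == 1L & smin >= 0L), , drop = FALSE]

  # split straddling faces; crossing vertices are cached per undirected
  # edge so adjacent faces share them exactly
  n0 <- nrow(v)
  new_pts <- list()
  cross_id <- new.env(hash = TRUE, parent = emptyenv())
  get_crossing <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- cross_id[[key]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    p <- p - sum((p - plane$point) * plane$normal) * plane$normal
    new_pts[[length(new_pts) + 1L]] <<- p
    id <- n0 + length(new_pts)
    cross_id[[key]] <- id
    id
  }

  extra_sac <- list()
  extra_ves <- list()
  segs <- list()
  for (fi in which(straddle)) {
    tri <- f[fi, ]
    pos <- integer(0)
    neg <- integer(0)
    onp <- integer(0)
    for (e in 1:3) {
      i <- tri[e]
      j <- tri[e %% 3L + 1L]
      si <- side[i]
      sj <- side[j]
      if (si >= 0L) pos <- c(pos, i)
      if (si <= 0L) neg <- c(neg, i)
      if (si == 0L) onp <- c(onp, i)
      if (si * sj < 0L) {
        id <- get_crossing(i, j)
        pos <- c(pos, id)
        neg <- c(neg, id)
        onp <- c(onp, id)
      }
    }
    fan <- function(poly) {
      if (length(poly) < 3L) return(NULL)
      cbind(poly[1], poly[2:(length(poly) - 1L)], poly[3:length(poly)])
    }
    extra_sac[[length(extra_sac) + 1L]] <- fan(pos)
    extra_ves[[length(extra_ves) + 1L]] <- fan(neg)
    onp <- unique(onp)
    if (length(onp) == 2L) segs[[length(segs) + 1L]] <- onp
  }

  allv <- rbind(v, do.call(rbind, new_pts))
  side <- c(side, rep(0L, length(new_pts)))
  sac_faces <- rbind(sac_faces, do.call(rbind, extra_sac))
  ves_faces <- rbind(ves_faces, do.call(rbind, extra_ves))

  seg <- do.call(rbind, segs)
  seg_len <- sqrt(rowSums((allv[seg[, 1], , drop = FALSE] -
                           allv[seg[, 2], , drop = FALSE])^2))
  seg <- seg[seg_len > on_tol, , drop = FALSE]
  seg <- unique(cbind(pmin(seg[, 1], seg[, 2]), pmax(seg[, 1], seg[, 2])))
  loops <- chain_segments(seg, what = "neck intersection")
  if (length(loops) != 1L)
    stop(sprintf("ambiguous neck: plane intersection yields %d closed loops",
                 length(loops)))
  curve <- allv[loops[[1]], , drop = FALSE]

  tags <- ifelse(side == 0L, "neck", ifelse(side > 0L, "sac", "vessel"))
  list(sac = drop_degenerate(submesh(allv, sac_faces, tags)),
       vessel = drop_degenerate(submesh(allv, ves_faces, tags)),
       neck_curve = curve)
}

drop_degenerate <- function(mesh) {
  a <- face_areas(mesh)
  if (any(a == 0)) mesh$faces <- mesh$faces[a > 0, , drop = FALSE]
  mesh
}

#' Cap a planar opening of a mesh
#'
#' Closes a single planar boundary loop with a triangle fan around the loop
#' centroid, oriented consistently with the surrounding surface. The added
#' area equals the polygon area of the loop.
#'
#' @param mesh a [triangle_mesh()] with an open boundary along `boundary`.
#' @param boundary ordered closed polyline (matrix, one row per vertex, mm)
#'   lying on a plane; typically the `neck_curve` from [split_at_plane()].
#' @return a [triangle_mesh()] with the opening closed.
#' @export
cap_opening <- function(mesh, boundary) {
  boundary <- as.matrix(boundary)
  k <- nrow(boundary)
  if (k < 3L) stop("boundary loop must have at least 3 vertices")
  key <- paste(round(boundary[, 1] / 1e-9), round(boundary[, 2] / 1e-9),
               round(boundary[, 3] / 1e-9))
  if (anyDuplicated(key))
    stop("boundary loop has a repeated vertex")
  ctr <- colMeans(boundary)
  nrm <- polygon_normal(boundary)
  if (max(abs(sweep(boundary, 2, ctr) %*% nrm)) > 1e-6)
    stop("boundary loop is not planar")

  # match loop points to mesh vertices
  idx <- integer(k)
  v <- mesh$vertices
  for (i in seq_len(k)) {
    d2 <- (v[, 1] - boundary[i, 1])^2 + (v[, 2] - boundary[i, 2])^2 +
      (v[, 3] - boundary[i, 3])^2
    j <- which.min(d2)
    if (d2[j] > 1e-12) stop("boundary loop vertex not found on the mesh")
    idx[i] <- j
  }

  # orient the fan so each boundary edge is traversed opposite to its
  # (single) incident mesh face
  e <- directed_edges(mesh)
  dkey <- paste(e[, 1], e[, 2])
  loop_fwd <- paste(idx, c(idx[-1], idx[1]))
  if (any(loop_fwd %in% dkey)) idx <- rev(idx)

  cid <- nrow(v) + 1L
  nxt <- c(idx[-1], idx[1])
  cap_faces <- cbind(rep(cid, k), idx, nxt)
  tags <- mesh$tags
  if (!is.null(tags)) tags <- c(tags, "neck")
  triangle_mesh(rbind(v, ctr), rbind(mesh$faces, cap_faces), tags = tags,
                validate = FALSE)
}

# Newell's method: unit normal of a (near-)planar polygon.
polygon_normal <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  n <- colSums(cross3(poly, nxt))
  len <- sqrt(sum(n^2))
  if (len == 0) stop("degenerate boundary loop")
  n / len
}

# Area of a planar polygon in 3-D (Newell).
polygon_area <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  0.5 * sqrt(sum(colSums(cross3(poly, nxt))^2))
}

# Area-weighted centroid of a planar polygon (fan about the vertex mean).
polygon_centroid <- function(poly) {
  m <- colMeans(poly)
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  a <- sweep(poly, 2, m)
  b <- sweep(nxt, 2, m)
  cr <- cross3(a, b)
  nrm <- polygon_normal(poly)
  w <- 0.5 * as.vector(cr %*% nrm)          # signed triangle areas
  tc <- (a + b) / 3                          # triangle centroids minus m
  m + colSums(tc * w) / sum(w)
}
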