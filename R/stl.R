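#' Read a surface mesh from an STL file
#'
#' Reads ASCII or binary stereolithography files. STL stores an unindexed
#' triangle soup; duplicate vertices within the merge tolerance are
#' collapsed to reconstruct shared topology.
#'
#' @param path path to an `.stl` file.
#' @param format `"auto"` (default, sniffed from the file), `"stl-ascii"`
#'   or `"stl-binary"`.
#' @param merge_tol duplicate-vertex merge tolerance in mm (default `1e-6`).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl-ascii", "stl-binary"),
                      merge_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") format <- sniff_stl_format(path)
  tri <- switch(format,
                "stl-ascii" = read_stl_ascii(path),
                "stl-binary" = read_stl_binary(path))
  if (nrow(tri) == 0L) stop(sprintf("'%s' contains no facets", path))
  nf <- nrow(tri) / 3L
  soup <- triangle_mesh(tri, matrix(seq_len(3L * nf), ncol = 3, byrow = TRUE),
                        validate = FALSE)
  merge_duplicate_vertices(soup, tol = merge_tol)
}

sniff_stl_format <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  txt <- rawToChar(head[head != as.raw(0)])
  # a binary file may still start with "solid"; require facet syntax
  if (grepl("^\\s*solid", txt, useBytes = TRUE) &&
      grepl("facet", txt, fixed = TRUE, useBytes = TRUE)) "stl-ascii"
  else "stl-binary"
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L) stop(sprintf("'%s' is not a valid ASCII STL", path))
  if (length(vl) %% 3L != 0L)
    stop(sprintf("'%s': vertex count not a multiple of 3", path))
  xyz <- strsplit(trimws(vl), "\\s+")
  bad <- vapply(xyz, length, 1L) != 4L
  if (any(bad)) stop(sprintf("'%s': malformed vertex line", path))
  m <- matrix(as.numeric(unlist(lapply(xyz, `[`, 2:4))), ncol = 3,
              byrow = TRUE)
  if (!all(is.finite(m))) stop(sprintf("'%s': non-numeric vertex", path))
  m
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 84L) stop(sprintf("'%s' is not a valid binary STL", path))
  nf <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (nf <= 0L || length(raw) < 84L + 50 * nf)
    stop(sprintf("'%s': truncated binary STL (declares %d facets)", path, nf))
  # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16
  idx <- as.vector(outer(1:48, (seq_len(nf) - 1L) * 50L, `+`)) + 84L
  fl <- readBin(raw[idx], "numeric", size = 4L, n = 12L * nf,
                endian = "little")
  rec <- matrix(fl, nrow = 12L)          # columns are facets
  tri <- matrix(as.vector(rec[4:12, ]), ncol = 3, byrow = TRUE)
  if (!all(is.finite(tri))) stop(sprintf("'%s': non-finite vertex", path))
  tri
}

#' Write a surface mesh to an STL file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"stl-binary"` (default) or `"stl-ascii"`. Binary STL
#'   stores float32 coordinates; round-trips preserve coordinates to that
#'   precision.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("stl-binary", "stl-ascii")) {
  format <- match.arg(format)
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_cross(mesh)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (format == "stl-ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid aneuscale", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9e %.9e %.9e", p[1], p[2], p[3]),
                   con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid aneuscale", con)
  } else {
    nf <- nrow(f)
    # per facet: 12 float32 (normal, v1, v2, v3) then a zero uint16
    vals <- rbind(t(nrm), t(v[f[, 1], , drop = FALSE]),
                  t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    fl <- writeBin(as.vector(vals), raw(), size = 4L, endian = "little")
    rec <- raw(50L * nf)
    rec[as.vector(outer(1:48, (seq_len(nf) - 1L) * 50L, `+`))] <- fl
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    writeBin(rec, con)
  }
  invisible(path)
}
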