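#' Rigid alignment of the neck plane to the XY plane
#'
#' Builds the rigid transformation that rotates the neck-plane normal onto
#' the +Z axis and translates the plane point to the origin, so that the
#' neck plane becomes z = 0. The rotation is composed from rotations about
#' X (theta) and Y (omega); no rotation about Z is needed (phi = 0).
#'
#' @param plane a [neck_plane()].
#' @return object of class `rigid_alignment` with rotation angles `theta`,
#'   `omega`, `phi` (rad), translation components `p`, `q`, `r` (mm), the
#'   3x3 rotation block `R` and the 4x4 homogeneous `matrix`.
#' @export
neck_alignment_transform <- function(plane) {
  n <- plane$normal
  s <- sqrt(n[2]^2 + n[3]^2)
  theta <- atan2(n[2], n[3])     # about X: zero the y-component
  omega <- atan2(-n[1], s)       # about Y: bring onto +Z
  R <- rot_y(omega) %*% rot_x(theta)
  t <- as.vector(-R %*% plane$point)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  structure(list(theta = theta, omega = omega, phi = 0,
                 p = t[1], q = t[2], r = t[3], R = R, matrix = m),
            class = "rigid_alignment")
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)),
                            3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                            3, 3)

#' Apply (or invert) a rigid alignment to a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param alignment a `rigid_alignment` from [neck_alignment_transform()].
#' @param inverse if `TRUE`, apply the inverse transform.
#' @return the transformed [triangle_mesh()]; all pairwise distances are
#'   preserved.
#' @export
apply_rigid <- function(mesh, alignment, inverse = FALSE) {
  if (!inherits(alignment, "rigid_alignment")) stop("not a rigid_alignment")
  v <- mesh$vertices
  t <- c(alignment$p, alignment$q, alignment$r)
  vv <- if (inverse) {
    sweep(v, 2, t) %*% alignment$R            # R^-1 = R^T: x = R'(y - t)
  } else {
    sweep(v %*% t(alignment$R), 2, t, `+`)
  }
  mesh$vertices <- vv
  mesh
}

# Apply the alignment to bare points (rows).
apply_rigid_points <- function(pts, alignment, inverse = FALSE) {
  t <- c(alignment$p, alignment$q, alignment$r)
  if (inverse) sweep(pts, 2, t) %*% alignment$R
  else sweep(pts %*% t(alignment$R), 2, t, `+`)
}

#' Solve the scaling factor for a target aspect ratio
#'
#' The graded transform leaves the parent artery and the aneurysmal neck
#' unchanged, so retargeting the aspect ratio reduces to retargeting the
#' perpendicular height. The axial map of the graded transform is
#' `zeta -> zeta * (1 + zeta (k - 1) / h)` (`zeta` = height above the neck
#' plane): for height ratios `r = AR_target / AR_current >= 1/2` the dome
#' apex stays the highest point and `k = r` is exact; for `1/4 < r < 1/2`
#' the axial map has an interior maximum `h / (4 (1 - k))`, so the
#' height-exact factor is `k = 1 - 1 / (4 r)`. Ratios at or below 1/4 are
#' unattainable with positive scaling factors.
#'
#' @param AR_current measured aspect ratio of the input model (> 0).
#' @param AR_target desired aspect ratio (> 0).
#' @return scaling factor k such that the re-measured height of the scaled
#'   model is `AR_target / AR_current` times the input height.
#' @export
solve_scaling_factor <- function(AR_current, AR_target) {
  if (!is.finite(AR_current) || AR_current <= 0)
    stop("AR_current must be positive")
  if (!is.finite(AR_target) || AR_target <= 0)
    stop("AR_target must be positive")
  r <- AR_target / AR_current
  if (r >= 0.5) return(r)
  if (r <= 0.25)
    stop(sprintf(paste0("target AR ratio %.4g is unattainable: the graded",
                        " transform cannot reduce the height below 1/4 of",
                        " the original"), r))
  1 - 1 / (4 * r)
}

#' Scaling specification for the graded sac transform
#'
#' @param k scaling factor (> 0).
#' @param a,b transverse scaling coefficients along x and y (default 1:
#'   the dome scales isotropically at the apex). The axial direction
#'   carries no coefficient.
#' @param h perpendicular height of the sac above the neck plane (mm).
#' @param neck_centroid geometric centre (x_m, y_m, z_m) of the neck curve
#'   (mm); the transform scales offsets from this point.
#' @return object of class `scaling_spec`.
#' @export
scaling_spec <- function(k, a = 1, b = 1, h, neck_centroid) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  neck_centroid <- as.numeric(neck_centroid)
  if (length(neck_centroid) != 3L) stop("neck_centroid must have length 3")
  structure(list(k = k, a = a, b = b, h = h, neck_centroid = neck_centroid,
                 z_m = neck_centroid[3]),
            class = "scaling_spec")
}

#' Graded scaling of the aneurysm sac
#'
#' Applies the height-graded linear scaling to every vertex strictly above
#' the neck plane (z > z_m, in a frame where the neck plane is
#' z = z_m): offsets from the neck centre (x_m, y_m, z_m) are multiplied
#' by `1 + a (z - z_m)(k - 1)/h` in x, `1 + b (z - z_m)(k - 1)/h` in y and
#' `1 + (z - z_m)(k - 1)/h` in z, then the centre offset is added back.
#' The per-vertex expansion factor grows from 1 at the neck to k at the
#' dome, so the parent artery and the neck are left bit-identical and the
#' expansion rate increases monotonically from neck to fundus.
#'
#' @param mesh a [triangle_mesh()] whose neck plane is parallel to XY
#'   (align first with [neck_alignment_transform()] / [apply_rigid()]).
#' @param plane the [neck_plane()]; its normal must be (0, 0, 1) within
#'   `1e-6`.
#' @param spec a [scaling_spec()].
#' @param on_tol on-plane tolerance (mm); vertices with
#'   `z <= z_m + on_tol` are left untouched.
#' @return the scaled [triangle_mesh()]; topology is unchanged.
#' @export
scale_sac <- function(mesh, plane, spec, on_tol = 1e-9) {
  if (!inherits(spec, "scaling_spec")) stop("spec must be a scaling_spec")
  if (max(abs(plane$normal - c(0, 0, 1))) > 1e-6)
    stop("mesh must be aligned: plane normal must be (0, 0, 1)")
  v <- mesh$vertices
  zm <- spec$z_m
  if (abs(plane$point[3] - zm) > 1e-6)
    stop("spec neck_centroid is not on the neck plane")
  zeta <- v[, 3] - zm
  up <- zeta > on_tol
  if (!any(up)) return(mesh)
  g <- zeta[up] * (spec$k - 1) / spec$h
  fx <- 1 + spec$a * g
  fy <- 1 + spec$b * g
  fz <- 1 + g
  if (min(fx, fy, fz) <= 0)
    stop("transform inverts geometry: a scaling factor is non-positive")
  ctr <- spec$neck_centroid
  v[up, 1] <- ctr[1] + fx * (v[up, 1] - ctr[1])
  v[up, 2] <- ctr[2] + fy * (v[up, 2] - ctr[2])
  v[up, 3] <- zm + fz * zeta[up]
  mesh$vertices <- v
  mesh
}

#' Paper-style series of target aspect ratios
#'
#' The eight aspect ratios used for the longitudinal model series.
#'
#' @return numeric vector `c(0.3, 0.5, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0)`.
#' @export
standard_ar_series <- function() c(0.3, 0.5, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0)

#' Generate the longitudinal scaled-model series
#'
#' Measures the input model, aligns it so the neck plane is z = 0, and for
#' each target aspect ratio solves the scaling factor and applies the
#' graded sac transform. The parent vessel and the neck are identical
#' across all series members.
#'
#' @param mesh combined aneurysm + vessel [triangle_mesh()].
#' @param plane the [neck_plane()].
#' @param target_ARs numeric vector of target aspect ratios (e.g.
#'   [standard_ar_series()]).
#' @param a,b transverse scaling coefficients (default 1).
#' @param aligned if `TRUE`, return meshes in the aligned frame; default
#'   `FALSE` maps results back to the input frame.
#' @return list of class `scaling_series`; each element has `target_AR`,
#'   `k` and `mesh` (or `error` if that target was infeasible — the series
#'   continues past per-target failures). The input morphometry is attached
#'   as attribute `"morphometry"`.
#' @export
generate_series <- function(mesh, plane, target_ARs, a = 1, b = 1,
                            aligned = FALSE) {
  target_ARs <- as.numeric(target_ARs)
  m <- morphometry(mesh, plane)
  al <- neck_alignment_transform(plane)
  mesh_a <- apply_rigid(mesh, al)
  ctr_a <- as.vector(apply_rigid_points(matrix(m$neck_centroid, 1, 3), al))
  plane_a <- neck_plane(c(ctr_a[1], ctr_a[2], ctr_a[3]), c(0, 0, 1))
  out <- vector("list", length(target_ARs))
  for (i in seq_along(target_ARs)) {
    res <- tryCatch({
      k <- solve_scaling_factor(m$AR, target_ARs[i])
      sp <- scaling_spec(k, a = a, b = b, h = m$h, neck_centroid = ctr_a)
      sm <- scale_sac(mesh_a, plane_a, sp)
      if (!aligned) sm <- apply_rigid(sm, al, inverse = TRUE)
      list(target_AR = target_ARs[i], k = k, mesh = sm)
    }, error = function(e) {
      list(target_AR = target_ARs[i], k = NA_real_,
           error = conditionMessage(e))
    })
    out[[i]] <- res
  }
  structure(out, class = "scaling_series", morphometry = m)
}
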