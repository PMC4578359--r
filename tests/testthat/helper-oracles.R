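# Independent oracles and small generators used across the suite.

# Literal per-vertex, per-coordinate application of the graded scaling
# matrix, written as a plain double loop independent of scale_sac().
oracle_graded_scale <- function(vertices, centroid, k, a, b, h,
                                on_tol = 1e-9) {
  out <- vertices
  for (i in seq_len(nrow(vertices))) {
    z <- vertices[i, 3]
    if (z - centroid[3] <= on_tol) next
    dz <- z - centroid[3]
    fx <- 1 + a * dz * (k - 1) / h
    fy <- 1 + b * dz * (k - 1) / h
    fz <- 1 + dz * (k - 1) / h
    out[i, 1] <- centroid[1] + fx * (vertices[i, 1] - centroid[1])
    out[i, 2] <- centroid[2] + fy * (vertices[i, 2] - centroid[2])
    out[i, 3] <- centroid[3] + fz * dz
  }
  out
}

# Brute-force cycle mean of the instantaneous energy balance, summed step
# by step with scalar arithmetic.
oracle_mean_el <- function(series, fluid) {
  total <- 0
  for (i in seq_len(series$n)) {
    flux <- function(df) {
      df$v[i] * df$A[i] *
        (df$P[i] + 0.5 * fluid$rho * df$v[i]^2 + fluid$rho * fluid$g * df$z[i])
    }
    el <- flux(series$inlet)
    for (o in series$outlets) el <- el - flux(o)
    total <- total + el
  }
  total / series$n
}

# Random triangle mesh: a jittered sphere-like point cloud with arbitrary
# faces; adequate for transform identities that hold vertex-wise.
random_mesh <- function(n_vertices = 40L, n_faces = 30L) {
  v <- matrix(stats::rnorm(3 * n_vertices), ncol = 3)
  f <- matrix(sample.int(n_vertices, 3 * n_faces, replace = TRUE), ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  triangle_mesh(v, f[ok, , drop = FALSE], validate = FALSE)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Random rigid motion as a rigid_alignment-compatible rotation + offset.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rigid_move <- function(mesh, plane, R, t) {
  mesh$vertices <- sweep(mesh$vertices %*% t(R), 2, t, `+`)
  plane <- neck_plane(as.vector(R %*% plane$point) + t,
                      as.vector(R %*% plane$normal), normalize = TRUE)
  list(mesh = mesh, plane = plane)
}

# Shared default fixture, built once per test run.
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_sidewall_aneurysm(seed = 0L)
    cache
  }
})
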