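test_that("neck alignment maps the plane normal to +Z and the point to the origin", {
  # already aligned: identity
  al <- neck_alignment_transform(neck_plane(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(al$R, diag(3))
  expect_equal(c(al$p, al$q, al$r), c(0, 0, 0))
  # axis swap: normal along +X needs omega = -pi/2 about Y
  al <- neck_alignment_transform(neck_plane(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(al$omega, -pi / 2)
  expect_equal(as.vector(al$R %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)
  # property over seeded random planes
  set.seed(7)
  for (i in 1:100) {
    n <- random_unit_vector()
    p <- stats::rnorm(3, sd = 5)
    al <- neck_alignment_transform(neck_plane(p, n, normalize = TRUE))
    expect_lt(max(abs(t(al$R) %*% al$R - diag(3))), 1e-12)
    expect_lt(max(abs(as.vector(al$R %*% n) - c(0, 0, 1))), 1e-9)
    moved <- as.vector(al$matrix %*% c(p, 1))[1:3]
    expect_lt(max(abs(moved)), 1e-9)
  }
})

test_that("apply_rigid preserves pairwise distances and inverts exactly", {
  set.seed(11)
  mesh <- random_mesh(30L, 20L)
  al <- neck_alignment_transform(
    neck_plane(stats::rnorm(3), random_unit_vector(), normalize = TRUE))
  out <- apply_rigid(mesh, al)
  d0 <- stats::dist(mesh$vertices)
  d1 <- stats::dist(out$vertices)
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  back <- apply_rigid(out, al, inverse = TRUE)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-9)
  # quarter turn about Z permutes cube coordinates
  cube <- triangle_mesh(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                        matrix(c(1L, 2L, 3L), 1))
  alz <- neck_alignment_transform(neck_plane(c(0, 0, 0), c(0, 0, 1)))
  alz$R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # Rz(pi/2)
  rot <- apply_rigid(cube, alz)
  expect_equal(rot$vertices,
               rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1)), tolerance = 1e-12)
})

test_that("scaling factor solves the target aspect-ratio ratio", {
  expect_equal(solve_scaling_factor(1.0, 2.0), 2.0)
  expect_equal(solve_scaling_factor(1.3, 1.3), 1.0)
  expect_equal(solve_scaling_factor(0.5, 0.3), 0.6)
  expect_error(solve_scaling_factor(0, 1), "positive")
  expect_error(solve_scaling_factor(1, -2), "positive")
})

test_that("below the monotone regime the height-exact factor is used", {
  # the axial map zeta (1 + zeta (k-1)/h) peaks at h/(4(1-k)) for k < 1/2
  k <- solve_scaling_factor(1.0, 0.3)
  expect_equal(k, 1 - 1 / (4 * 0.3))
  expect_equal(1 / (4 * (1 - k)), 0.3)       # analytic re-measured ratio
  expect_equal(solve_scaling_factor(1.0, 0.5), 0.5)  # continuous at r = 1/2
  expect_error(solve_scaling_factor(1.0, 0.2), "unattainable")
})

test_that("graded scaling matches the literal per-vertex oracle", {
  set.seed(3)
  for (i in 1:100) {
    mesh <- random_mesh(25L, 15L)
    ctr <- c(stats::rnorm(2, sd = 0.5), min(mesh$vertices[, 3]) +
               0.2 * diff(range(mesh$vertices[, 3])))
    h <- max(mesh$vertices[, 3]) - ctr[3]
    k <- stats::runif(1, 0.6, 2.5)
    a <- stats::runif(1, 0.5, 1.5)
    b <- stats::runif(1, 0.5, 1.5)
    plane <- neck_plane(ctr, c(0, 0, 1))
    got <- scale_sac(mesh, plane, scaling_spec(k, a, b, h = h,
                                               neck_centroid = ctr))
    want <- oracle_graded_scale(mesh$vertices, ctr, k, a, b, h)
    expect_lt(max(abs(got$vertices - want)), 1e-12)
  }
})

test_that("k = 1 is the identity and the closed-form substitutions hold", {
  fx <- default_fixture()
  al <- neck_alignment_transform(fx$plane)
  mesh <- apply_rigid(fx$mesh, al)
  plane <- neck_plane(c(0, 0, 0), c(0, 0, 1))
  id <- scale_sac(mesh, plane, scaling_spec(1, 0.7, 1.3, h = 2,
                                            neck_centroid = c(0, 0, 0)))
  expect_identical(id$vertices, mesh$vertices)
  # apex and mid-height closed forms, k = 2, a = b = 1
  ctr <- c(1, -2, 0.5)
  h <- 3
  d <- 0.8
  pts <- triangle_mesh(rbind(ctr + c(0, 0, h), ctr + c(d, 0, h / 2),
                             ctr + c(0, 0, -1)),
                       matrix(c(1L, 2L, 3L), 1), validate = FALSE)
  out <- scale_sac(pts, neck_plane(ctr, c(0, 0, 1)),
                   scaling_spec(2, 1, 1, h = h, neck_centroid = ctr))
  expect_equal(out$vertices[1, ], ctr + c(0, 0, 2 * h))
  expect_equal(out$vertices[2, ], ctr + c(1.5 * d, 0, 0.75 * h))
  expect_identical(out$vertices[3, ], pts$vertices[3, ])
})

test_that("an inverting transverse factor is rejected", {
  fx <- default_fixture()
  al <- neck_alignment_transform(fx$plane)
  mesh <- apply_rigid(fx$mesh, al)
  plane <- neck_plane(c(0, 0, 0), c(0, 0, 1))
  spec <- scaling_spec(0.5, a = 3, b = 1, h = 2, neck_centroid = c(0, 0, 0))
  expect_error(scale_sac(mesh, plane, spec), "inverts")
})

test_that("the parent vessel and neck are bit-identical after scaling", {
  fx <- default_fixture()
  al <- neck_alignment_transform(fx$plane)
  mesh <- apply_rigid(fx$mesh, al)
  plane <- neck_plane(c(0, 0, 0), c(0, 0, 1))
  out <- scale_sac(mesh, plane, scaling_spec(1.8, h = 2,
                                             neck_centroid = c(0, 0, 0)))
  below <- mesh$vertices[, 3] <= 1e-9
  expect_identical(out$vertices[below, ], mesh$vertices[below, ])
  expect_identical(out$faces, mesh$faces)
  expect_false(identical(out$vertices[!below, ], mesh$vertices[!below, ]))
})

test_that("height law: measured height scales by k in the monotone regime", {
  fx <- default_fixture()
  al <- neck_alignment_transform(fx$plane)
  mesh <- apply_rigid(fx$mesh, al)
  plane <- neck_plane(c(0, 0, 0), c(0, 0, 1))
  parts <- split_at_plane(mesh, plane)
  h0 <- compute_height(parts$sac, plane)
  for (k in c(0.5, 0.8, 1.3, 2.0, 2.5)) {
    out <- scale_sac(mesh, plane, scaling_spec(k, h = h0,
                                               neck_centroid = c(0, 0, 0)))
    h1 <- compute_height(split_at_plane(out, plane)$sac, plane)
    expect_equal(h1, k * h0, tolerance = 1e-9)
  }
})

test_that("axial expansion factor grows monotonically from neck to fundus for k > 1", {
  h <- 2
  k <- 1.7
  zeta <- seq(0.01, h, length.out = 200)
  factor <- 1 + zeta * (k - 1) / h
  expect_true(all(diff(factor) > 0))
  expect_equal(factor[length(factor)], k)
  # and the factor tends to 1 at the neck: no tear across the plane
  expect_equal(1 + 1e-9 * (k - 1) / h, 1, tolerance = 1e-8)
})

test_that("generate_series reproduces the requested aspect-ratio ladder", {
  fx <- default_fixture()
  series <- generate_series(fx$mesh, fx$plane, standard_ar_series())
  expect_length(series, 8L)
  meas <- vapply(series, function(s) morphometry(s$mesh, fx$plane)$AR,
                 numeric(1))
  expect_true(all(abs(meas - standard_ar_series()) /
                    standard_ar_series() < 0.01))
  # vessel part identical across the series
  v1 <- series[[1]]$mesh$vertices
  v8 <- series[[8]]$mesh$vertices
  below <- fx$mesh$vertices[, 3] <= fx$plane$point[3] + 1e-9
  expect_identical(v1[below, ], v8[below, ])
})

test_that("generate_series handles empty and duplicate target lists", {
  fx <- default_fixture()
  expect_length(generate_series(fx$mesh, fx$plane, numeric(0)), 0L)
  twice <- generate_series(fx$mesh, fx$plane, c(0.5, 0.5))
  expect_identical(twice[[1]]$mesh$vertices, twice[[2]]$mesh$vertices)
  # an unattainable target errors per-target while the series continues
  mixed <- generate_series(fx$mesh, fx$plane, c(0.1, 1.5))
  expect_match(mixed[[1]]$error, "unattainable")
  expect_null(mixed[[2]]$error)
  expect_s3_class(mixed[[2]]$mesh, "triangle_mesh")
})
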