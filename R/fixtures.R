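#' Idealized sidewall-aneurysm fixture
#'
#' Deterministic synthetic stand-in for a patient aneurysm model: a
#' straight cylindrical parent vessel (open inlet/outlet ends, axis along
#' x) carrying a spherical-cap sac seated tangentially on the vessel top
#' line. The neck plane is tangent to the cylinder at z = `vessel_radius`,
#' where the sac's analytic neck circle (diameter `neck_diameter`) lies;
#' the sac shell continues a short skirt below the plane and is closed by
#' a flat disk, so the plane cuts it transversally in exactly one loop.
#' Every morphometric quantity has a closed form: dome height
#' `h = target_AR * neck_diameter`, cap-sphere radius
#' `r = (a^2 + h^2) / (2 h)` (`a` = neck radius), sac volume
#' `pi h^2 (3 r - h) / 3`. The sac is sampled at half the nominal edge
#' length (curvature-adaptive sampling).
#'
#' @param vessel_radius parent-vessel radius (mm).
#' @param vessel_length parent-vessel length (mm).
#' @param neck_diameter analytic neck diameter (mm); must be smaller than
#'   the vessel diameter.
#' @param target_AR aspect ratio h / D_n of the sac (> 0).
#' @param resolution nominal edge length (mm).
#' @param seed integer seed; rotates the sac azimuthal sampling phase.
#'   Outputs are bit-identical for identical seed and parameters.
#' @return list with `mesh` (a [triangle_mesh()] with generator metadata in
#'   attribute `"generator"`) and `plane` (the analytic [neck_plane()]).
#' @export
make_sidewall_aneurysm <- function(vessel_radius = 2, vessel_length = 24,
                                   neck_diameter = 2, target_AR = 1,
                                   resolution = 0.25, seed = 0L) {
  if (neck_diameter >= 2 * vessel_radius)
    stop("neck_diameter must be smaller than the vessel diameter")
  if (target_AR <= 0) stop("target_AR must be positive")
  if (resolution <= 0) stop("resolution must be positive")
  a <- neck_diameter / 2
  h <- target_AR * neck_diameter
  rs <- (a^2 + h^2) / (2 * h)
  zc <- vessel_radius + h - rs              # cap-sphere centre (on z axis)
  dip <- a^2 / h                            # sphere depth below the plane
  delta <- min(1.5 * resolution, 0.5 * dip)

  # widest horizontal extent of the retained sphere zone
  zlo <- vessel_radius - delta
  r_max <- if (zc >= zlo) rs else sqrt(rs^2 - (zlo - zc)^2)
  if (2 * r_max >= 0.9 * vessel_length)
    stop("infeasible geometry: sac would overlap both vessel ends")

  edge_sac <- resolution / 2
  n_phi <- max(16L, as.integer(ceiling(2 * pi * a / edge_sac)))
  theta_max <- acos((zlo - zc) / rs)
  n_theta <- max(8L, as.integer(ceiling(rs * theta_max / edge_sac)))
  set.seed(as.integer(seed))
  phase <- stats::runif(1) * 2 * pi / n_phi

  sac <- sphere_zone(c(0, 0, zc), rs, theta_max, n_phi, n_theta, phase)
  # close the skirt with a flat disk at z = zlo
  ring <- sac$ring
  cid <- nrow(sac$vertices) + 1L
  sac$vertices <- rbind(sac$vertices, c(0, 0, zlo))
  nxt <- c(ring[-1], ring[1])
  sac$faces <- rbind(sac$faces, cbind(cid, nxt, ring))
  if (mesh_volume(triangle_mesh(sac$vertices, sac$faces,
                                validate = FALSE)) < 0)
    sac$faces <- sac$faces[, c(1, 3, 2)]

  cyl <- cylinder_shell(vessel_radius, vessel_length, resolution)

  mesh <- triangle_mesh(rbind(cyl$vertices, sac$vertices),
                        rbind(cyl$faces, sac$faces + nrow(cyl$vertices)),
                        validate = TRUE)
  attr(mesh, "generator") <- list(
    vessel_radius = vessel_radius, vessel_length = vessel_length,
    neck_diameter = neck_diameter, target_AR = target_AR,
    resolution = resolution, seed = as.integer(seed),
    h = h, D_n = neck_diameter, AR = target_AR,
    V_A = pi * h^2 * (3 * rs - h) / 3,
    sphere_radius = rs, sphere_center = c(0, 0, zc),
    skirt_depth = delta,
    n_vertices = nrow(mesh$vertices), n_faces = nrow(mesh$faces))
  list(mesh = mesh,
       plane = neck_plane(c(0, 0, vessel_radius), c(0, 0, 1)))
}

# Sphere zone from the +z pole down to polar angle theta_max, with the
# pole as an explicit vertex. Returns vertices, faces, and the indices of
# the last (open) ring.
sphere_zone <- function(center, rs, theta_max, n_phi, n_theta, phase = 0) {
  th <- theta_max * seq_len(n_theta) / n_theta
  ph <- phase + 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  v <- matrix(0, 1L + n_theta * n_phi, 3)
  v[1, ] <- center + c(0, 0, rs)
  row0 <- function(i) 1L + (i - 1L) * n_phi
  for (i in seq_len(n_theta)) {
    v[row0(i) + seq_len(n_phi), ] <-
      cbind(center[1] + rs * sin(th[i]) * cos(ph),
            center[2] + rs * sin(th[i]) * sin(ph),
            center[3] + rs * cos(th[i]))
  }
  j <- seq_len(n_phi)
  jn <- c(j[-1], j[1])
  faces <- cbind(1L, row0(1L) + j, row0(1L) + jn)
  for (i in seq_len(n_theta - 1L)) {
    aa <- row0(i) + j
    bb <- row0(i) + jn
    cc <- row0(i + 1L) + j
    dd <- row0(i + 1L) + jn
    faces <- rbind(faces, cbind(aa, cc, dd), cbind(aa, dd, bb))
  }
  list(vertices = v, faces = faces,
       ring = row0(n_theta) + seq_len(n_phi))
}

# Open-ended cylinder along x, radius R, length L, with the azimuthal grid
# pinned so the top line (y = 0, z = R) is an exact vertex row.
cylinder_shell <- function(R, L, resolution) {
  n_c <- max(16L, as.integer(ceiling(2 * pi * R / resolution)))
  n_x <- max(4L, as.integer(ceiling(L / resolution)))
  ph <- 2 * pi * (seq_len(n_c) - 1L) / n_c   # includes phi = 0 (top)
  xs <- -L / 2 + L * (seq_len(n_x + 1L) - 1L) / n_x
  v <- cbind(rep(xs, each = n_c), rep(R * sin(ph), n_x + 1L),
             rep(R * cos(ph), n_x + 1L))
  j <- seq_len(n_c)
  jn <- c(j[-1], j[1])
  faces <- NULL
  for (i in seq_len(n_x)) {
    aa <- (i - 1L) * n_c + j
    bb <- (i - 1L) * n_c + jn
    cc <- i * n_c + j
    dd <- i * n_c + jn
    faces <- rbind(faces, cbind(aa, dd, cc), cbind(aa, bb, dd))
  }
  # orient outward (radial normals)
  m <- triangle_mesh(v, faces, validate = FALSE)
  cr <- face_cross(m)
  ctr <- (v[faces[, 1], , drop = FALSE] + v[faces[, 2], , drop = FALSE] +
            v[faces[, 3], , drop = FALSE]) / 3
  if (mean(rowSums(cr * cbind(0, ctr[, 2], ctr[, 3]))) < 0)
    faces <- faces[, c(1, 3, 2)]
  list(vertices = v, faces = faces)
}

#' Open hemisphere mesh
#'
#' UV-sampled open hemisphere of the given radius, pole up, seated on the
#' plane z = `center[3]` (boundary on the equator). Used as an analytic
#' morphometry oracle: height = radius, capped volume = (2/3) pi r^3.
#'
#' @param radius sphere radius (mm).
#' @param edge_length target edge length (mm).
#' @param center sphere centre (mm).
#' @return a [triangle_mesh()].
#' @export
make_hemisphere <- function(radius = 3, edge_length = 0.3,
                            center = c(0, 0, 0)) {
  n_phi <- max(16L, as.integer(ceiling(2 * pi * radius / edge_length)))
  n_theta <- max(8L, as.integer(ceiling(radius * (pi / 2) / edge_length)))
  z <- sphere_zone(center, radius, pi / 2, n_phi, n_theta, 0)
  triangle_mesh(z$vertices, z$faces, validate = TRUE)
}

#' Pulsatile inlet velocity waveform
#'
#' Smooth periodic cardiac waveform (sharp systolic peak plus a dicrotic
#' bump, built from von Mises-type harmonics) sampled on a uniform grid
#' over one period. The sampled time mean equals `mean_velocity` and the
#' sampled maximum equals `peak_velocity` exactly (the template is shifted
#' and rescaled after sampling). Defaults give a cycle-averaged Reynolds
#' number well inside the laminar regime for a 4 mm vessel.
#'
#' @param period cardiac period (s).
#' @param mean_velocity time-mean velocity (m/s), positive.
#' @param peak_velocity maximum velocity (m/s), at least `mean_velocity`.
#' @param n_steps number of time steps per pulse (>= 2).
#' @return data frame with columns `t` (s) and `v` (m/s), with attributes
#'   `period`, `mean_velocity`, `peak_velocity`.
#' @export
make_pulsatile_waveform <- function(period = 0.8, mean_velocity = 0.25,
                                    peak_velocity = 0.6, n_steps = 800L) {
  if (mean_velocity <= 0) stop("mean_velocity must be positive")
  if (peak_velocity < mean_velocity)
    stop("peak_velocity must be at least mean_velocity")
  if (n_steps < 2L) stop("n_steps must be at least 2")
  t <- period * (seq_len(n_steps) - 1L) / n_steps
  if (peak_velocity == mean_velocity) {
    v <- rep(mean_velocity, n_steps)
  } else {
    tau <- t / period
    s <- exp(2 * cos(2 * pi * (tau - 0.2))) +
      0.15 * exp(2 * cos(2 * pi * (tau - 0.55)))
    w <- s - mean(s)
    v <- mean_velocity + (peak_velocity - mean_velocity) * w / max(w)
    if (min(v) < 0)
      stop("waveform undershoots zero; increase mean or reduce peak")
  }
  structure(data.frame(t = t, v = v), period = period,
            mean_velocity = mean_velocity, peak_velocity = peak_velocity)
}

#' Analytic Poiseuille flow series (energy-balance oracle)
#'
#' Steady fully developed tube flow: equal velocity and area at inlet and
#' outlet, pressure drop `dP = 8 mu L Q / (pi R^4)`, so the Bernoulli
#' balance reduces to `EL = Q dP`, attached as attribute
#' `"closed_form_el"` for assertion against the pipeline.
#'
#' @param tube_radius tube radius (mm).
#' @param tube_length tube length (mm).
#' @param mean_velocity cross-section mean velocity (m/s).
#' @param n_steps number of time steps (>= 2).
#' @param fluid a [fluid_properties()].
#' @param period nominal sampling period (s).
#' @return a [flow_series()] with attribute `closed_form_el` (W).
#' @export
make_poiseuille_series <- function(tube_radius = 2, tube_length = 50,
                                   mean_velocity = 0.25, n_steps = 8L,
                                   fluid = fluid_properties(),
                                   period = 0.8) {
  if (tube_radius <= 0 || tube_length < 0 || mean_velocity < 0)
    stop("tube geometry and velocity must be non-negative (radius positive)")
  R <- tube_radius * 1e-3
  L <- tube_length * 1e-3
  A <- pi * R^2
  Q <- mean_velocity * A
  dP <- 8 * fluid$mu * L * Q / (pi * R^4)
  t <- period * (seq_len(n_steps) - 1L) / n_steps
  inlet <- plane_flow_sample(t, P = rep(dP, n_steps),
                             v = rep(mean_velocity, n_steps),
                             A = rep(A, n_steps))
  outlet <- plane_flow_sample(t, P = rep(0, n_steps),
                              v = rep(mean_velocity, n_steps),
                              A = rep(A, n_steps))
  fs <- flow_series(inlet, list(outlet))
  attr(fs, "closed_form_el") <- Q * dP
  fs
}

#' Paired flow series with prescribed mean energy losses
#'
#' Two synthetic single-outlet series over one pulse whose cycle-mean
#' energy losses equal the given targets (pulsatile pressure-drop shape
#' normalized to unit mean), for round-trip tests of the volume-normalized
#' energy-loss difference.
#'
#' @param el_with_target target mean EL of the first series (W, >= 0).
#' @param el_pre_target target mean EL of the second series (W, >= 0).
#' @param n_steps time steps per pulse.
#' @param fluid a [fluid_properties()].
#' @param seed integer seed for the pulsatile phase.
#' @return list with elements `with` and `pre`, both [flow_series()].
#' @export
make_paired_el_series <- function(el_with_target, el_pre_target,
                                  n_steps = 800L,
                                  fluid = fluid_properties(), seed = 0L) {
  if (el_with_target < 0 || el_pre_target < 0)
    stop("target energy losses must be non-negative")
  set.seed(as.integer(seed))
  shift <- stats::runif(1)
  R <- 2e-3
  A <- pi * R^2
  v <- 0.25
  t <- 0.8 * (seq_len(n_steps) - 1L) / n_steps
  w <- exp(2 * cos(2 * pi * (t / 0.8 - shift)))
  w <- w / mean(w)
  build <- function(target) {
    dP <- target * w / (v * A)
    flow_series(plane_flow_sample(t, P = dP, v = rep(v, n_steps),
                                  A = rep(A, n_steps)),
                list(plane_flow_sample(t, P = rep(0, n_steps),
                                       v = rep(v, n_steps),
                                       A = rep(A, n_steps))))
  }
  list(with = build(el_with_target), pre = build(el_pre_target))
}
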