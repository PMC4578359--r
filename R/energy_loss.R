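#' Blood fluid properties
#'
#' Physical constants for the Bernoulli energy balance. Defaults model
#' blood as an incompressible Newtonian fluid: density 1050 kg/m^3,
#' dynamic viscosity 0.0035 Pa·s.
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (Pa·s).
#' @param g gravitational acceleration (m/s^2).
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1050, mu = 0.0035, g = 9.81) {
  if (!all(is.finite(c(rho, mu, g))) || rho <= 0 || mu <= 0 || g < 0)
    stop("fluid properties must be positive (g may be zero)")
  structure(list(rho = rho, mu = mu, g = g), class = "fluid_properties")
}

#' Plane flow sample
#'
#' One time sample of area-averaged flow quantities on an inlet or outlet
#' test plane. All quantities are SI.
#'
#' @param t time (s), non-negative.
#' @param P static pressure on the plane (Pa).
#' @param v area-averaged velocity magnitude normal to the plane (m/s).
#' @param A plane area (m^2), positive.
#' @param z elevation of the plane centroid (m), default 0 (horizontal
#'   configuration: gravity terms cancel).
#' @return a one-row data frame with columns `t`, `P`, `v`, `A`, `z`.
#' @export
plane_flow_sample <- function(t, P, v, A, z = 0) {
  if (any(t < 0)) stop("time must be non-negative")
  if (any(A <= 0)) stop("plane area must be positive")
  if (any(v < 0)) stop("velocity magnitude must be non-negative")
  data.frame(t = t, P = P, v = v, A = A, z = z)
}

#' Inlet/outlet plane flow series
#'
#' Time-ordered plane samples over one cardiac cycle for the inlet and one
#' or more outlet planes, all on the identical time grid.
#'
#' @param inlet data frame of inlet samples (columns `t`, `P`, `v`, `A`,
#'   `z`), e.g. built with [plane_flow_sample()].
#' @param outlets list of outlet sample data frames on the same time grid.
#' @return object of class `flow_series` with elements `inlet`, `outlets`
#'   and `n` (number of time steps).
#' @export
flow_series <- function(inlet, outlets) {
  if (is.data.frame(outlets)) outlets <- list(outlets)
  if (length(outlets) == 0L) stop("no outlet plane")
  check <- function(df, nm) {
    need <- c("t", "P", "v", "A", "z")
    if (!all(need %in% names(df)))
      stop(sprintf("%s series must have columns t, P, v, A, z", nm))
    if (any(df$A <= 0)) stop(sprintf("%s plane area must be positive", nm))
    if (any(df$v < 0)) stop(sprintf("%s velocity must be non-negative", nm))
    if (any(df$t < 0)) stop(sprintf("%s time must be non-negative", nm))
    if (is.unsorted(df$t, strictly = TRUE))
      stop(sprintf("%s time grid must be strictly increasing", nm))
    df[, need]
  }
  inlet <- check(inlet, "inlet")
  outlets <- lapply(seq_along(outlets), function(i)
    check(outlets[[i]], sprintf("outlet%d", i)))
  n <- nrow(inlet)
  if (n < 2L) stop("flow series needs at least 2 time steps")
  for (o in outlets) {
    if (nrow(o) != n || max(abs(o$t - inlet$t)) > 1e-12)
      stop("all planes must share the identical time grid")
  }
  structure(list(inlet = inlet, outlets = outlets, n = n),
            class = "flow_series")
}

# Energy flux through one plane: v A (P + rho v^2 / 2 + rho g z), in W.
energy_flux <- function(df, fluid) {
  df$v * df$A * (df$P + 0.5 * fluid$rho * df$v^2 + fluid$rho * fluid$g * df$z)
}

#' Instantaneous energy loss (Bernoulli balance)
#'
#' Net rate of mechanical energy flux lost between the inlet and the
#' outlet test planes at one instant:
#' `EL = v_i A_in (P_i + rho v_i^2 / 2 + rho g z_i)
#'      - sum_outlets v_o A_o (P_o + rho v_o^2 / 2 + rho g z_o)` (W).
#' `P` is the static pressure, so `P + rho v^2 / 2` is the total pressure
#' entering the balance. With several outlet planes (bifurcating vessels)
#' the outlet flux term is summed over all of them.
#'
#' @param inlet one-row inlet sample ([plane_flow_sample()]).
#' @param outlets one-row outlet sample or list of such samples at the
#'   same timestamp.
#' @param fluid a [fluid_properties()].
#' @return instantaneous energy loss (W); positive means net energy lost
#'   between inlet and outlets.
#' @export
instantaneous_el <- function(inlet, outlets, fluid = fluid_properties()) {
  if (is.data.frame(outlets)) outlets <- list(outlets)
  if (length(outlets) == 0L) stop("no outlet plane")
  if (any(inlet$A <= 0) || any(vapply(outlets, function(o) any(o$A <= 0),
                                      TRUE)))
    stop("plane area must be positive")
  for (o in outlets) {
    if (max(abs(o$t - inlet$t)) > 1e-12)
      stop("mismatched timestamps between inlet and outlet samples")
  }
  sum(energy_flux(inlet, fluid)) -
    sum(vapply(outlets, function(o) sum(energy_flux(o, fluid)), numeric(1)))
}

#' Cycle-averaged energy loss
#'
#' Arithmetic mean of the instantaneous energy loss over the n time steps
#' of one pulse. The time grid must be uniform; non-uniform grids are
#' rejected rather than reweighted.
#'
#' @param series a [flow_series()].
#' @param fluid a [fluid_properties()].
#' @return mean energy loss over the cycle (W).
#' @export
mean_el <- function(series, fluid = fluid_properties()) {
  if (!inherits(series, "flow_series")) stop("not a flow_series")
  if (series$n < 2L) stop("flow series needs at least 2 time steps")
  dt <- diff(series$inlet$t)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("non-uniform time grid; resample before averaging")
  el <- energy_flux(series$inlet, fluid)
  for (o in series$outlets) el <- el - energy_flux(o, fluid)
  mean(el)
}

#' Instantaneous energy-loss series
#'
#' @param series a [flow_series()].
#' @param fluid a [fluid_properties()].
#' @return numeric vector of instantaneous EL (W), one per time step.
#' @export
el_series <- function(series, fluid = fluid_properties()) {
  if (!inherits(series, "flow_series")) stop("not a flow_series")
  el <- energy_flux(series$inlet, fluid)
  for (o in series$outlets) el <- el - energy_flux(o, fluid)
  el
}

#' Volume-normalized energy-loss difference
#'
#' Difference between the with-aneurysm and pre-aneurysm mean energy
#' losses per unit sac volume.
#'
#' @param el_with mean EL of the with-aneurysm condition (W).
#' @param el_pre mean EL of the pre-aneurysm condition (W).
#' @param V_A aneurysm sac volume (m^3), positive.
#' @return list with `W_per_m3` and `mW_per_mm3`
#'   (`mW_per_mm3 = W_per_m3 * 1e-6`).
#' @export
el_dif <- function(el_with, el_pre, V_A) {
  if (!is.finite(V_A) || V_A <= 0) stop("V_A must be positive")
  w <- (el_with - el_pre) / V_A
  list(W_per_m3 = w, mW_per_mm3 = w * 1e-6)
}

#' Full energy-loss comparison of two conditions
#'
#' @param with_series [flow_series()] of the with-aneurysm condition.
#' @param pre_series [flow_series()] of the pre-aneurysm condition.
#' @param V_A sac volume (m^3).
#' @param fluid a [fluid_properties()].
#' @return object of class `el_result` with the instantaneous series of
#'   the with-aneurysm condition, both cycle means, the sac volume and the
#'   normalized difference in both unit systems.
#' @export
el_result <- function(with_series, pre_series, V_A,
                      fluid = fluid_properties()) {
  series <- el_series(with_series, fluid)
  el_with <- mean_el(with_series, fluid)
  el_pre <- mean_el(pre_series, fluid)
  d <- el_dif(el_with, el_pre, V_A)
  structure(list(el_series = series, el_mean = mean(series),
                 el_with = el_with, el_pre = el_pre, V_A = V_A,
                 el_dif_W_per_m3 = d$W_per_m3,
                 el_dif_mW_per_mm3 = d$mW_per_mm3),
            class = "el_result")
}

#' Reynolds number
#'
#' `Re = rho v D / mu`. For the cycle-averaged variant pass the time-mean
#' velocity of one pulse (or use [reynolds_mean()]).
#'
#' @param fluid a [fluid_properties()].
#' @param v velocity (m/s), non-negative.
#' @param D vessel diameter (m), positive.
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(fluid, v, D) {
  if (!is.finite(D) || D <= 0) stop("diameter must be positive")
  if (any(!is.finite(v)) || any(v < 0)) stop("velocity must be non-negative")
  fluid$rho * v * D / fluid$mu
}

#' Cycle-averaged Reynolds number
#'
#' @param fluid a [fluid_properties()].
#' @param v velocity time series over one pulse (m/s).
#' @param D vessel diameter (m).
#' @return Reynolds number at the time-mean velocity.
#' @export
reynolds_mean <- function(fluid, v, D) reynolds(fluid, mean(v), D)

#' Read a plane flow series from CSV
#'
#' Expects columns `t,plane,P,v,A,z` with `plane` equal to `inlet` for the
#' inlet plane and `outlet1`, `outlet2`, ... for the outlets (plain
#' `outlet` is accepted for a single outlet).
#'
#' @param path path to a CSV file.
#' @return a [flow_series()].
#' @export
read_flow_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "plane", "P", "v", "A", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("'%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  planes <- unique(df$plane)
  if (!"inlet" %in% planes) stop(sprintf("'%s' has no inlet plane", path))
  onames <- sort(setdiff(planes, "inlet"))
  if (length(onames) == 0L) stop(sprintf("'%s' has no outlet plane", path))
  pick <- function(nm) {
    sub <- df[df$plane == nm, c("t", "P", "v", "A", "z")]
    sub[order(sub$t), ]
  }
  flow_series(pick("inlet"), lapply(onames, pick))
}

#' Write a plane flow series to CSV
#'
#' @param series a [flow_series()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_flow_series <- function(series, path) {
  if (!inherits(series, "flow_series")) stop("not a flow_series")
  rows <- list(cbind(plane = "inlet", series$inlet))
  for (i in seq_along(series$outlets))
    rows[[i + 1L]] <- cbind(plane = sprintf("outlet%d", i),
                            series$outlets[[i]])
  out <- do.call(rbind, rows)
  out <- out[, c("t", "plane", "P", "v", "A", "z")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
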