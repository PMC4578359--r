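test_that("identical inlet and outlet give zero instantaneous energy loss", {
  s <- plane_flow_sample(t = 0, P = 9000, v = 0.3, A = 1.2e-5, z = 0.01)
  expect_equal(instantaneous_el(s, s), 0)
  expect_error(instantaneous_el(s, plane_flow_sample(1, 0, 0.1, 1e-5)),
               "timestamps")
})

test_that("EL is gauge-invariant on mass-conserving series", {
  fluid <- fluid_properties()
  n <- 50L
  t <- 0.8 * (0:(n - 1)) / n
  a_in <- 1.2e-5
  v_in <- 0.2 + 0.1 * sin(2 * pi * t / 0.8)
  a1 <- 7e-6
  a2 <- 4e-6
  v1 <- 0.6 * v_in * a_in / a1
  v2 <- 0.4 * v_in * a_in / a2
  mk <- function(offset) {
    flow_series(
      plane_flow_sample(t, P = 5000 + 500 * cos(2 * pi * t / 0.8) + offset,
                        v = v_in, A = rep(a_in, n)),
      list(plane_flow_sample(t, P = 4000 + offset, v = v1, A = rep(a1, n)),
           plane_flow_sample(t, P = 3900 + offset, v = v2, A = rep(a2, n))))
  }
  el0 <- mean_el(mk(0), fluid)
  el1 <- mean_el(mk(1000), fluid)
  expect_equal(el1, el0, tolerance = 1e-9)
})

test_that("gravity terms vanish for equal elevations and act linearly otherwise", {
  t <- c(0, 0.1, 0.2)
  base <- flow_series(plane_flow_sample(t, P = c(100, 110, 120),
                                        v = c(0.2, 0.3, 0.25),
                                        A = rep(1e-5, 3), z = 0.05),
                      list(plane_flow_sample(t, P = c(90, 95, 100),
                                             v = c(0.2, 0.3, 0.25),
                                             A = rep(1e-5, 3), z = 0.05)))
  g0 <- fluid_properties(g = 0)
  g1 <- fluid_properties()
  expect_equal(mean_el(base, g0), mean_el(base, g1), tolerance = 1e-12)
  # raising the outlet by dz removes rho g dz per unit flux from the loss
  lifted <- base
  lifted$outlets[[1]]$z <- 0.15
  q <- mean(c(0.2, 0.3, 0.25) * 1e-5 *
              (g1$rho * g1$g * 0.1))
  expect_equal(mean_el(lifted, g1), mean_el(base, g1) - q, tolerance = 1e-9)
})

test_that("the Bernoulli balance reproduces the Hagen-Poiseuille closed form", {
  fluid <- fluid_properties()
  fs <- make_poiseuille_series(tube_radius = 2, tube_length = 50,
                               mean_velocity = 0.25, fluid = fluid)
  want <- attr(fs, "closed_form_el")
  # independent closed form, recomputed here
  q <- 0.25 * pi * 0.002^2
  expect_equal(want, q * 8 * fluid$mu * 0.05 * q / (pi * 0.002^4))
  expect_equal(mean_el(fs, fluid), want, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:25) {
    r <- stats::runif(1, 1, 3)
    l <- stats::runif(1, 20, 80)
    v <- stats::runif(1, 0.1, 0.6)
    fs <- make_poiseuille_series(r, l, v, fluid = fluid)
    expect_equal(mean_el(fs, fluid), attr(fs, "closed_form_el"),
                 tolerance = 1e-9)
  }
  # zero length tube loses nothing
  fs0 <- make_poiseuille_series(2, 0, 0.25, fluid = fluid)
  expect_equal(mean_el(fs0, fluid), 0)
})

test_that("mean EL equals the brute-force time loop and validates its grid", {
  fluid <- fluid_properties()
  wf <- make_pulsatile_waveform(n_steps = 800L)
  a <- 1.26e-5
  fs <- flow_series(plane_flow_sample(wf$t, P = 6000 + 2000 * wf$v, v = wf$v,
                                      A = rep(a, 800)),
                    list(plane_flow_sample(wf$t, P = rep(5500, 800), v = wf$v,
                                           A = rep(a, 800))))
  expect_equal(mean_el(fs, fluid), oracle_mean_el(fs, fluid),
               tolerance = 1e-12)
  expect_equal(mean_el(fs, fluid), mean(el_series(fs, fluid)),
               tolerance = 1e-12)
  # constant series: the mean is the constant instantaneous value
  cs <- make_poiseuille_series(2, 50, 0.25, n_steps = 4L, fluid = fluid)
  expect_equal(mean_el(cs, fluid),
               instantaneous_el(cs$inlet[1, ], cs$outlets[[1]][1, ], fluid))
  expect_error(flow_series(fs$inlet[1, , drop = FALSE],
                           list(fs$outlets[[1]][1, , drop = FALSE])),
               "at least 2")
  bad <- fs
  bad$inlet$t[3] <- bad$inlet$t[3] + 1e-4
  bad$outlets[[1]]$t[3] <- bad$inlet$t[3]
  expect_error(mean_el(bad, fluid), "non-uniform")
})

test_that("el_dif normalizes by sac volume in both unit systems", {
  expect_equal(el_dif(1e-3, 0, 1e-7)$W_per_m3, 1e4)
  expect_equal(el_dif(2e-3, 1e-3, 1e-7)$W_per_m3, 1e4)
  expect_equal(el_dif(2e-3, 1e-3, 1e-7)$mW_per_mm3, 0.01)
  expect_equal(el_dif(5, 5, 1e-6)$W_per_m3, 0)
  # antisymmetry
  d1 <- el_dif(3e-3, 1e-3, 2e-7)
  d2 <- el_dif(1e-3, 3e-3, 2e-7)
  expect_equal(d1$W_per_m3, -d2$W_per_m3)
  expect_error(el_dif(1, 0, 0), "positive")
  # published group-mean magnitude: 0.00374 mW/mm^3 is 3740 W/m^3
  expect_equal(el_dif(3740 * 1e-7, 0, 1e-7)$mW_per_mm3, 0.00374)
})

test_that("Reynolds number follows rho v D / mu", {
  fluid <- fluid_properties(rho = 1050, mu = 0.0035)
  expect_equal(reynolds(fluid, 0.5, 0.004), 600)
  expect_equal(reynolds(fluid, 0, 0.004), 0)
  expect_error(reynolds(fluid, 0.5, 0), "positive")
  wf <- make_pulsatile_waveform()
  expect_equal(reynolds_mean(fluid, wf$v, 0.004),
               reynolds(fluid, mean(wf$v), 0.004))
})

test_that("flow-series CSV round-trips and validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  fluid <- fluid_properties()
  pair <- make_paired_el_series(2e-3, 1e-3, n_steps = 64L, seed = 5L)
  write_flow_series(pair$with, path)
  back <- read_flow_series(path)
  expect_equal(mean_el(back, fluid), mean_el(pair$with, fluid),
               tolerance = 1e-9)
  # tiny hand-written 3-step file
  toy <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,plane,P,v,A,z",
               "0,inlet,100,0.2,1e-5,0", "0.1,inlet,110,0.25,1e-5,0",
               "0.2,inlet,120,0.22,1e-5,0",
               "0,outlet1,90,0.2,1e-5,0", "0.1,outlet1,95,0.25,1e-5,0",
               "0.2,outlet1,99,0.22,1e-5,0"), toy)
  fs <- read_flow_series(toy)
  expect_equal(fs$n, 3L)
  # inlet only
  onlyin <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,plane,P,v,A,z", "0,inlet,1,0.1,1e-5,0",
               "0.1,inlet,1,0.1,1e-5,0"), onlyin)
  expect_error(read_flow_series(onlyin), "no outlet plane")
  # missing column
  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,plane,P,v", "0,inlet,1,0.1"), nocol)
  expect_error(read_flow_series(nocol), "missing column")
})
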