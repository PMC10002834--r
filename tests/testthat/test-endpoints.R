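test_that("TAWSS is the magnitude of the vector time average", {
  s_const <- synthetic_traction_series(list(c(0, 0, 3), c(0, 0, 3)))
  expect_equal(unname(tawss(s_const)), c(3, 3))
  ## equal-duration reversal cancels the vector mean
  s_rev <- synthetic_traction_series(list(c(2, 0, 0), c(-2, 0, 0)))
  expect_equal(max(tawss(s_rev)), 0, tolerance = 1e-12)
  ## hand case: (2,0,0) then (0,2,0) averages to (1,1,0), magnitude sqrt(2)
  s_two <- synthetic_traction_series(list(c(2, 0, 0), c(0, 2, 0)))
  expect_equal(unname(tawss(s_two)), rep(sqrt(2), 2))
})

test_that("OSI spans its limit cases and stays within [0, 0.5]", {
  s_steady <- synthetic_traction_series(list(c(1, 2, 0), c(1, 2, 0)))
  expect_equal(max(osi(s_steady)), 0)
  s_rev <- synthetic_traction_series(list(c(2, 0, 0), c(-2, 0, 0)))
  expect_equal(unname(osi(s_rev)), c(0.5, 0.5))
  ## collinear same-direction magnitudes: ratio 1, OSI 0
  s_col <- synthetic_traction_series(list(c(2, 0, 0), c(1, 0, 0)))
  expect_equal(max(osi(s_col)), 0, tolerance = 1e-12)
  ## degenerate zero history defined as 0
  s_zero <- synthetic_traction_series(list(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(unname(osi(s_zero)), c(0, 0))
  ## random series: bounds and the triangle inequality TAWSS <= mean |tau|
  set.seed(1)
  for (k in 1:20) {
    taus <- lapply(1:5, function(i) stats::rnorm(3))
    s <- synthetic_traction_series(taus)
    o <- osi(s)
    expect_true(all(o >= 0 & o <= 0.5))
    mean_mag <- mean(vapply(taus, function(t) sqrt(sum(t^2)), 0))
    expect_lte(max(tawss(s)), mean_mag + 1e-12)
  }
})

test_that("wall traction vanishes for rest and hydrostatic states", {
  rc <- resistance_pipe_case()
  n <- nrow(rc$mesh$nodes)
  rest <- structure(list(times = 0, v = list(matrix(0, n, 3)),
                         p = list(numeric(n)), mesh = rc$mesh, info = list()),
                    class = "flow_field")
  expect_lt(max(tawss(wall_traction(rest, "wall"))), 1e-12)
  hydro <- rest
  hydro$p <- list(rep(5000, n))
  tr <- wall_traction(hydro, "wall")
  expect_lt(max(tawss(tr)), 1e-9)
  ## tangency at every node by construction
  tau <- tr$tau[[1]]
  expect_lt(max(abs(rowSums(tau * tr$normal))), 1e-9)
})

test_that("low-WSS area fraction is area-weighted and threshold-monotone", {
  rc <- resistance_pipe_case()
  tr <- wall_traction(rc$field, "wall", mu = 0.035)
  nw <- length(tr$nodes)
  f_hi <- low_wss_area_fraction(tr, rep(10, nw), rc$mesh, "wall", 5)
  f_lo <- low_wss_area_fraction(tr, rep(1, nw), rc$mesh, "wall", 5)
  expect_equal(f_hi, 0)
  expect_equal(f_lo, 1)
  tw <- tawss(tr)
  fr <- vapply(c(1, 3, 5, 10), function(thr)
    low_wss_area_fraction(tr, tw, rc$mesh, "wall", thr), 0)
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("cut-plane pressures convert units and subtract antisymmetrically", {
  rc <- resistance_pipe_case()
  n <- nrow(rc$mesh$nodes)
  unif <- structure(list(times = 0, v = list(matrix(0, n, 3)),
                         p = list(rep(1333.22, n)), mesh = rc$mesh,
                         info = list()), class = "flow_field")
  pl <- cut_plane(arm = "z", offset = 2)
  expect_equal(cut_plane_pressure(unif, pl), 1.0, tolerance = 1e-9)
  p1 <- cut_plane(arm = "z", offset = 0.5)
  p2 <- cut_plane(arm = "z", offset = 3.5)
  expect_equal(pressure_loss(rc$field, p1, p1), 0)
  dp <- pressure_loss(rc$field, p1, p2)
  expect_equal(pressure_loss(rc$field, p2, p1), -dp)
  ## 4 cm of developed low-Re pipe within 10% of the closed form
  pc <- poiseuille_case()
  q1 <- cut_plane(arm = "z", offset = 3)
  q2 <- cut_plane(arm = "z", offset = 7)
  dp2 <- pressure_loss(pc$field, q1, q2)
  analytic <- dyn_to_mmhg(128 * pc$mu * pc$Q / (pi * pc$D^4) * 4)
  expect_lt(abs(dp2 - analytic) / analytic, 0.10)
})

test_that("flow split follows the resistance divider on the junction", {
  jc <- junction2d_case(5)
  split <- flow_split(jc$field)
  divider <- 100 * 222.49 / (204.51 + 222.49)
  expect_lt(abs(split - divider), 1.0)
  ## equal resistances on a symmetric junction: 50/50
  bc_eq <- jc$bc
  bc_eq$outlet_resistances <- c(outlet_RPA = 210, outlet_LPA = 210)
  f_eq <- solve_steady(jc$mesh, bc_eq,
                       solver_settings(steady_mode = TRUE,
                                       steady_max_steps = 80L))
  expect_lt(abs(flow_split(f_eq) - 50), 0.5)
})

test_that("power loss is positive for dissipative flow and zero at rest", {
  rc <- resistance_pipe_case()
  n <- nrow(rc$mesh$nodes)
  rest <- structure(list(times = 0, v = list(matrix(0, n, 3)),
                         p = list(numeric(n)), mesh = rc$mesh, info = list()),
                    class = "flow_field")
  expect_equal(power_loss(rest), 0)
  pc <- poiseuille_case()
  pw <- power_loss(pc$field, rho = pc$rho)
  expect_gt(pw, 0)
  ## developed flow: dissipation = dP * Q (kinetic flux change negligible)
  dp_dyn <- 128 * pc$mu * pc$Q / (pi * pc$D^4) * pc$L
  analytic_mw <- dp_dyn * pc$Q * 1e-4
  expect_lt(abs(pw - analytic_mw) / analytic_mw, 0.10)
})

test_that("Stokes-regime losses scale linearly in viscosity", {
  D <- 0.5; L <- 3
  m <- make_pipe_mesh(D, L, 0.12, n_boundary_layers = 1)
  Q <- 0.05
  dps <- vapply(c(1, 4), function(fac) {
    bc <- make_bc_set(5, fluid = fluid_properties(viscosity = 0.035 * fac))
    bc$inlet_flows <- c(inlet = Q)
    bc$outlet_resistances <- c(outlet = 0)
    f <- solve_steady(m, bc, solver_settings(steady_mode = TRUE))
    pressure_loss(f, cut_plane("z", 0.6), cut_plane("z", 2.4))
  }, 0)
  expect_lt(abs(dps[2] / dps[1] - 4) / 4, 0.05)
})
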