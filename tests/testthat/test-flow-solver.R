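test_that("developed pipe flow matches Hagen-Poiseuille within 10%", {
  pc <- poiseuille_case()
  expect_equal(pc$field$info$flag, "converged")
  ## axial pressure gradient in the developed segment
  z <- pc$mesh$nodes[, 3]
  sel <- z > 3 & z < 7
  fit <- stats::lm(pc$field$p[[1]][sel] ~ z[sel])
  grad <- -stats::coef(fit)[[2]]
  analytic <- 128 * pc$mu * pc$Q / (pi * pc$D^4)
  expect_lt(abs(grad - analytic) / analytic, 0.10)
  ## inlet flux within 0.5% of the prescription
  qin <- -boundary_flux(pc$mesh, pc$field$v[[1]], "inlet")
  expect_lt(abs(qin - pc$Q) / pc$Q, 0.005)
  ## mass imbalance on the converged case
  imb <- check_mass_conservation(pc$field)
  expect_lt(imb$imbalance[1], 1e-3)
})

test_that("wall traction magnitude matches the Poiseuille value within 10%", {
  pc <- poiseuille_case()
  tr <- wall_traction(pc$field, "wall", mu = pc$mu)
  z <- pc$mesh$nodes[tr$nodes, 3]
  sel <- z > 3 & z < 7
  tw <- tawss(tr)
  analytic <- 32 * pc$mu * pc$Q / (pi * pc$D^3)
  expect_lt(abs(mean(tw[sel]) - analytic) / analytic, 0.10)
  ## steady single snapshot: OSI identically zero
  expect_equal(max(osi(tr)), 0)
})

test_that("pressure gradient error shrinks with mesh refinement at first order", {
  pc <- poiseuille_case()
  analytic <- 128 * pc$mu * pc$Q / (pi * pc$D^4)
  err <- vapply(c(0.45, 0.3, 0.2), function(h) {
    m <- make_pipe_mesh(pc$D, pc$L, h, n_boundary_layers = 1)
    f <- solve_steady(m, pc$bc, solver_settings(steady_mode = TRUE))
    z <- m$nodes[, 3]
    sel <- z > 3 & z < 7
    grad <- -stats::coef(stats::lm(f$p[[1]][sel] ~ z[sel]))[[2]]
    abs(grad - analytic) / analytic
  }, 0)
  expect_true(all(diff(err) < 0))
  order_obs <- log(err[1] / err[3]) / log(0.45 / 0.2)
  expect_gt(order_obs, 1)
})

test_that("resistance outlet sets p_out = R Q and scales linearly in R", {
  rc <- resistance_pipe_case()
  expect_equal(rc$field$info$flag, "converged")
  p_out <- cut_plane_pressure(rc$field, cut_plane("z", rc$mesh$nodes[1, 3] + 3.9))
  expect_lt(abs(p_out - dyn_to_mmhg(rc$R * rc$Q)) / dyn_to_mmhg(rc$R * rc$Q),
            0.01)
  ## doubling R doubles the outlet pressure
  bc2 <- rc$bc
  bc2$outlet_resistances <- c(outlet = 2 * rc$R)
  f2 <- solve_steady(rc$mesh, bc2, solver_settings(steady_mode = TRUE))
  p2 <- cut_plane_pressure(f2, cut_plane("z", rc$mesh$nodes[1, 3] + 3.9))
  expect_lt(abs(p2 - 2 * p_out) / p2, 0.01)
  ## traction contract: h = -R Q n, implicit in the current flux
  rr <- apply_resistance_outlet(rc$mesh, "outlet", rc$R, rc$field$v[[1]])
  expect_equal(rr$traction_normal, -rc$R * rr$Q, tolerance = 1e-12)
  expect_lt(abs(rr$Q - rc$Q) / rc$Q, 0.005)
  r0 <- apply_resistance_outlet(rc$mesh, "outlet", 0, rc$field$v[[1]])
  expect_equal(r0$traction_normal, 0)
})

test_that("zero inflow yields the rest state in one step", {
  m <- make_pipe_mesh(1, 3, 0.3)
  bc <- make_bc_set(5)
  bc$inlet_flows <- c(inlet = 0)
  bc$outlet_resistances <- c(outlet = 100)
  f <- solve_steady(m, bc, solver_settings(steady_mode = TRUE))
  expect_equal(f$info$flag, "converged")
  expect_lte(f$info$n_steps, 1L)
  expect_lt(max(abs(f$v[[1]])), 1e-10)
  expect_lt(diff(range(f$p[[1]])), 1e-8)
  imb <- check_mass_conservation(f)
  expect_true(imb$absolute[1])
  expect_lt(imb$imbalance[1], 1e-12)
})

test_that("inlet profiles integrate to the requested flow", {
  ## short stub with a finely resolved inlet disk (the profile-peak check
  ## needs the interpolation error of the parabola below 0.5%)
  stub <- make_pipe_mesh(1.91, 0.4, 0.09)
  pr <- inlet_profile(stub, "inlet", 70, "parabolic")
  v <- matrix(0, nrow(stub$nodes), 3)
  v[pr$nodes, ] <- pr$vel
  expect_lt(abs(-boundary_flux(stub, v, "inlet") - 70) / 70, 0.001)
  ## parabolic peak = 2 Q / A
  expect_lt(abs(max(sqrt(rowSums(pr$vel^2))) - 2 * 70 / pr$area) /
            (2 * 70 / pr$area), 0.005)
  pc <- poiseuille_case()
  pg <- inlet_profile(pc$mesh, "inlet", 70, "plug")
  speeds <- sqrt(rowSums(pg$vel^2))
  expect_equal(max(speeds), 70 / pg$area, tolerance = 1e-10)
  expect_equal(min(speeds), 70 / pg$area, tolerance = 1e-10)
  p0 <- inlet_profile(pc$mesh, "inlet", 0)
  expect_equal(max(abs(p0$vel)), 0)
})

test_that("backflow correction activates only on reversed outlet flow", {
  rc <- resistance_pipe_case()
  fw <- backflow_correction(rc$mesh, "outlet", rc$field$v[[1]], 0.2, 1.06)
  expect_equal(max(abs(fw$force)), 0)
  ## synthetic reversed flow: the correction opposes the reversal
  vr <- -rc$field$v[[1]]
  bw <- backflow_correction(rc$mesh, "outlet", vr, 0.2, 1.06)
  expect_gt(max(abs(bw$force)), 0)
  ## the weak-form contribution acts as a drag on the reversed velocity:
  ## its residual component carries the velocity's own sign (like viscosity)
  onodes <- group_nodes(rc$mesh, "outlet")
  fz <- bw$force[(onodes - 1) * 3 + 3]
  vz <- vr[onodes, 3]
  nz <- abs(fz) > 1e-12
  expect_true(all(sign(fz[nz]) == sign(vz[nz])))
  b0 <- backflow_correction(rc$mesh, "outlet", vr, 0, 1.06)
  expect_equal(max(abs(b0$force)), 0)
})

test_that("transient integration reaches the steady profile", {
  D <- 0.3; L <- 1.5
  fl <- fluid_properties()
  Q <- 30 * pi * D * fl$viscosity / (4 * fl$density)
  m <- make_pipe_mesh(D, L, 0.075)
  bc <- make_bc_set(5)
  bc$inlet_flows <- c(inlet = Q)
  bc$outlet_resistances <- c(outlet = 0)
  fs <- solve_steady(m, bc, solver_settings(steady_mode = TRUE))
  ## development time is rho R^2 / mu ~ 0.7 s; run several time constants.
  ## dt = 0.04 keeps the transient stabilization tau close to the steady
  ## solver's spatial-only tau, so the two discrete solutions coincide
  ft <- solve_transient(m, bc, solver_settings(dt = 0.04, t_end = 4,
                                               save_every = 0.4,
                                               newton_max_iter = 3))
  last <- length(ft$times)
  p1 <- cut_plane(arm = "z", offset = 0.3)
  p2 <- cut_plane(arm = "z", offset = 1.2)
  dps <- pressure_loss(fs, p1, p2)
  dpt <- pressure_loss(ft, p1, p2, window = rep(ft$times[last], 2))
  expect_lt(abs(dps - dpt) / abs(dps), 0.01)
  ## prescribed inlet flux holds at every snapshot
  qin <- -boundary_flux(m, ft$v[[last]], "inlet")
  expect_lt(abs(qin - Q) / Q, 0.005)
})
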