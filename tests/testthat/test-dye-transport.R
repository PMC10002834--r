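test_that("dye initialization is sharp and region-bound", {
  m <- make_junction_mesh(junction_geometry(), 0.35)
  sf <- init_dye(m, dye_region(edge = 3.5))
  phi <- sf$phi[[1]]
  expect_setequal(unique(phi), c(0, 1))
  inside <- apply(abs(m$nodes) <= 3.5 / 2 + 1e-12, 1, all)
  expect_equal(phi, as.numeric(inside))
  ## far-arm nodes hold no dye
  expect_true(all(phi[abs(m$nodes[, 1]) > 4] == 0))
  ## degenerate and oversized regions
  expect_error(init_dye(m, dye_region(center = c(50, 50, 50), edge = 1)),
               "disjoint")
  all_in <- init_dye(m, dye_region(edge = 1000))
  expect_true(all(all_in$phi[[1]] == 1))
})

test_that("dye is inert without velocity or diffusivity", {
  m <- make_channel_mesh(3, 0.4, 0.1)
  vel <- uniform_flow_field(m, 0)
  sf0 <- init_dye(m, dye_region(center = c(1.5, 0.2), edge = 1))
  sf <- advance_scalar(sf0, vel, dt = 0.05, t_end = 0.5, kappa = 0)
  ## inlet clamp aside, the interior field is unchanged
  interior <- m$nodes[, 1] > 0.05
  for (k in seq_along(sf$times))
    expect_equal(sf$phi[[k]][interior], sf0$phi[[1]][interior],
                 tolerance = 1e-10)
})

test_that("an advected front travels at the flow speed", {
  m <- make_channel_mesh(5, 0.4, 0.1)
  vel <- uniform_flow_field(m, 10)
  sf0 <- init_dye(m, dye_region(center = c(0.5, 0.2), edge = 1))
  sf <- advance_scalar(sf0, vel, dt = 0.01, t_end = 0.2, kappa = 1e-6)
  phi <- sf$phi[[length(sf$phi)]]
  x <- m$nodes[, 1]
  xs <- sort(unique(x))
  prof <- vapply(xs, function(xx) mean(phi[abs(x - xx) < 1e-9]), 0)
  i <- max(which(prof > 0.5))
  front <- xs[i] + (prof[i] - 0.5) / (prof[i] - prof[i + 1]) *
    (xs[i + 1] - xs[i])
  ## method of characteristics: front started at x = 1, U t = 2
  expect_lt(abs(front - 3), 1.5 * 0.1)
  ## boundedness under discontinuity capturing
  rng <- range(unlist(sf$phi))
  expect_gte(rng[1], -0.05)
  expect_lte(rng[2], 1.05)
})

test_that("pure diffusion reproduces the heat-kernel variance growth", {
  m <- make_channel_mesh(6, 0.3, 0.05)
  vel <- uniform_flow_field(m, 0)
  x <- m$nodes[, 1]
  s0 <- 0.3; kap <- 0.01; t_end <- 2
  sf0 <- synthetic_scalar_field(cbind(exp(-(x - 3)^2 / (2 * s0^2))), 0, m)
  sf <- advance_scalar(sf0, vel, dt = 0.02, t_end = t_end, kappa = kap,
                       dc_scale = 0)
  phiT <- sf$phi[[length(sf$phi)]]
  w <- fontanflow:::lumped_mass(m)
  m0 <- sum(w * phiT)
  mu1 <- sum(w * phiT * x) / m0
  v2 <- sum(w * phiT * (x - mu1)^2) / m0
  expect_lt(abs(v2 - (s0^2 + 2 * kap * t_end)) / (s0^2 + 2 * kap * t_end),
            0.02)
})

test_that("total dye is non-increasing once inlets are clamped clean", {
  jc <- junction2d_case(5)
  sf0 <- init_dye(jc$mesh, dye_region(edge = 3.5))
  sf <- advance_scalar(sf0, jc$field, dt = 0.05, t_end = 1.5, kappa = 1e-4)
  w <- fontanflow:::lumped_mass(jc$mesh)
  totals <- vapply(sf$phi, function(p) sum(w * p), 0)
  expect_true(all(diff(totals) <= 0.005 * totals[-length(totals)]))
})

test_that("washout time follows its definition on synthetic histories", {
  tms <- seq(0, 2, by = 0.01)
  ## linear decay from 1 with slope 1/s: crosses 1% at t = 0.99
  decay <- pmax(0, 1 - tms)
  ## rise then plateau at the max: censored over the horizon
  plateau <- pmin(1, tms * 10)
  ## never-dyed node
  dark <- rep(0, length(tms))
  P <- rbind(decay, plateau, dark)
  wf <- washout_time(synthetic_scalar_field(P, tms))
  expect_equal(wf$T[1], 0.99, tolerance = 1e-6)
  expect_false(wf$censored[1])
  expect_true(wf$censored[2])
  expect_equal(wf$t_max[2], 0.1, tolerance = 1e-9)
  expect_equal(wf$T[3], 0)
  expect_false(wf$censored[3])
  ## t_max ties resolve to the earliest time
  twopeak <- c(0, 1, 0.5, 1, 0)
  wf2 <- washout_time(synthetic_scalar_field(rbind(twopeak), 0:4))
  expect_equal(wf2$t_max[1], 1)
  expect_error(washout_time(synthetic_scalar_field(cbind(decay), 0)),
               "two snapshots")
})

test_that("mean washout averages per volume and reports censoring", {
  m <- make_channel_mesh(2, 0.4, 0.1)
  n <- nrow(m$nodes)
  wf <- structure(list(T = rep(0.5, n), t_max = numeric(n),
                       t_1pct = rep(0.5, n), censored = rep(FALSE, n),
                       mesh = m, horizon = 5), class = "washout_field")
  reg <- dye_region(center = c(1, 0.2), edge = 10)
  mw <- mean_washout(wf, reg)
  expect_equal(mw$mean_T, 0.5)
  expect_equal(mw$censored_fraction, 0)
  ## equal-volume halves at 0.2 and 0.6 average to 0.4 (nodes on the split
  ## line carry half-weights, hence the loose tolerance)
  wf$T <- ifelse(m$nodes[, 1] < 1, 0.2, 0.6)
  mw2 <- mean_washout(wf, reg)
  expect_equal(mw2$mean_T, 0.4, tolerance = 0.05)
  wf$censored <- rep(TRUE, n)
  expect_error(mean_washout(wf, reg), "censored")
})

test_that("plug flow washes a dye block out at the transit-time scale", {
  m <- make_channel_mesh(8, 0.5, 0.1)
  U <- 10; edge <- 3.5
  vel <- uniform_flow_field(m, U)
  reg <- dye_region(center = c(2, 0.25), edge = edge)
  sf0 <- init_dye(m, reg)
  ## small implicit step: the backward-Euler streamwise smearing
  ## (~ U^2 dt / 2) must stay well below kappa-free transit resolution
  sf <- advance_scalar(sf0, vel, dt = 0.002, t_end = 1.2, kappa = 1e-6)
  mw <- mean_washout(washout_time(sf), reg)
  ## mean trailing-edge transit: (edge / 2) / U
  expect_lt(abs(mw$mean_T - edge / 2 / U) / (edge / 2 / U), 0.30)
})
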