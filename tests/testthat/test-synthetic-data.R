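test_that("pipe mesh reproduces cylinder surface area and sphere topology", {
  m <- make_pipe_mesh(1.91, 10, 0.3)
  a <- audit_mesh(m, strict = FALSE)
  expect_true(a$ok)
  expect_identical(a$euler_characteristic, 2L)
  D <- 1.91; L <- 10
  analytic <- 2 * pi * (D / 2)^2 + pi * D * L
  expect_lt(abs(sum(face_geometry(m)$area) - analytic) / analytic, 0.05)
  expect_setequal(unique(m$face_labels), c("inlet", "outlet", "wall"))
})

test_that("boundary-layer pipe mesh keeps positive volumes and fair angles", {
  m <- make_pipe_mesh(2, 4, 0.5, n_boundary_layers = 2)
  expect_gt(min(cell_volumes(m)), 0)
  q <- mesh_quality(m)
  expect_gt(q$min_dihedral_deg, 5)
  ## graded layers: thinnest wall-adjacent radial spacing = h/4
  r <- sqrt(rowSums(m$nodes[, 1:2]^2))
  ru <- sort(unique(round(r, 6)), decreasing = TRUE)
  expect_lt(ru[1] - ru[2], 0.5 * 0.5^1 + 1e-6)
  expect_equal(ru[1] - ru[2], 0.5 * 0.5^2, tolerance = 1e-6)
})

test_that("blank junction carries ports and housing wall, no insert groups", {
  m <- make_junction_mesh(junction_geometry(), 0.3)
  expect_true(audit_mesh(m, strict = FALSE)$ok)
  groups <- unique(m$face_labels)
  expect_true(all(c("inlet_IVC", "inlet_SVC", "outlet_RPA", "outlet_LPA",
                    "wall_housing") %in% groups))
  expect_false(any(c("wall_rotor", "wall_strut") %in% groups))
})

test_that("bicone insert adds rotor and strut walls; blade height grows the rotor surface", {
  m162 <- make_junction_mesh(junction_geometry(insert_kind = "bicone",
                                               blade_height = 0.162), 0.22)
  m109 <- make_junction_mesh(junction_geometry(insert_kind = "bicone",
                                               blade_height = 0.109), 0.22)
  expect_true(all(c("wall_rotor", "wall_strut") %in% m162$face_labels))
  expect_gt(group_area(m162, "wall_rotor"), group_area(m109, "wall_rotor"))
})

test_that("symmetric junction is mirror-symmetric across the outlet axis", {
  m <- make_junction_mesh(junction_geometry(), 0.3)
  h <- 10 / (2 * ceiling(5 / 0.3))
  ## reflected node set matches within a fraction of the grid spacing
  refl <- m$nodes
  refl[, 1] <- -refl[, 1]
  ## surface snapping and sliver cleanup move boundary nodes by up to ~h
  ## under reflection of the (asymmetric) background tetrahedralization
  nn <- vapply(sample(nrow(refl), 300), function(i) {
    min(sqrt(rowSums(sweep(m$nodes, 2, refl[i, ])^2)))
  }, 0)
  expect_lt(max(nn), 1.25 * h)
  ## RPA/LPA wetted areas agree within 1%
  aR <- group_area(m, "outlet_RPA")
  aL <- group_area(m, "outlet_LPA")
  expect_lt(abs(aR - aL) / aR, 0.01)
})

test_that("mesh audits hold across a randomized parameter sweep", {
  set.seed(42)
  for (k in 1:4) {
    p <- junction_geometry(
      tube_diameter = runif(1, 1.5, 2.2),
      housing_max_diameter = runif(1, 3.0, 3.8),
      arm_length = runif(1, 4.5, 6),
      insert_kind = sample(c("none", "bicone"), 1),
      bicone_equator_diameter = runif(1, 1.8, 2.4),
      blade_height = runif(1, 0.08, 0.2))
    m <- make_junction_mesh(p, 0.33)
    a <- audit_mesh(m, strict = FALSE)
    expect_true(a$ok, info = sprintf("sweep case %d", k))
  }
  m2 <- make_junction_mesh(junction_geometry(), 0.15, dim = 2L)
  expect_true(audit_mesh(m2, strict = FALSE)$ok)
})

test_that("invalid geometry parameters are rejected", {
  expect_error(junction_geometry(arm_length = 3), "arm_length")
  expect_error(junction_geometry(insert_kind = "bicone",
                                 bicone_equator_diameter = 3.6),
               "fit")
  expect_error(junction_geometry(tube_diameter = 3.5),
               "housing")
  expect_error(make_pipe_mesh(-1, 10, 0.3), "positive")
})

test_that("caval flows follow the 60/40 split in cm^3/s", {
  bc <- make_bc_set(11, 0.6)
  expect_equal(unname(bc$inlet_flows["inlet_IVC"]), 110, tolerance = 1e-12)
  expect_equal(unname(bc$inlet_flows["inlet_SVC"]), 73 + 1 / 3,
               tolerance = 1e-10)
  even <- make_bc_set(3, 0.5)
  expect_equal(unname(even$inlet_flows), c(25, 25), tolerance = 1e-12)
  bc7 <- make_bc_set(7, 0.6, R_rpa = 204.51, R_lpa = 222.49)
  expect_identical(unname(bc7$outlet_resistances),
                   c(204.51, 222.49))
  expect_error(make_bc_set(0), "positive")
})

test_that("Reynolds number follows 4 rho Q / (pi D mu)", {
  bc <- make_bc_set(11)
  ## closed form at the printed properties (the paper's printed 2250 is not
  ## reproducible from its own numbers; the formula is implemented as stated)
  expect_equal(reynolds_number(bc, 1.91, "inlet_IVC"),
               4 * 1.06 * 110 / (pi * 1.91 * 0.035), tolerance = 1e-12)
  expect_equal(round(reynolds_number(bc, 1.91, "inlet_IVC")), 2221)
  bc0 <- bc; bc0$inlet_flows["inlet_IVC"] <- 0
  expect_equal(reynolds_number(bc0, 1.91, "inlet_IVC"), 0)
  bc2 <- bc; bc2$inlet_flows["inlet_IVC"] <- 220
  expect_equal(reynolds_number(bc2, 1.91, "inlet_IVC"),
               2 * reynolds_number(bc, 1.91, "inlet_IVC"))
  bcmu <- bc; bcmu$fluid$viscosity <- 0.07
  expect_equal(reynolds_number(bcmu, 1.91, "inlet_IVC"),
               reynolds_number(bc, 1.91, "inlet_IVC") / 2)
  expect_error(reynolds_number(bc, 0), "diameter")
})

test_that("target PA pressures follow the printed affine relations", {
  expect_equal(mcl_target_pa_pressure(11, "RPA"), 14.14, tolerance = 1e-12)
  expect_equal(mcl_target_pa_pressure(0, "LPA"), 6.0)
  expect_equal(mcl_target_pa_pressure(7, "LPA"), 11.39, tolerance = 1e-12)
})

test_that("synthetic measurements reproduce bias and noise reproducibly", {
  m0 <- synth_mcl_measurements(c(1, 2), bias = 0, noise_sd = 0)
  expect_equal(m0$dP_mmHg, c(1, 2))
  mb <- synth_mcl_measurements(c(1, 1, 1), bias = 0.23, noise_sd = 0)
  expect_equal(mb$dP_mmHg, rep(1.23, 3))
  n <- 1000; sd0 <- 0.1
  ms <- synth_mcl_measurements(rep(2, n), bias = 0.5, noise_sd = sd0,
                               seed = 7)
  emp_bias <- mean(ms$dP_mmHg - ms$dP_model_mmHg)
  expect_lt(abs(emp_bias - 0.5), 3 * sd0 / sqrt(n))
  ms2 <- synth_mcl_measurements(rep(2, n), bias = 0.5, noise_sd = sd0,
                                seed = 7)
  expect_identical(ms$dP_mmHg, ms2$dP_mmHg)
})
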