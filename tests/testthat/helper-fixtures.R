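# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## Poiseuille pipe at Re = 50 (bench fluid), with boundary layers, solved
## steady.  Used by the flow, endpoint and acceptance oracles.
poiseuille_case <- function() {
  fixture("poiseuille", function() {
    D <- 1.91; L <- 10
    fl <- fluid_properties()
    Q <- 50 * pi * D * fl$viscosity / (4 * fl$density)
    mesh <- make_pipe_mesh(D, L, 0.25, n_boundary_layers = 2)
    bc <- make_bc_set(5)
    bc$inlet_flows <- c(inlet = Q)
    bc$outlet_resistances <- c(outlet = 0)
    field <- solve_steady(mesh, bc, solver_settings(steady_mode = TRUE))
    list(mesh = mesh, bc = bc, field = field, Q = Q, D = D, L = L,
         mu = fl$viscosity, rho = fl$density)
  })
}

## Small pipe with the calibrated RPA resistance on its outlet.
resistance_pipe_case <- function() {
  fixture("resistance_pipe", function() {
    D <- 1.91; L <- 4
    Q <- 95.33
    mesh <- make_pipe_mesh(D, L, 0.3)
    bc <- make_bc_set(5)
    bc$inlet_flows <- c(inlet = Q)
    bc$outlet_resistances <- c(outlet = 204.51)
    field <- solve_steady(mesh, bc, solver_settings(steady_mode = TRUE))
    list(mesh = mesh, bc = bc, field = field, Q = Q, R = 204.51)
  })
}

## Planar cross-junction analog (cheap), blank housing, solved at one CO.
junction2d_case <- function(CO = 5, model = "blank", h = 0.12) {
  key <- sprintf("jn2d_%s_%g_%g", model, CO, h)
  fixture(key, function() {
    mesh <- make_junction_mesh(model_geometry(model), h, dim = 2L)
    bc <- make_bc_set(CO)
    field <- solve_steady(mesh, bc,
                          solver_settings(steady_mode = TRUE,
                                          steady_max_steps = 80L))
    list(mesh = mesh, bc = bc, field = field)
  })
}

## Uniform synthetic flow field on a mesh (for transport oracles).
uniform_flow_field <- function(mesh, U) {
  n <- nrow(mesh$nodes)
  v <- matrix(0, n, mesh$dim)
  v[, 1L] <- U
  structure(list(times = 0, v = list(v), p = list(numeric(n)),
                 mesh = mesh, info = list()), class = "flow_field")
}

## Synthetic wall-traction series from explicit per-time traction vectors
## (each a single 3-vector applied at every node of a trivial 2-node set).
synthetic_traction_series <- function(taus, times = seq_along(taus) - 1) {
  d <- length(taus[[1L]])
  tau <- lapply(taus, function(t) matrix(rep(t, each = 2L), 2L, d))
  structure(list(groups = "wall", nodes = 1:2, times = times, tau = tau,
                 normal = matrix(rep(c(rep(0, d - 1L), 1), each = 2L), 2L, d),
                 node_area = c(1, 1)),
            class = "wall_traction_series")
}

## Synthetic scalar field from a matrix of nodal histories (nodes x times).
synthetic_scalar_field <- function(P, times, mesh = NULL) {
  structure(list(times = times,
                 phi = lapply(seq_along(times), function(k) P[, k]),
                 kappa = 0, mesh = mesh), class = "scalar_field")
}
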