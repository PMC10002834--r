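#' Solver settings
#'
#' Numerical controls for the stabilized flow solver.  The bench-replication
#' protocol uses `dt = 0.001` s, `t_end = 5` s and snapshots every 0.02 s;
#' steady mode (pseudo-transient continuation) is the desk-scale default.
#'
#' @param dt time step (s).
#' @param t_end final time (s).
#' @param save_every snapshot cadence (s); must be an integer multiple of `dt`.
#' @param rho_inf generalized-alpha spectral radius in `[0, 1]`.
#' @param newton_tol relative nonlinear residual tolerance.
#' @param newton_max_iter maximum nonlinear corrections per time step.
#' @param backflow_beta outlet backflow-stabilization coefficient in `[0, 1]`.
#' @param steady_mode logical; solve for a stationary state by
#'   pseudo-transient continuation.
#' @param steady_max_steps cap on pseudo-time steps (all stages combined).
#' @param mu_continuation viscosity-continuation factors for steady solves
#'   (each stage multiplies the viscosity, warm-starting the next; the last
#'   entry must be 1).
#' @param relax Newton relaxation factor.
#' @param verbose print per-step residuals.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(dt = 0.001, t_end = 5, save_every = 0.02,
                            rho_inf = 0.5, newton_tol = 1e-3,
                            newton_max_iter = 6L, backflow_beta = 0.2,
                            steady_mode = FALSE, steady_max_steps = 60L,
                            mu_continuation = c(16, 4, 1),
                            relax = 1.0, verbose = FALSE) {
  if (dt <= 0) stop("solver_settings: dt must be positive")
  n_sub <- save_every / dt
  if (abs(n_sub - round(n_sub)) > 1e-8)
    stop("solver_settings: save_every must be an integer multiple of dt")
  if (rho_inf < 0 || rho_inf > 1)
    stop("solver_settings: rho_inf must lie in [0, 1]")
  if (backflow_beta < 0 || backflow_beta > 1)
    stop("solver_settings: backflow_beta must lie in [0, 1]")
  if (utils::tail(mu_continuation, 1L) != 1)
    stop("solver_settings: mu_continuation must end at factor 1")
  structure(list(dt = dt, t_end = t_end, save_every = save_every,
                 rho_inf = rho_inf, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 backflow_beta = backflow_beta, steady_mode = steady_mode,
                 steady_max_steps = as.integer(steady_max_steps),
                 mu_continuation = mu_continuation,
                 relax = relax, verbose = verbose),
            class = "solver_settings")
}

## ---- boundary machinery ----------------------------------------------------

#' Nodal inlet velocity profile
#'
#' Builds the nodal boundary velocity on a planar inlet patch carrying
#' volumetric flow `Q` directed along the inward normal.  The parabolic kind
#' vanishes on the patch rim and is rescaled so the discrete flux equals `Q`
#' exactly; the plug kind is uniform at `Q / A`.
#'
#' @param mesh an [fe_mesh].
#' @param group inlet face-group name.
#' @param Q volumetric flow (cm^3/s), >= 0.
#' @param kind `"parabolic"` or `"plug"`.
#' @return List with `nodes` (indices), `vel` (matrix of nodal velocities),
#'   `normal` (outward unit normal), `area` (patch area).
#' @export
inlet_profile <- function(mesh, group, Q, kind = c("parabolic", "plug")) {
  kind <- match.arg(kind)
  sel <- which(mesh$face_labels == group)
  if (!length(sel)) stop(sprintf("inlet_profile: group '%s' empty", group))
  fg <- face_geometry(mesh)
  n_avg <- colSums(fg$normal[sel, , drop = FALSE] * fg$area[sel])
  n_avg <- n_avg / sqrt(sum(n_avg^2))
  ## planarity check
  nds <- group_nodes(mesh, group)
  pts <- mesh$nodes[nds, , drop = FALSE]
  proj <- as.vector(pts %*% n_avg)
  span <- max(proj) - min(proj)
  patch_h <- sqrt(sum(fg$area[sel]))
  if (span > 0.05 * patch_h)
    stop(sprintf("inlet_profile: face group '%s' is not planar", group))
  area <- sum(fg$area[sel])
  ## area-weighted centroid
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  cen <- centroid_of(mesh$nodes, faces)
  cg <- colSums(cen * fg$area[sel]) / area
  if (Q == 0) {
    vel <- matrix(0, length(nds), mesh$dim)
    return(list(nodes = nds, vel = vel, normal = n_avg, area = area))
  }
  if (kind == "plug") {
    w <- rep(1, length(nds))
    scale <- Q / area
  } else {
    d <- sweep(pts, 2L, cg)
    d <- d - outer(as.vector(d %*% n_avg), n_avg)   # in-plane offset
    r <- sqrt(rowSums(d^2))
    Rmax <- max(r)
    w <- pmax(0, 1 - (r / Rmax)^2)
    ## discrete flux of the unit-peak profile
    wf <- matrix(0, nrow(mesh$nodes), 1L)
    wf[nds, 1L] <- w
    flux <- 0
    for (k in seq_along(sel)) {
      f <- faces[k, ]
      flux <- flux + fg$area[sel[k]] * mean(wf[f, 1L])
    }
    if (flux <= 0) stop("inlet_profile: degenerate parabolic profile")
    scale <- Q / flux
  }
  vel <- -outer(w * scale, n_avg)    # inward
  list(nodes = nds, vel = vel, normal = n_avg, area = area)
}

#' Volumetric flux through a face group
#'
#' Exact integral of the linearly interpolated velocity normal component
#' over the group's faces (positive = outflow along outward normals).
#'
#' @param mesh an [fe_mesh].
#' @param v nodal velocity matrix.
#' @param group face-group name.
#' @return Flux (cm^3/s).
#' @export
boundary_flux <- function(mesh, v, group) {
  sel <- which(mesh$face_labels == group)
  if (!length(sel)) stop(sprintf("boundary_flux: group '%s' empty", group))
  fg <- face_geometry(mesh)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  acc <- 0
  for (j in seq_len(ncol(faces))) {
    vj <- v[faces[, j], , drop = FALSE]
    acc <- acc + rowSums(vj * fg$normal[sel, , drop = FALSE])
  }
  sum(fg$area[sel] * acc / ncol(faces))
}

## lumped boundary vector s with s[(a-1)*d + i] = int_G N_a n_i dGamma
outlet_weight_vector <- function(mesh, group) {
  d <- mesh$dim
  sel <- which(mesh$face_labels == group)
  if (!length(sel)) stop(sprintf("outlet group '%s' empty", group))
  fg <- face_geometry(mesh)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  s <- numeric(nrow(mesh$nodes) * d)
  nfn <- ncol(faces)
  for (j in seq_len(nfn)) {
    for (i in seq_len(d)) {
      idx <- (faces[, j] - 1L) * d + i
      contrib <- fg$area[sel] * fg$normal[sel, i] / nfn
      t <- tapply(contrib, idx, sum)
      at <- as.integer(names(t))
      s[at] <- s[at] + as.numeric(t)
    }
  }
  s
}

#' Resistance outflow traction
#'
#' Implements the resistance boundary condition `h = -R Q n` on an outlet
#' group: the weak-form boundary traction equals minus the resistance times
#' the instantaneous outlet flux along the outward normal (plus a distal
#' pressure offset), coupled implicitly through the flux of the current
#' iterate.
#'
#' @param mesh an [fe_mesh].
#' @param group outlet face-group name.
#' @param R resistance (dyn.s/cm^5), >= 0.
#' @param v nodal velocity matrix (current state).
#' @param distal_pressure downstream pressure offset (dyn/cm^2).
#' @return List with `Q` (flux, cm^3/s), `traction_normal` (the applied
#'   normal traction `-(R Q + P0)`, dyn/cm^2), and `force` (assembled nodal
#'   force vector on velocity dofs).
#' @export
apply_resistance_outlet <- function(mesh, group, R, v, distal_pressure = 0) {
  if (R < 0) stop("apply_resistance_outlet: R must be non-negative")
  s <- outlet_weight_vector(mesh, group)
  Q <- sum(s * as.vector(t(v)))
  p_eff <- R * Q + distal_pressure
  list(Q = Q, traction_normal = -p_eff, force = p_eff * s, weight = s)
}

#' Backflow stabilization correction
#'
#' Convective-inflow penalty `-beta * rho * (v.n)_- * v` on outlet faces with
#' locally reversed flow; identically zero where `v.n >= 0`.  The returned
#' `force` is the weak-form residual contribution, i.e. a drag carrying the
#' sign of the local velocity (as viscous resistance does).
#'
#' @param mesh an [fe_mesh].
#' @param group outlet face-group name.
#' @param v nodal velocity matrix.
#' @param beta coefficient in `[0, 1]`.
#' @param rho fluid density (g/cm^3).
#' @return List with `force` (nodal force vector on velocity dofs; the
#'   residual contribution) and `diag` (lumped Jacobian diagonal weights).
#' @export
backflow_correction <- function(mesh, group, v, beta, rho) {
  d <- mesh$dim
  nvd <- nrow(mesh$nodes) * d
  force <- numeric(nvd)
  dg <- numeric(nvd)
  if (beta <= 0) return(list(force = force, diag = dg))
  sel <- which(mesh$face_labels == group)
  fg <- face_geometry(mesh)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  nfn <- ncol(faces)
  for (k in seq_along(sel)) {
    f <- faces[k, ]
    nrm <- fg$normal[sel[k], ]
    w <- fg$area[sel[k]] / nfn
    for (j in f) {
      vn <- sum(v[j, ] * nrm)
      if (vn < 0) {
        idx <- (j - 1L) * d + seq_len(d)
        force[idx] <- force[idx] - beta * rho * vn * v[j, ] * w
        dg[idx] <- dg[idx] - beta * rho * vn * w
      }
    }
  }
  list(force = force, diag = dg)
}

## Dirichlet data: wall no-slip + inlet profiles. Wall wins on shared nodes.
dirichlet_data <- function(mesh, bc) {
  d <- mesh$dim
  n <- nrow(mesh$nodes)
  vbc <- matrix(NA_real_, n, d)
  for (g in names(bc$inlet_flows)) {
    pr <- inlet_profile(mesh, g, bc$inlet_flows[[g]], bc$inlet_profile)
    vbc[pr$nodes, ] <- pr$vel
  }
  wall_groups <- unique(grep("^wall", mesh$face_labels, value = TRUE))
  if (length(wall_groups)) {
    wn <- group_nodes(mesh, wall_groups)
    vbc[wn, ] <- 0
  }
  ## rescale each inlet so the discrete flux matches despite wall-clipped rims
  for (g in names(bc$inlet_flows)) {
    Qtarget <- bc$inlet_flows[[g]]
    if (Qtarget == 0) next
    vtmp <- vbc
    vtmp[is.na(vtmp)] <- 0
    Qnow <- -boundary_flux(mesh, vtmp, g)
    pn <- group_nodes(mesh, g)
    if (Qnow <= 1e-9 * Qtarget) {
      ## cap only one element wide: every port node sits on the rim.  Fall
      ## back to a plug profile with the inlet taking precedence there.
      pr <- inlet_profile(mesh, g, Qtarget, "plug")
      vbc[pr$nodes, ] <- pr$vel
      vtmp <- vbc
      vtmp[is.na(vtmp)] <- 0
      Qnow <- -boundary_flux(mesh, vtmp, g)
      vbc[pn, ] <- vbc[pn, , drop = FALSE] * (Qtarget / Qnow)
    } else {
      free <- pn[!pn %in% group_nodes(mesh, wall_groups)]
      vbc[free, ] <- vbc[free, , drop = FALSE] * (Qtarget / Qnow)
    }
  }
  fixed <- which(!is.na(vbc[, 1L]))
  idx <- as.vector(t(outer(fixed, seq_len(d), function(a, i) (a - 1L) * d + i)))
  vals <- as.vector(t(vbc[fixed, , drop = FALSE]))
  list(dofs = idx, values = vals, vbc = vbc, fixed_nodes = fixed)
}

## ---- nonlinear solve drivers ----------------------------------------------

new_flow_field <- function(mesh, times, vlist, plist, info = list()) {
  structure(list(times = times, v = vlist, p = plist, mesh = mesh,
                 info = info), class = "flow_field")
}

#' @export
#' @method print flow_field
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d snapshots on [%g, %g] s, %d nodes\n",
              length(x$times), min(x$times), max(x$times), nrow(x$mesh$nodes)))
  invisible(x)
}

## Cached assembly path: the sparsity pattern of the element contributions
## is fixed per mesh, so duplicate triplets are pre-mapped once and later
## assemblies only accumulate values.
make_assembly_cache <- function(i, j, ndof) {
  key <- as.numeric(i) + (as.numeric(j) - 1) * ndof
  o <- order(key)
  ks <- key[o]
  first <- c(TRUE, ks[-1L] != ks[-length(ks)])
  gid <- cumsum(first)
  map <- integer(length(key))
  map[o] <- gid
  ui <- i[o][first]; uj <- j[o][first]
  tmpl <- Matrix::sparseMatrix(i = ui, j = uj, x = as.numeric(seq_along(ui)),
                               dims = c(ndof, ndof))
  list(map = map, nnz = sum(first), tmpl = tmpl,
       xperm = as.integer(tmpl@x))
}

matrix_from_cache <- function(cache, x) {
  acc <- accumulate_triplets_cpp(cache$map, x, cache$nnz)
  M <- cache$tmpl
  M@x <- acc[cache$xperm]
  M
}

assemble_system <- function(mesh, v, p, vdot, bc, inv_dt2, c_dot, c_vel,
                            include_mass, beta, cache = NULL) {
  rho <- bc$fluid$density; mu <- bc$fluid$viscosity
  out <- ns_assemble_cpp(mesh$nodes, mesh$cells, v, p, vdot,
                         rho, mu, inv_dt2, c_dot, c_vel, include_mass)
  ndof <- out$ndof
  resid <- out$resid
  if (is.null(cache)) cache <- make_assembly_cache(out$i, out$j, ndof)
  J <- matrix_from_cache(cache, out$x)
  ## resistance outlets (implicit rank-one coupling)
  for (g in names(bc$outlet_resistances)) {
    rr <- apply_resistance_outlet(mesh, g, bc$outlet_resistances[[g]], v,
                                  bc$distal_pressure)
    nvd <- nrow(mesh$nodes) * mesh$dim
    resid[seq_len(nvd)] <- resid[seq_len(nvd)] + rr$force
    if (bc$outlet_resistances[[g]] > 0) {
      s <- rr$weight
      nz <- which(s != 0)
      J[nz, nz] <- J[nz, nz] +
        bc$outlet_resistances[[g]] * c_vel * outer(s[nz], s[nz])
    }
    bf <- backflow_correction(mesh, g, v, beta, rho)
    resid[seq_along(bf$force)] <- resid[seq_along(bf$force)] + bf$force
    nzb <- which(bf$diag != 0)
    if (length(nzb))
      J <- J + Matrix::sparseMatrix(i = nzb, j = nzb,
                                    x = c_vel * bf$diag[nzb],
                                    dims = c(ndof, ndof))
  }
  list(J = J, resid = resid, ndof = ndof, cache = cache)
}

## Per-node interleaved dof permutation (v1..vd, p per node): dramatically
## reduces sparse-LU fill compared to the field-blocked assembly ordering.
interleave_perm <- function(n, d) {
  perm <- integer(n * (d + 1L))
  for (i in seq_len(d))
    perm[(seq_len(n) - 1L) * (d + 1L) + i] <- (seq_len(n) - 1L) * d + i
  perm[seq_len(n) * (d + 1L)] <- n * d + seq_len(n)
  perm
}

## Tiny Jacobian-only shift on the pressure diagonal.  Snapped meshes can
## carry sliver patches whose local pressure mode is numerically floating;
## the shift bounds its update without touching the residual (so converged
## solutions are unaffected).
regularize_pressure_block <- function(J, nvd, n) {
  pdofs <- nvd + seq_len(n)
  eps_p <- 1e-6 * stats::median(abs(Matrix::diag(J)[pdofs]))
  if (!is.finite(eps_p) || eps_p <= 0) return(J)
  J + Matrix::sparseMatrix(i = pdofs, j = pdofs, x = rep(eps_p, n),
                           dims = dim(J))
}

apply_dirichlet_rows <- function(J, resid, dofs) {
  resid[dofs] <- 0
  keep <- rep(1, nrow(J))
  keep[dofs] <- 0
  J <- Matrix::Diagonal(x = keep) %*% J +
    Matrix::sparseMatrix(i = dofs, j = dofs, x = rep(1, length(dofs)),
                         dims = dim(J))
  list(J = J, resid = resid)
}

#' Steady flow by pseudo-transient continuation
#'
#' Solves the stationary stabilized Navier-Stokes system by damped Newton
#' iteration with switched-evolution pseudo-time relaxation: each step adds a
#' lumped-mass damping `rho / dtau` whose pseudo-step grows as the steady
#' residual falls, recovering full Newton near the solution.  Reports
#' non-convergence (genuinely unsteady flow or solver failure) explicitly.
#'
#' @param mesh an [fe_mesh].
#' @param bc a [make_bc_set] object.
#' @param settings a [solver_settings] object.
#' @param v0,p0 optional warm-start state (e.g. interpolated from a coarser
#'   mesh); when supplied, the viscosity-continuation stages are skipped and
#'   the solve starts at the physical viscosity.
#' @return A `flow_field` with one snapshot; `$info` carries `converged`,
#'   `residuals`, `n_steps`, and `flag` (`"converged"`, `"unsteady_physics"`
#'   or `"solver_failure"`).
#' @export
solve_steady <- function(mesh, bc, settings = solver_settings(steady_mode = TRUE),
                         v0 = NULL, p0 = NULL) {
  d <- mesh$dim
  n <- nrow(mesh$nodes)
  dd <- dirichlet_data(mesh, bc)
  warm <- !is.null(v0)
  v <- if (warm) v0 else matrix(0, n, d)
  v[dd$fixed_nodes, ] <- dd$vbc[dd$fixed_nodes, ]
  p <- if (warm && !is.null(p0)) p0 else numeric(n)
  vdot <- matrix(0, n, d)
  nvd <- n * d
  rho <- bc$fluid$density

  ## pseudo-time scale from the advective crossing of a typical element
  hmed <- stats::median(abs(cell_volumes(mesh)))^(1 / d)
  vmax <- max(sqrt(rowSums(v^2)), 1e-12)
  dtau0 <- 2 * hmed / vmax
  lumped <- lumped_mass(mesh)
  res_hist <- numeric(0)
  total_steps <- 0L
  failure <- FALSE

  ## fixed residual scale: the steady residual of the initial (BC-only) state
  ## at the physical viscosity
  sys0 <- assemble_system(mesh, v, p, vdot, bc, inv_dt2 = 0,
                          c_dot = 0, c_vel = 1, include_mass = FALSE,
                          beta = settings$backflow_beta)
  acache <- sys0$cache
  res_scale <- sqrt(sum(sys0$resid[-dd$dofs]^2))
  if (res_scale < 1e-12)
    return(new_flow_field(mesh, 0, list(v), list(p),
                          info = list(converged = TRUE, flag = "converged",
                                      residuals = 0, n_steps = 1L)))

  iperm <- interleave_perm(n, d)
  ## viscosity continuation: damped Newton at elevated viscosity first, each
  ## stage warm-starting the next, so the advection-dominated final stage
  ## starts near its solution.
  stages <- if (warm) 1 else settings$mu_continuation
  stage_tols <- c(rep(3e-2, length(stages) - 1L), settings$newton_tol)
  converged <- FALSE
  for (sidx in seq_along(stages)) {
    bc_s <- bc
    bc_s$fluid$viscosity <- bc$fluid$viscosity * stages[sidx]
    tol_abs <- stage_tols[sidx] * res_scale
    ## linearized backward-Euler pseudo-stepping: the damping matrix
    ## rho M / dtau keeps each step stable; dtau is floored so the state
    ## always moves and grows toward full Newton as the residual falls.
    dtau_min <- dtau0 / 8
    dtau_max <- 1e3 * dtau0
    ## a warm start sits near the root: begin in the full-Newton regime
    dtau <- if (warm) dtau_max else dtau0
    rn_best <- Inf
    best <- NULL
    stage_converged <- FALSE
    n_worse <- 0L
    n_lin_fail <- 0L
    fact <- NULL
    fact_age <- 0L
    while (total_steps < settings$steady_max_steps) {
      sys <- assemble_system(mesh, v, p, vdot, bc_s,
                             inv_dt2 = 0, c_dot = 0, c_vel = 1,
                             include_mass = FALSE,
                             beta = settings$backflow_beta, cache = acache)
      rn <- sqrt(sum(sys$resid[-dd$dofs]^2))
      res_hist <- c(res_hist, rn)
      total_steps <- total_steps + 1L
      if (settings$verbose)
        message(sprintf("  stage %d step %d: |R| = %.3e (dtau = %.2e)",
                        sidx, total_steps, rn, dtau))
      if (is.finite(rn) && rn < tol_abs) { stage_converged <- TRUE; break }
      if (!is.finite(rn) || (!is.null(best) && rn > 1e3 * rn_best)) {
        ## catastrophic divergence: restart from the best state, damped
        v <- best$v; p <- best$p
        sys <- best$sys; rn <- rn_best
        dtau <- max(dtau / 8, dtau_min)
        n_worse <- 0L
      } else if (rn <= rn_best) {
        rn_best <- rn
        best <- list(v = v, p = p, sys = sys)
        dtau <- min(dtau * 2, dtau_max)
        n_worse <- 0L
      } else if (rn < 0.08 * res_scale || dtau >= 0.9 * dtau_max) {
        ## near the root: push to full Newton, which contracts even onto a
        ## linearly unstable steady state (damped stepping cannot)
        dtau <- dtau_max
        n_worse <- n_worse + 1L
        if (n_worse > 10L) {
          v <- best$v; p <- best$p
          break
        }
      } else {
        dtau <- max(dtau / 2, dtau_min)
        n_worse <- 0L
      }
      mdiag <- rep(rho * lumped / dtau, each = d)
      J <- sys$J + Matrix::sparseMatrix(i = seq_len(nvd), j = seq_len(nvd),
                                        x = mdiag, dims = dim(sys$J))
      J <- regularize_pressure_block(J, nvd, n)
      ad <- apply_dirichlet_rows(J, sys$resid, dd$dofs)
      ## modified Newton in the full-Newton push: reuse the factorization a
      ## few steps (residual-based convergence is unaffected); solve in the
      ## per-node interleaved ordering to limit LU fill
      push_active <- dtau >= 0.9 * dtau_max
      if (!push_active || is.null(fact) || fact_age >= 3L || n_worse > 0L) {
        fact <- tryCatch(Matrix::lu(ad$J[iperm, iperm]),
                         error = function(e) NULL)
        fact_age <- 0L
      }
      du <- if (is.null(fact)) NULL else
        tryCatch({
          dp_ <- as.numeric(Matrix::solve(fact, -ad$resid[iperm]))
          du_ <- numeric(length(dp_)); du_[iperm] <- dp_; du_
        }, error = function(e) NULL)
      fact_age <- fact_age + 1L
      if (is.null(du) || any(!is.finite(du))) {
        ## ill-conditioned step: retreat to the best state, heavily damped
        n_lin_fail <- n_lin_fail + 1L
        if (is.null(best) || n_lin_fail > 6L) {
          failure <- TRUE
          break
        }
        v <- best$v; p <- best$p
        dtau <- max(dtau / 8, 1e-3 * dtau_min)
        next
      }
      v <- v + settings$relax * matrix(du[seq_len(nvd)], n, d, byrow = TRUE)
      p <- p + settings$relax * du[nvd + seq_len(n)]
    }
    if (failure) break
    if (sidx == length(stages)) converged <- stage_converged
  }
  flag <- if (failure) "solver_failure"
          else if (converged) "converged" else "unsteady_physics"
  new_flow_field(mesh, 0, list(v), list(p),
                 info = list(converged = converged, flag = flag,
                             residuals = res_hist, n_steps = length(res_hist)))
}

lumped_mass <- function(mesh) {
  vol <- abs(cell_volumes(mesh))
  n <- nrow(mesh$nodes)
  m <- numeric(n)
  nen <- ncol(mesh$cells)
  for (j in seq_len(nen)) {
    t <- tapply(vol / nen, mesh$cells[, j], sum)
    idx <- as.integer(names(t))
    m[idx] <- m[idx] + as.numeric(t)
  }
  m
}

#' Transient flow with generalized-alpha time integration
#'
#' Second-order generalized-alpha stepping for the first-order stabilized
#' system, with Newton-Raphson correction at each step.  Snapshots are
#' retained at the `save_every` cadence.
#'
#' @inheritParams solve_steady
#' @param v0,p0 optional initial state (defaults: rest).
#' @return A `flow_field` with snapshots at the save cadence (plus t = 0);
#'   `$info` carries per-step residual histories.
#' @export
solve_transient <- function(mesh, bc, settings = solver_settings(),
                            v0 = NULL, p0 = NULL) {
  d <- mesh$dim
  n <- nrow(mesh$nodes)
  dd <- dirichlet_data(mesh, bc)
  v <- if (is.null(v0)) matrix(0, n, d) else v0
  v[dd$fixed_nodes, ] <- dd$vbc[dd$fixed_nodes, ]
  p <- if (is.null(p0)) numeric(n) else p0
  vdot <- matrix(0, n, d)
  nvd <- n * d
  dt <- settings$dt
  rho_inf <- settings$rho_inf
  am <- 0.5 * (3 - rho_inf) / (1 + rho_inf)
  af <- 1 / (1 + rho_inf)
  gam <- 0.5 + am - af
  nstep <- as.integer(round(settings$t_end / dt))
  nsub <- as.integer(round(settings$save_every / dt))
  times <- 0
  vlist <- list(v); plist <- list(p)
  res_log <- list()

  for (step in seq_len(nstep)) {
    v_n <- v; vdot_n <- vdot
    ## same-velocity predictor
    vdot_new <- (gam - 1) / gam * vdot_n
    v_new <- v_n
    p_new <- p
    hist <- numeric(0)
    converged <- FALSE
    for (it in seq_len(settings$newton_max_iter)) {
      v_af <- v_n + af * (v_new - v_n)
      vdot_am <- vdot_n + am * (vdot_new - vdot_n)
      sys <- assemble_system(mesh, v_af, p_new, vdot_am, bc,
                             inv_dt2 = 4 / dt^2,
                             c_dot = am / (gam * dt), c_vel = af,
                             include_mass = TRUE,
                             beta = settings$backflow_beta,
                             cache = if (exists("acache")) acache else NULL)
      acache <- sys$cache
      rn <- sqrt(sum(sys$resid[-dd$dofs]^2))
      hist <- c(hist, rn)
      if (it == 1L) r0 <- max(rn, 1e-14)
      if (rn / r0 < settings$newton_tol || rn < 1e-10) { converged <- TRUE; break }
      ad <- apply_dirichlet_rows(regularize_pressure_block(sys$J, nvd, n),
                                 sys$resid, dd$dofs)
      if (!exists("iperm")) iperm <- interleave_perm(n, d)
      du <- tryCatch({
        dp_ <- as.numeric(Matrix::solve(ad$J[iperm, iperm], -ad$resid[iperm]))
        du_ <- numeric(length(dp_)); du_[iperm] <- dp_; du_
      }, error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du)))
        stop(sprintf(paste0("transient solve: singular linear system at step ",
                            "%d (assembly stage)"), step))
      dv <- settings$relax * matrix(du[seq_len(nvd)], n, d, byrow = TRUE)
      v_new <- v_new + dv
      p_new <- p_new + settings$relax * du[nvd + seq_len(n)]
      vdot_new <- vdot_new + dv / (gam * dt)
    }
    if (!converged && hist[length(hist)] > 10 * r0)
      stop(sprintf(paste0("transient solve: Newton divergence at step %d; ",
                          "residual history: %s"), step,
                   paste(signif(hist, 3), collapse = ", ")))
    v <- v_new; p <- p_new; vdot <- vdot_new
    res_log[[length(res_log) + 1L]] <- hist
    if (step %% nsub == 0L) {
      times <- c(times, step * dt)
      vlist[[length(vlist) + 1L]] <- v
      plist[[length(plist) + 1L]] <- p
    }
  }
  new_flow_field(mesh, times, vlist, plist,
                 info = list(newton_residuals = res_log,
                             settings = settings))
}

#' Mass-conservation audit
#'
#' Per-snapshot relative imbalance `|sum Q_in - sum Q_out| / sum Q_in`
#' between inlet and outlet boundary fluxes; when total inflow is zero the
#' absolute imbalance is returned and flagged.
#'
#' @param field a `flow_field`.
#' @return Data frame with columns `time`, `imbalance`, `absolute` (flag).
#' @export
check_mass_conservation <- function(field) {
  mesh <- field$mesh
  groups <- unique(mesh$face_labels)
  inlets <- grep("^inlet", groups, value = TRUE)
  outlets <- grep("^outlet", groups, value = TRUE)
  out <- data.frame(time = field$times, imbalance = NA_real_,
                    absolute = FALSE)
  for (k in seq_along(field$times)) {
    v <- field$v[[k]]
    qin <- -sum(vapply(inlets, function(g) boundary_flux(mesh, v, g), 0))
    qout <- sum(vapply(outlets, function(g) boundary_flux(mesh, v, g), 0))
    if (abs(qin) < 1e-12) {
      out$imbalance[k] <- abs(qin - qout)
      out$absolute[k] <- TRUE
    } else {
      out$imbalance[k] <- abs(qin - qout) / abs(qin)
    }
  }
  out
}
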