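#' Virtual-dye release region
#'
#' Axis-aligned cube of dye, matching the 3.5 cm cube released at the pump
#' center in the washout protocol.
#'
#' @param center numeric coordinates of the cube center (cm).
#' @param edge edge length (cm, default 3.5).
#' @return A `dye_region`.
#' @export
dye_region <- function(center = c(0, 0, 0), edge = 3.5) {
  if (edge < 0) stop("dye_region: edge must be non-negative")
  structure(list(shape = "axis_aligned_cube", center = center, edge = edge),
            class = "dye_region")
}

in_region <- function(region, pts) {
  d <- ncol(pts)
  cen <- region$center[seq_len(d)]
  off <- abs(sweep(pts, 2L, cen))
  apply(off <= region$edge / 2 + 1e-12, 1L, all)
}

#' Initialize the dye field
#'
#' Nodal concentration phi = 1 inside the release region, 0 elsewhere
#' (sharp, no smoothing).
#'
#' @param mesh an [fe_mesh].
#' @param region a [dye_region].
#' @return A `scalar_field` with a single t = 0 snapshot.
#' @export
init_dye <- function(mesh, region) {
  inside <- in_region(region, mesh$nodes)
  if (!any(inside))
    stop("init_dye: release region is disjoint from the fluid domain")
  phi <- as.numeric(inside)
  structure(list(times = 0, phi = list(phi), kappa = NA_real_,
                 mesh = mesh), class = "scalar_field")
}

#' Advance the dye field
#'
#' Implicit (backward-Euler) stabilized advection-diffusion transport of the
#' dye on a frozen or time-interpolated velocity field, with SUPG weighting
#' and residual-based discontinuity capturing (lagged one step).  The dye
#' concentration is held at 0 on the inlets; transport is one-way (the
#' velocity is never modified).
#'
#' @param field0 a `scalar_field` (initial snapshot).
#' @param velocity a `flow_field`; a single snapshot is used frozen,
#'   multiple snapshots are linearly interpolated in time.
#' @param dt scalar transport time step (s); implicit, so it may exceed the
#'   flow time step (default 0.02 s, the save cadence).
#' @param t_end transport horizon (s, default 5).
#' @param kappa molecular diffusivity (cm^2/s, default 1e-4).
#' @param dc_scale scaling of the discontinuity-capturing diffusivity.
#' @return A `scalar_field` with snapshots every `dt`.
#' @export
advance_scalar <- function(field0, velocity, dt = 0.02, t_end = 5,
                           kappa = 1e-4, dc_scale = 1) {
  mesh <- field0$mesh
  if (dt <= 0) stop("advance_scalar: dt must be positive")
  n <- nrow(mesh$nodes)
  inlet_groups <- unique(grep("^inlet", mesh$face_labels, value = TRUE))
  fixed <- if (length(inlet_groups)) group_nodes(mesh, inlet_groups) else integer(0)
  phi <- field0$phi[[length(field0$phi)]]
  phi[fixed] <- 0
  phi_prev <- phi
  nstep <- as.integer(round(t_end / dt))
  times <- field0$times[length(field0$times)]
  phis <- list(phi)
  vk <- length(velocity$times)
  v_at <- function(t) {
    if (vk == 1L) return(velocity$v[[1L]])
    if (t <= velocity$times[1L]) return(velocity$v[[1L]])
    if (t >= velocity$times[vk]) return(velocity$v[[vk]])
    i <- findInterval(t, velocity$times)
    w <- (t - velocity$times[i]) / (velocity$times[i + 1L] - velocity$times[i])
    (1 - w) * velocity$v[[i]] + w * velocity$v[[i + 1L]]
  }
  t_now <- times[1L]
  for (step in seq_len(nstep)) {
    v <- v_at(t_now + dt / 2)
    sys <- scalar_assemble_cpp(mesh$nodes, mesh$cells, v, phi, phi_prev,
                               kappa, dt, dc_scale)
    A <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$ax, dims = c(n, n))
    B <- Matrix::sparseMatrix(i = sys$i, j = sys$j, x = sys$bx, dims = c(n, n))
    rhs <- as.numeric(B %*% phi)
    if (length(fixed)) {
      rhs[fixed] <- 0
      A[fixed, ] <- 0
      A <- A + Matrix::sparseMatrix(i = fixed, j = fixed,
                                    x = rep(1, length(fixed)), dims = c(n, n))
    }
    phi_prev <- phi
    phi <- as.numeric(Matrix::solve(A, rhs))
    t_now <- t_now + dt
    times <- c(times, t_now)
    phis[[length(phis) + 1L]] <- phi
  }
  structure(list(times = times, phi = phis, kappa = kappa, mesh = mesh),
            class = "scalar_field")
}

#' Washout-time field
#'
#' Per-node washout time `T = t_1pct - t_max`: `t_max` is the earliest time
#' of the nodal concentration maximum, `t_1pct` the first subsequent time the
#' concentration falls to `threshold_fraction` of that maximum (linearly
#' interpolated between snapshots).  Nodes whose concentration never crosses
#' the threshold before the horizon are censored (carrying the horizon);
#' nodes that never saw dye have `T = 0`, uncensored.
#'
#' @param field a `scalar_field` with at least two snapshots.
#' @param threshold_fraction decay threshold (default 0.01, i.e. 1%).
#' @param horizon censoring horizon (s); defaults to the last snapshot.
#' @return A `washout_field`: list with per-node `T`, `t_max`, `t_1pct`,
#'   `censored`, and `mesh`.
#' @export
washout_time <- function(field, threshold_fraction = 0.01, horizon = NULL) {
  if (length(field$times) < 2L)
    stop("washout_time: need at least two snapshots")
  if (is.null(horizon)) horizon <- max(field$times)
  tms <- field$times
  P <- do.call(cbind, field$phi)      # nodes x times
  n <- nrow(P)
  idx_max <- max.col(P, ties.method = "first")
  phimax <- P[cbind(seq_len(n), idx_max)]
  t_max <- tms[idx_max]
  thr <- threshold_fraction * phimax
  T_out <- numeric(n)
  t1 <- rep(NA_real_, n)
  censored <- logical(n)
  never <- phimax <= 0
  for (a in which(!never)) {
    js <- idx_max[a]
    row <- P[a, ]
    hit <- NA_real_
    if (row[js] <= thr[a]) {
      hit <- tms[js]
    } else if (js < length(tms)) {
      for (j in (js + 1L):length(tms)) {
        if (row[j] <= thr[a]) {
          f <- (row[j - 1L] - thr[a]) / (row[j - 1L] - row[j])
          hit <- tms[j - 1L] + f * (tms[j] - tms[j - 1L])
          break
        }
      }
    }
    if (is.na(hit) || hit > horizon) {
      censored[a] <- TRUE
      t1[a] <- horizon
      T_out[a] <- horizon - t_max[a]
    } else {
      t1[a] <- hit
      T_out[a] <- hit - t_max[a]
    }
  }
  t_max[never] <- 0
  structure(list(T = T_out, t_max = t_max, t_1pct = t1,
                 censored = censored, mesh = field$mesh,
                 horizon = horizon), class = "washout_field")
}

#' Mean washout time over a release region
#'
#' Volume-weighted (lumped nodal mass) mean of the washout time over the
#' uncensored nodes inside the region, with the censored fraction reported
#' alongside.
#'
#' @param wf a [washout_time] field.
#' @param region the [dye_region] used at initialization.
#' @return List with `mean_T` (s), `censored_fraction`, `n_nodes`.
#' @export
mean_washout <- function(wf, region) {
  mesh <- wf$mesh
  inside <- which(in_region(region, mesh$nodes))
  if (!length(inside)) stop("mean_washout: region contains no nodes")
  w <- lumped_mass(mesh)[inside]
  cen <- wf$censored[inside]
  cf <- sum(w[cen]) / sum(w)
  if (all(cen))
    stop(sprintf("mean_washout: all nodes censored (fraction %.2f)", cf))
  keep <- !cen
  list(mean_T = sum(w[keep] * wf$T[inside][keep]) / sum(w[keep]),
       censored_fraction = cf, n_nodes = length(inside))
}
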