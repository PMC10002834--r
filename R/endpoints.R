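#' Wall traction time series
#'
#' Evaluates the viscous-stress traction on wall faces from a flow field.
#' Velocity gradients are recovered at nodes by volume-weighted averaging of
#' element gradients (consistent for linear elements); the full stress
#' `sigma = -p I + mu (grad v + grad v^T)` is contracted with the nodal
#' outward unit normal (area-weighted over adjacent faces) and projected onto
#' the wall tangent plane, `tau = sigma.n - (sigma.n.n) n`, so the nodal
#' tangency `tau . n = 0` holds by construction.
#'
#' @param field a `flow_field`.
#' @param groups character vector of wall face-group names.
#' @param mu dynamic viscosity (Poise).
#' @return A `wall_traction_series`: list with `nodes` (wall node indices),
#'   `times`, `tau` (list per time of node x dim tangential traction,
#'   dyn/cm^2), `normal` (nodal unit normals), `node_area` (nodal area
#'   weights, cm^2).
#' @export
wall_traction <- function(field, groups, mu = 0.035) {
  mesh <- field$mesh
  d <- mesh$dim
  sel <- which(mesh$face_labels %in% groups)
  if (!length(sel))
    stop(sprintf("wall_traction: no faces in group(s) %s",
                 paste(groups, collapse = ", ")))
  fg <- face_geometry(mesh)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  wnodes <- sort(unique(as.vector(faces)))
  nw <- length(wnodes)
  node_pos <- integer(nrow(mesh$nodes))
  node_pos[wnodes] <- seq_len(nw)
  ## nodal area weights and area-weighted normals
  n_nodal <- matrix(0, nw, d)
  a_nodal <- numeric(nw)
  nfn <- ncol(faces)
  for (j in seq_len(nfn)) {
    idx <- node_pos[faces[, j]]
    w <- fg$area[sel] / nfn
    for (i in seq_len(d)) {
      t <- tapply(w * fg$normal[sel, i], idx, sum)
      at <- as.integer(names(t))
      n_nodal[at, i] <- n_nodal[at, i] + as.numeric(t)
    }
    t <- tapply(w, idx, sum)
    at <- as.integer(names(t))
    a_nodal[at] <- a_nodal[at] + as.numeric(t)
  }
  n_nodal <- n_nodal / sqrt(rowSums(n_nodal^2))

  tau_list <- vector("list", length(field$times))
  for (k in seq_along(field$times)) {
    v <- field$v[[k]]; p <- field$p[[k]]
    gv <- nodal_gradients(mesh, v)      # n x (d*d): column (c-1)*d+i = dv_c/dx_i
    tau <- matrix(0, nw, d)
    for (a in seq_len(nw)) {
      nd <- wnodes[a]
      nrm <- n_nodal[a, ]
      G <- matrix(gv[nd, ], d, d, byrow = TRUE)  # row c = grad of v_c
      sig <- -p[nd] * diag(d) + mu * (G + t(G))
      tvec <- as.vector(sig %*% nrm)
      tau[a, ] <- tvec - sum(tvec * nrm) * nrm
    }
    tau_list[[k]] <- tau
  }
  structure(list(groups = groups, nodes = wnodes, times = field$times,
                 tau = tau_list, normal = n_nodal, node_area = a_nodal),
            class = "wall_traction_series")
}

## volume-weighted recovery of element gradients to nodes
nodal_gradients <- function(mesh, field) {
  if (is.null(dim(field))) field <- matrix(field, ncol = 1L)
  eg <- element_gradients_cpp(mesh$nodes, mesh$cells, field)
  nel <- nrow(mesh$cells)
  n <- nrow(mesh$nodes)
  nc <- ncol(eg$grads)
  out <- matrix(0, n, nc)
  wt <- numeric(n)
  nen <- ncol(mesh$cells)
  for (j in seq_len(nen)) {
    idx <- mesh$cells[, j]
    t <- rowsum(eg$grads * eg$vols, idx)
    at <- as.integer(rownames(t))
    out[at, ] <- out[at, ] + t
    tw <- rowsum(eg$vols, idx)
    wt[at] <- wt[at] + as.numeric(tw)
  }
  out / wt
}

## trapezoid weights over a time window restricted to series times
window_weights <- function(times, window) {
  sel <- which(times >= window[1L] - 1e-12 & times <= window[2L] + 1e-12)
  if (!length(sel)) stop("empty averaging window")
  if (length(sel) == 1L) return(list(idx = sel, w = 1))
  t <- times[sel]
  w <- numeric(length(sel))
  dt <- diff(t)
  w[1L] <- dt[1L] / 2
  w[length(sel)] <- dt[length(dt)] / 2
  if (length(sel) > 2L)
    w[2:(length(sel) - 1L)] <- (dt[-length(dt)] + dt[-1L]) / 2
  list(idx = sel, w = w / sum(w))
}

#' Time-averaged wall shear stress
#'
#' TAWSS = | (1/T) integral of tau dt | : the magnitude of the time-averaged
#' traction vector (vector average first, then magnitude).
#'
#' @param series a [wall_traction] series.
#' @param window numeric `c(t0, t1)`; defaults to the full series.
#' @return Numeric vector of per-node TAWSS (dyn/cm^2).
#' @export
tawss <- function(series, window = range(series$times)) {
  ww <- window_weights(series$times, window)
  acc <- 0
  for (k in seq_along(ww$idx))
    acc <- acc + ww$w[k] * series$tau[[ww$idx[k]]]
  sqrt(rowSums(acc^2))
}

#' Oscillatory shear index
#'
#' OSI = 1/2 (1 - |int tau dt| / int |tau| dt), in `[0, 0.5]`; defined as 0
#' where the denominator vanishes.  Zero for steady unidirectional shear,
#' 0.5 for full reversal.
#'
#' @inheritParams tawss
#' @return Numeric vector of per-node OSI (dimensionless).
#' @export
osi <- function(series, window = range(series$times)) {
  ww <- window_weights(series$times, window)
  acc <- 0; mag <- 0
  for (k in seq_along(ww$idx)) {
    tk <- series$tau[[ww$idx[k]]]
    acc <- acc + ww$w[k] * tk
    mag <- mag + ww$w[k] * sqrt(rowSums(tk^2))
  }
  num <- sqrt(rowSums(acc^2))
  out <- ifelse(mag > 0, 0.5 * (1 - num / mag), 0)
  pmin(0.5, pmax(0, out))
}

#' Low-WSS area fraction
#'
#' Area fraction of a wall group whose TAWSS falls below a threshold
#' (5 dyn/cm^2 is the conventional low-shear cutoff for thrombosis risk).
#'
#' @param series a [wall_traction] series (defines the wall nodes).
#' @param tawss_values per-node TAWSS from [tawss].
#' @param mesh the mesh.
#' @param group face-group name to restrict to.
#' @param threshold dyn/cm^2.
#' @return Fraction in `[0, 1]`, area-weighted by face.
#' @export
low_wss_area_fraction <- function(series, tawss_values, mesh, group,
                                  threshold = 5) {
  sel <- which(mesh$face_labels == group)
  if (!length(sel)) stop(sprintf("low_wss_area_fraction: group '%s' empty", group))
  fg <- face_geometry(mesh)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  node_val <- rep(NA_real_, nrow(mesh$nodes))
  node_val[series$nodes] <- tawss_values
  fv <- 0
  for (j in seq_len(ncol(faces))) fv <- fv + node_val[faces[, j]]
  fv <- fv / ncol(faces)
  if (anyNA(fv))
    stop("low_wss_area_fraction: group extends beyond the traction series")
  sum(fg$area[sel][fv < threshold]) / sum(fg$area[sel])
}

#' Mean TAWSS over a wall group
#' @inheritParams low_wss_area_fraction
#' @return Area-weighted mean TAWSS (dyn/cm^2).
#' @export
mean_tawss <- function(series, tawss_values, mesh, group) {
  sel <- which(mesh$face_labels == group)
  if (!length(sel)) stop(sprintf("mean_tawss: group '%s' empty", group))
  fg <- face_geometry(mesh)
  faces <- mesh$boundary_faces[sel, , drop = FALSE]
  node_val <- rep(NA_real_, nrow(mesh$nodes))
  node_val[series$nodes] <- tawss_values
  fv <- 0
  for (j in seq_len(ncol(faces))) fv <- fv + node_val[faces[, j]]
  fv <- fv / ncol(faces)
  sum(fg$area[sel] * fv) / sum(fg$area[sel])
}

#' Cut plane through an arm
#'
#' @param arm one of `"RPA"`, `"LPA"`, `"SVC"`, `"IVC"` (junction
#'   convention: RPA +x, LPA -x, SVC +y, IVC -y), or `"z"` for a pipe axis.
#' @param offset distance of the plane from the origin along the arm (cm);
#'   the bench catheters sit at 4 cm.
#' @return A `cut_plane` (point + unit normal).
#' @export
cut_plane <- function(arm = c("RPA", "LPA", "SVC", "IVC", "z"), offset = 4) {
  arm <- match.arg(arm)
  axis <- switch(arm,
                 RPA = c(1, 0, 0), LPA = c(-1, 0, 0),
                 SVC = c(0, 1, 0), IVC = c(0, -1, 0),
                 z   = c(0, 0, 1))
  structure(list(arm = arm, point = axis * offset, normal = axis,
                 offset = offset), class = "cut_plane")
}

## area-weighted mean of a nodal scalar over the mesh-plane intersection
plane_mean_scalar <- function(mesh, scalar, plane) {
  d <- mesh$dim
  nrm <- plane$normal[seq_len(d)]
  nrm <- nrm / sqrt(sum(nrm^2))
  sd_ <- as.vector(mesh$nodes %*% nrm) - sum(plane$point[seq_len(d)] * nrm)
  ## nudge off node planes (zero-measure intersections)
  if (any(sd_ == 0)) sd_ <- sd_ + 1e-6 * diff(range(sd_)) / max(1, length(sd_)^(1 / d))
  cl <- mesh$cells
  smat <- matrix(sd_[cl], nrow(cl), ncol(cl))
  rmin <- do.call(pmin, lapply(seq_len(ncol(cl)), function(j) smat[, j]))
  rmax <- do.call(pmax, lapply(seq_len(ncol(cl)), function(j) smat[, j]))
  cross <- which(rmin < 0 & rmax > 0)
  if (!length(cross)) stop("cut plane does not intersect the mesh")
  tot_a <- 0; tot_pa <- 0
  edges <- utils::combn(d + 1L, 2L)
  for (e in cross) {
    vids <- cl[e, ]
    sv <- sd_[vids]
    pts <- NULL; vals <- NULL
    for (k in seq_len(ncol(edges))) {
      i <- edges[1L, k]; j <- edges[2L, k]
      if (sv[i] * sv[j] < 0) {
        t <- sv[i] / (sv[i] - sv[j])
        pts <- rbind(pts, (1 - t) * mesh$nodes[vids[i], ] +
                            t * mesh$nodes[vids[j], ])
        vals <- c(vals, (1 - t) * scalar[vids[i]] + t * scalar[vids[j]])
      }
    }
    ## include vertices exactly on the plane
    on_pl <- which(sv == 0)
    for (i in on_pl) {
      pts <- rbind(pts, mesh$nodes[vids[i], ])
      vals <- c(vals, scalar[vids[i]])
    }
    if (is.null(pts) || nrow(pts) < d) next
    if (d == 2L) {
      len <- sqrt(sum((pts[2L, ] - pts[1L, ])^2))
      tot_a <- tot_a + len
      tot_pa <- tot_pa + len * mean(vals[1:2])
    } else {
      ## order polygon vertices around their centroid within the plane
      cen <- colMeans(pts)
      ref <- pts[1L, ] - cen
      ref <- ref - sum(ref * nrm) * nrm
      b2 <- c(nrm[2L] * ref[3L] - nrm[3L] * ref[2L],
              nrm[3L] * ref[1L] - nrm[1L] * ref[3L],
              nrm[1L] * ref[2L] - nrm[2L] * ref[1L])
      ang <- atan2((pts - rep(cen, each = nrow(pts))) %*% b2,
                   (pts - rep(cen, each = nrow(pts))) %*% ref)
      ord <- order(ang)
      pts <- pts[ord, , drop = FALSE]; vals <- vals[ord]
      np <- nrow(pts)
      for (k in 2:(np - 1L)) {
        u <- pts[k, ] - pts[1L, ]; w <- pts[k + 1L, ] - pts[1L, ]
        cr <- c(u[2L] * w[3L] - u[3L] * w[2L],
                u[3L] * w[1L] - u[1L] * w[3L],
                u[1L] * w[2L] - u[2L] * w[1L])
        a <- sqrt(sum(cr^2)) / 2
        tot_a <- tot_a + a
        tot_pa <- tot_pa + a * mean(vals[c(1L, k, k + 1L)])
      }
    }
  }
  if (tot_a <= 0) stop("cut plane intersection has zero area")
  tot_pa / tot_a
}

#' Cut-plane mean pressure
#'
#' Area-weighted mean of the linearly interpolated pressure over the
#' mesh-plane intersection, time-averaged over the window, in mmHg.
#'
#' @param field a `flow_field`.
#' @param plane a [cut_plane].
#' @param window averaging window `c(t0, t1)` (defaults to full series; a
#'   steady field uses its single snapshot).
#' @return Pressure in mmHg.
#' @export
cut_plane_pressure <- function(field, plane, window = range(field$times)) {
  ww <- window_weights(field$times, window)
  acc <- 0
  for (k in seq_along(ww$idx))
    acc <- acc + ww$w[k] *
      plane_mean_scalar(field$mesh, field$p[[ww$idx[k]]], plane)
  dyn_to_mmhg(acc)
}

#' Pressure loss between two cut planes
#'
#' Mean inlet-plane pressure minus mean outlet-plane pressure (mmHg).
#'
#' @param field a `flow_field`.
#' @param inlet_plane,outlet_plane [cut_plane] objects.
#' @param window averaging window.
#' @return Pressure loss in mmHg (antisymmetric under plane swap).
#' @export
pressure_loss <- function(field, inlet_plane, outlet_plane,
                          window = range(field$times)) {
  cut_plane_pressure(field, inlet_plane, window) -
    cut_plane_pressure(field, outlet_plane, window)
}

#' All four inlet-outlet pressure losses of a junction
#'
#' @param field a `flow_field` on a junction mesh.
#' @param offset cut-plane distance from the junction center (cm).
#' @param window averaging window.
#' @return List with the four pairwise losses (mmHg) and `dP_max`.
#' @export
junction_pressure_losses <- function(field, offset = 4,
                                     window = range(field$times)) {
  pr <- vapply(c("IVC", "SVC", "RPA", "LPA"), function(a)
    cut_plane_pressure(field, cut_plane(a, offset), window), 0)
  out <- list(dP_ivc_rpa = pr[["IVC"]] - pr[["RPA"]],
              dP_ivc_lpa = pr[["IVC"]] - pr[["LPA"]],
              dP_svc_rpa = pr[["SVC"]] - pr[["RPA"]],
              dP_svc_lpa = pr[["SVC"]] - pr[["LPA"]])
  out$dP_max <- max(unlist(out))
  out
}

#' Pulmonary flow split
#'
#' Percentage of total outflow leaving through the RPA, time-averaged.
#'
#' @param field a `flow_field`.
#' @param outlets names of the two outlet groups (RPA first).
#' @param window averaging window.
#' @return Percentage in `[0, 100]`.
#' @export
flow_split <- function(field, outlets = c("outlet_RPA", "outlet_LPA"),
                       window = range(field$times)) {
  ww <- window_weights(field$times, window)
  q1 <- 0; q2 <- 0
  for (k in seq_along(ww$idx)) {
    v <- field$v[[ww$idx[k]]]
    q1 <- q1 + ww$w[k] * boundary_flux(field$mesh, v, outlets[1L])
    q2 <- q2 + ww$w[k] * boundary_flux(field$mesh, v, outlets[2L])
  }
  if (abs(q1 + q2) < 1e-12) stop("flow_split: zero total outflow")
  100 * q1 / (q1 + q2)
}

#' Hydraulic power loss
#'
#' Net rate of mechanical energy (static + dynamic pressure flux) entering
#' minus leaving through the ports,
#' `sum_ports -int (p + rho |v|^2 / 2) (v . n) dGamma`, reported in mW.
#' Positive for a dissipative flow.
#'
#' @param field a `flow_field`.
#' @param rho fluid density (g/cm^3).
#' @param window averaging window.
#' @return Power loss in mW (1 erg/s = 1e-4 mW).
#' @export
power_loss <- function(field, rho = 1.06, window = range(field$times)) {
  mesh <- field$mesh
  ports <- unique(grep("^(inlet|outlet)", mesh$face_labels, value = TRUE))
  fg <- face_geometry(mesh)
  ww <- window_weights(field$times, window)
  acc <- 0
  for (k in seq_along(ww$idx)) {
    v <- field$v[[ww$idx[k]]]; p <- field$p[[ww$idx[k]]]
    e_nodal <- p + 0.5 * rho * rowSums(v^2)
    net <- 0
    for (g in ports) {
      sel <- which(mesh$face_labels == g)
      faces <- mesh$boundary_faces[sel, , drop = FALSE]
      flux <- 0
      for (j in seq_len(ncol(faces))) {
        vn <- rowSums(v[faces[, j], , drop = FALSE] *
                      fg$normal[sel, , drop = FALSE])
        flux <- flux + e_nodal[faces[, j]] * vn
      }
      net <- net - sum(fg$area[sel] * flux / ncol(faces))
    }
    acc <- acc + ww$w[k] * net
  }
  acc * 1e-4
}
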