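#' Geometry parameters for the idealized cavopulmonary junction
#'
#' Describes a planar four-port cross junction: two perpendicular circular
#' tubes meeting at a spherically bulged housing, optionally containing a
#' static biconical pump insert (two cones base-to-base, axis normal to the
#' junction plane) with an annular blade ridge at its equator and cylindrical
#' support struts.  Coordinates: junction center at the origin, IVC along -y,
#' SVC along +y, RPA along +x, LPA along -x, insert axis along z.
#'
#' @param tube_diameter inner tube diameter (cm).
#' @param housing_max_diameter maximum housing (bulge) diameter (cm).
#' @param arm_length port distance from the junction center (cm, > 4 so the
#'   4 cm pressure cut planes fit inside the arms).
#' @param insert_kind `"none"` (blank housing control) or `"bicone"`.
#' @param bicone_height total insert height along its axis (cm).
#' @param bicone_equator_diameter insert diameter at the equator (cm).
#' @param blade_height radial protrusion of the equatorial blade ridge (cm);
#'   the tested prototypes use 0.109 and 0.162 cm.
#' @param blade_band axial half-width of the blade ridge (cm).
#' @param n_struts number of support struts (evenly spaced between the arms).
#' @param strut_diameter strut diameter (cm).
#' @param fillet_edges logical, smooth the ridge/cone junction (cosmetic at
#'   desk-scale mesh resolution; retained for parity with the prototypes).
#' @return A `junction_geometry` parameter object.
#' @export
junction_geometry <- function(tube_diameter = 1.91,
                              housing_max_diameter = 3.4,
                              arm_length = 5,
                              insert_kind = c("none", "bicone"),
                              bicone_height = 2.4,
                              bicone_equator_diameter = 2.2,
                              blade_height = 0.162,
                              blade_band = 0.25,
                              n_struts = 4L,
                              strut_diameter = 0.24,
                              fillet_edges = FALSE) {
  insert_kind <- match.arg(insert_kind)
  if (tube_diameter <= 0 || housing_max_diameter <= 0)
    stop("junction geometry stage: diameters must be positive")
  if (tube_diameter >= housing_max_diameter)
    stop("junction geometry stage: tube_diameter must be < housing_max_diameter")
  if (arm_length <= 4)
    stop("junction geometry stage: arm_length must exceed 4 cm (cut planes)")
  if (insert_kind == "bicone") {
    r_out <- bicone_equator_diameter / 2 + blade_height
    if (r_out >= housing_max_diameter / 2)
      stop("junction geometry stage: insert does not fit inside the housing")
    if (bicone_height / 2 >= housing_max_diameter / 2)
      stop("junction geometry stage: insert taller than the housing")
  }
  structure(list(tube_diameter = tube_diameter,
                 housing_max_diameter = housing_max_diameter,
                 arm_length = arm_length, insert_kind = insert_kind,
                 bicone_height = bicone_height,
                 bicone_equator_diameter = bicone_equator_diameter,
                 blade_height = blade_height, blade_band = blade_band,
                 n_struts = as.integer(n_struts),
                 strut_diameter = strut_diameter,
                 fillet_edges = fillet_edges),
            class = "junction_geometry")
}

## ---- signed distance functions (negative inside the fluid) -----------------

## p: n x d matrix. All SDFs approximate but sign-exact and Lipschitz ~ 1.
sdf_tube_x <- function(p, r) {
  if (ncol(p) == 3L) sqrt(p[, 2L]^2 + p[, 3L]^2) - r else abs(p[, 2L]) - r
}
sdf_tube_y <- function(p, r) {
  if (ncol(p) == 3L) sqrt(p[, 1L]^2 + p[, 3L]^2) - r else abs(p[, 1L]) - r
}
sdf_sphere <- function(p, R) sqrt(rowSums(p^2)) - R

## biconical insert (axis z in 3D; a disk in the 2D junction plane)
sdf_bicone <- function(p, re, hh) {
  if (ncol(p) == 2L) return(sqrt(rowSums(p^2)) - re)
  r <- sqrt(p[, 1L]^2 + p[, 2L]^2)
  ## double cone |z|/hh + r/re = 1; normalized to approximate distance
  scale <- re * hh / sqrt(re^2 + hh^2)
  (r / re + abs(p[, 3L]) / hh - 1) * scale
}

sdf_ridge <- function(p, r_ridge, band) {
  if (ncol(p) == 2L) return(sqrt(rowSums(p^2)) - r_ridge)
  r <- sqrt(p[, 1L]^2 + p[, 2L]^2)
  pmax(r - r_ridge, abs(p[, 3L]) - band)
}

sdf_struts <- function(p, params) {
  ns <- params$n_struts
  if (ns < 1L) return(rep(Inf, nrow(p)))
  rs <- params$strut_diameter / 2
  d <- rep(Inf, nrow(p))
  th0 <- pi / 4
  for (k in seq_len(ns)) {
    th <- th0 + 2 * pi * (k - 1L) / ns
    u <- c(cos(th), sin(th))
    if (ncol(p) == 3L) {
      s <- p[, 1L] * u[1L] + p[, 2L] * u[2L]     # along-axis coordinate
      perp2 <- (p[, 1L] - s * u[1L])^2 + (p[, 2L] - s * u[2L])^2 + p[, 3L]^2
      dk <- pmax(sqrt(perp2) - rs, -s)           # half-infinite outward strut
    } else {
      s <- p[, 1L] * u[1L] + p[, 2L] * u[2L]
      perp <- abs(p[, 1L] * (-u[2L]) + p[, 2L] * u[1L])
      dk <- pmax(perp - rs, -s)
    }
    d <- pmin(d, dk)
  }
  d
}

## full fluid SDF: union of tubes and bulge, minus the insert assembly
junction_sdf <- function(params) {
  rt <- params$tube_diameter / 2
  Rh <- params$housing_max_diameter / 2
  function(p) {
    p <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
    f <- pmin(sdf_tube_x(p, rt), sdf_tube_y(p, rt), sdf_sphere(p, Rh))
    if (params$insert_kind == "bicone") {
      re <- params$bicone_equator_diameter / 2
      hh <- params$bicone_height / 2
      if (ncol(p) == 2L) {
        ## 2D analog: a fitted central disk (the equatorial section would
        ## seal the planar channel); no struts
        ins <- sqrt(rowSums(p^2)) - min(re + params$blade_height, 0.75 * rt)
      } else {
        ins <- pmin(sdf_bicone(p, re, hh),
                    sdf_ridge(p, re + params$blade_height, params$blade_band),
                    sdf_struts(p, params))
      }
      f <- pmax(f, -ins)
    }
    f
  }
}

## which solid primitive is nearest (for wall labeling)
junction_wall_label <- function(p, params) {
  lab <- rep("wall_housing", nrow(p))
  if (params$insert_kind == "bicone") {
    re <- params$bicone_equator_diameter / 2
    hh <- params$bicone_height / 2
    if (ncol(p) == 2L) {
      d_rot <- sqrt(rowSums(p^2)) -
        min(re + params$blade_height, 0.75 * params$tube_diameter / 2)
      d_str <- rep(Inf, nrow(p))
    } else {
      d_rot <- pmin(sdf_bicone(p, re, hh),
                    sdf_ridge(p, re + params$blade_height, params$blade_band))
      d_str <- sdf_struts(p, params)
    }
    rt <- params$tube_diameter / 2
    Rh <- params$housing_max_diameter / 2
    d_house <- -pmin(sdf_tube_x(p, rt), sdf_tube_y(p, rt), sdf_sphere(p, Rh))
    m <- pmin(abs(d_rot), abs(d_str), abs(d_house))
    lab[abs(d_str) <= m + 1e-12] <- "wall_strut"
    lab[abs(d_rot) <= m + 1e-12] <- "wall_rotor"
  }
  lab
}

#' Tetrahedral (or triangular) mesh of the idealized junction
#'
#' Meshes the cross-junction fluid domain on a Cartesian background grid:
#' each grid cube (square in 2D) is split into Kuhn simplices, simplices with
#' centroid inside the fluid are kept, and boundary nodes are projected onto
#' the zero level set of the signed distance function along its gradient
#' (with an inverted-element safeguard that backs off the projection).
#' Port faces lie exactly on the planes `x = +/- arm_length`,
#' `y = +/- arm_length` and are labeled `outlet_RPA` / `outlet_LPA` /
#' `inlet_SVC` / `inlet_IVC`; remaining boundary faces are labeled
#' `wall_housing`, `wall_rotor` or `wall_strut` by nearest solid primitive.
#'
#' @param params a [junction_geometry] object.
#' @param target_h background grid spacing (cm).
#' @param dim 3 (tetrahedra, default) or 2 (in-plane cross-channel analog
#'   for cheap verification).
#' @param sliver_quality drop cells with volume / longest-edge^dim below
#'   this after boundary snapping (0 disables the cleanup).
#' @return An [fe_mesh].
#' @export
make_junction_mesh <- function(params, target_h, dim = 3L,
                               sliver_quality = 2e-3) {
  stopifnot(inherits(params, "junction_geometry"))
  if (target_h <= 0) stop("junction meshing stage: target_h must be positive")
  L <- params$arm_length
  sdf <- junction_sdf(params)
  nx <- 2L * max(4L, as.integer(ceiling(L / target_h)))
  hx <- 2 * L / nx
  Rh <- params$housing_max_diameter / 2
  if (dim == 3L) {
    nz2 <- max(2L, as.integer(ceiling(Rh / hx)))
    zmax <- nz2 * hx
    grid <- list(x = seq(-L, L, length.out = nx + 1L),
                 y = seq(-L, L, length.out = nx + 1L),
                 z = seq(-zmax, zmax, length.out = 2L * nz2 + 1L))
  } else {
    grid <- list(x = seq(-L, L, length.out = nx + 1L),
                 y = seq(-L, L, length.out = nx + 1L))
  }
  bg <- background_simplices(grid)
  nodes <- bg$nodes; cells <- bg$cells
  ## keep simplices whose centroid lies in the fluid, or most of whose
  ## nodes do (keeps thin features meshable at coarse h)
  cen <- centroid_of(nodes, cells)
  f_cen <- sdf(cen)
  f_node <- sdf(nodes)
  n_in <- rowSums(matrix(f_node[cells] < 0, nrow(cells), ncol(cells)))
  keep <- f_cen < 0 | n_in >= ncol(cells) - 1L
  ## port-cap coverage: at coarse h the simplices owning the cap-facet
  ## triangles can lose the centroid vote even where the tube is open;
  ## keep near-fluid cells with a full face on a port plane
  ptol <- 1e-9 * L
  on_plane <- (abs(abs(nodes[, 1L]) - L) < ptol) |
              (abs(abs(nodes[, 2L]) - L) < ptol)
  n_on <- rowSums(matrix(on_plane[cells], nrow(cells), ncol(cells)))
  keep <- keep | (n_on >= dim & f_cen < 0.5 * hx)
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0L)
    stop("junction meshing stage: no cells inside the fluid domain")
  cells <- keep_largest_component(nodes, cells, dim)
  cm <- compact_mesh_arrays(nodes, cells)
  nodes <- cm$nodes; cells <- cm$cells
  cells <- orient_cells(nodes, cells, dim)
  ## snap boundary nodes to the surface
  bf <- boundary_faces_of(cells, dim)
  bnodes <- sort(unique(as.vector(bf)))
  port_tol <- 1e-9 * L
  on_port <- abs(abs(nodes[bnodes, 1L]) - L) < port_tol |
             abs(abs(nodes[bnodes, 2L]) - L) < port_tol
  nodes <- snap_to_surface(nodes, bnodes, sdf, hx,
                           freeze_axis = ifelse(on_port,
                             ifelse(abs(abs(nodes[bnodes, 1L]) - L) < port_tol,
                                    1L, 2L), 0L))
  freeze <- matrix(FALSE, nrow(nodes), dim)
  for (j in 1:2) freeze[abs(abs(nodes[, j]) - L) < port_tol, j] <- TRUE
  nodes <- untangle_snap(nodes, cells, dim, bnodes, freeze = freeze)
  ## drop extreme slivers left by snapping (they defeat the element-level
  ## stabilization); the boundary is re-extracted afterwards
  vol <- abs(fe_mesh_measures(nodes, cells, dim))
  lmax2 <- 0
  for (j in seq_len(dim)) for (k in (j + 1L):(dim + 1L)) {
    e2 <- rowSums((nodes[cells[, j], , drop = FALSE] -
                   nodes[cells[, k], , drop = FALSE])^2)
    lmax2 <- pmax(lmax2, e2)
  }
  qual <- vol / lmax2^(dim / 2)
  good <- qual > sliver_quality
  if (!all(good)) {
    cells <- cells[good, , drop = FALSE]
    cells <- keep_largest_component(nodes, cells, dim)
    cm <- compact_mesh_arrays(nodes, cells)
    nodes <- cm$nodes; cells <- cm$cells
    bf <- boundary_faces_of(cells, dim)
  }
  ## labels
  fc <- centroid_of(nodes, bf)
  labels <- rep(NA_character_, nrow(bf))
  all_on <- function(j, val) {
    m <- matrix(abs(nodes[as.vector(bf), j] - val) < 10 * port_tol,
                nrow(bf), ncol(bf))
    rowSums(m) == ncol(bf)
  }
  labels[all_on(1L, L)] <- "outlet_RPA"
  labels[all_on(1L, -L)] <- "outlet_LPA"
  labels[all_on(2L, L)] <- "inlet_SVC"
  labels[all_on(2L, -L)] <- "inlet_IVC"
  wall <- is.na(labels)
  labels[wall] <- junction_wall_label(fc[wall, , drop = FALSE], params)
  fe_mesh(nodes, cells, bf, labels)
}

centroid_of <- function(nodes, simp) {
  d <- ncol(nodes)
  out <- matrix(0, nrow(simp), d)
  for (j in seq_len(ncol(simp)))
    out <- out + nodes[simp[, j], , drop = FALSE]
  out / ncol(simp)
}

## Kuhn subdivision of a structured grid into simplices (6 tets per cube,
## 2 triangles per square); identical in every cell, hence face-conforming.
background_simplices <- function(grid) {
  d <- length(grid)
  dims <- vapply(grid, length, integer(1L))
  if (d == 2L) {
    nodes <- cbind(rep(grid$x, times = dims[2L]),
                   rep(grid$y, each = dims[1L]))
    idx <- function(i, j) (j - 1L) * dims[1L] + i
    i <- rep(seq_len(dims[1L] - 1L), times = dims[2L] - 1L)
    j <- rep(seq_len(dims[2L] - 1L), each = dims[1L] - 1L)
    v00 <- idx(i, j); v10 <- idx(i + 1L, j)
    v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
    cells <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
    return(list(nodes = nodes, cells = cells))
  }
  nodes <- cbind(rep(grid$x, times = dims[2L] * dims[3L]),
                 rep(rep(grid$y, each = dims[1L]), times = dims[3L]),
                 rep(grid$z, each = dims[1L] * dims[2L]))
  idx <- function(i, j, k) ((k - 1L) * dims[2L] + (j - 1L)) * dims[1L] + i
  i <- rep(seq_len(dims[1L] - 1L), times = (dims[2L] - 1L) * (dims[3L] - 1L))
  j <- rep(rep(seq_len(dims[2L] - 1L), each = dims[1L] - 1L),
           times = dims[3L] - 1L)
  k <- rep(seq_len(dims[3L] - 1L), each = (dims[1L] - 1L) * (dims[2L] - 1L))
  c000 <- idx(i, j, k);        c100 <- idx(i + 1L, j, k)
  c010 <- idx(i, j + 1L, k);   c110 <- idx(i + 1L, j + 1L, k)
  c001 <- idx(i, j, k + 1L);   c101 <- idx(i + 1L, j, k + 1L)
  c011 <- idx(i, j + 1L, k + 1L); c111 <- idx(i + 1L, j + 1L, k + 1L)
  ## Kuhn: path simplices along the 6 permutations of (x,y,z)
  cells <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111))
  list(nodes = nodes, cells = cells)
}

## Project selected nodes onto the SDF zero level set along the numerical
## gradient; freeze_axis = 1 or 2 keeps that coordinate fixed (port planes).
snap_to_surface <- function(nodes, bnodes, sdf, h, freeze_axis) {
  d <- ncol(nodes)
  p <- nodes[bnodes, , drop = FALSE]
  f0 <- sdf(p)
  eps <- 1e-4 * h
  g <- matrix(0, nrow(p), d)
  for (j in seq_len(d)) {
    pp <- p; pp[, j] <- pp[, j] + eps
    pm <- p; pm[, j] <- pm[, j] - eps
    g[, j] <- (sdf(pp) - sdf(pm)) / (2 * eps)
  }
  for (j in seq_len(d))
    if (j <= 2L) g[freeze_axis == j, j] <- 0
  gn <- sqrt(rowSums(g^2))
  ok <- gn > 1e-8 & abs(f0) < 0.95 * h
  g[ok, ] <- g[ok, , drop = FALSE] / gn[ok]
  ## secant root find along -sign(f) * g capped at 0.95 h
  t <- ifelse(ok, -f0, 0)
  for (iter in 1:4) {
    pt <- p + g * t
    ft <- sdf(pt)
    slope <- rep(1, length(ft))
    t_new <- t - ft * slope
    t <- ifelse(ok, pmax(-0.95 * h, pmin(0.95 * h, t_new)), t)
  }
  p2 <- p + g * t
  moved <- ok & abs(sdf(p2)) < abs(f0)
  p[moved, ] <- p2[moved, , drop = FALSE]
  nodes[bnodes, ] <- p
  nodes
}

## Back off snapped nodes that inverted or degenerated incident cells by
## pulling them toward the centroid of their cell neighborhood.
untangle_snap <- function(nodes, cells, dim, bnodes, max_rounds = 8L,
                          freeze = NULL) {
  node_cells <- NULL
  for (round in seq_len(max_rounds)) {
    vol <- fe_mesh_measures(nodes, cells, dim)
    bad <- vol <= 1e-12
    if (!any(bad)) break
    if (is.null(node_cells))
      node_cells <- split(rep(seq_len(nrow(cells)), ncol(cells)),
                          as.vector(cells))
    bad_nodes <- intersect(unique(as.vector(cells[bad, , drop = FALSE])),
                           bnodes)
    for (nd in bad_nodes) {
      inc <- node_cells[[as.character(nd)]]
      nb <- setdiff(unique(as.vector(cells[inc, , drop = FALSE])), nd)
      new_pos <- 0.5 * nodes[nd, ] + 0.5 * colMeans(nodes[nb, , drop = FALSE])
      if (!is.null(freeze)) {
        fz <- freeze[nd, ]
        new_pos[fz] <- nodes[nd, fz]
      }
      nodes[nd, ] <- new_pos
    }
  }
  nodes
}

#' Uniformly refine a junction mesh, keeping the geometry nested
#'
#' Splits every simplex into 2^dim children through edge midpoints (the
#' octahedral core of each tetrahedron is split along its shortest
#' diagonal), replicates boundary-face labels onto the four child faces,
#' and projects the new boundary midpoints onto the junction surface
#' (port-plane coordinates frozen).  Because parent topology and labels are
#' inherited, a refinement sequence represents one converging geometry --
#' the construction used for the mesh-sensitivity study.
#'
#' @param mesh an [fe_mesh] produced by [make_junction_mesh].
#' @param params the [junction_geometry] the mesh discretizes.
#' @return An [fe_mesh] with attribute `parent_edges` (matrix: for each new
#'   node, its two parent node indices; used for solution prolongation).
#' @export
refine_junction_mesh <- function(mesh, params) {
  d <- mesh$dim
  nd <- mesh$nodes
  cl <- mesh$cells
  n0 <- nrow(nd)
  ## unique edges over all cells
  pairs <- utils::combn(d + 1L, 2L)
  eall <- NULL
  for (k in seq_len(ncol(pairs)))
    eall <- rbind(eall, cl[, pairs[, k]])
  ekey <- pmin(eall[, 1L], eall[, 2L]) * (n0 + 1) + pmax(eall[, 1L], eall[, 2L])
  ue <- !duplicated(ekey)
  edges <- eall[ue, , drop = FALSE]
  mid_id <- integer(max(ekey))
  mid_id[ekey[ue]] <- n0 + seq_len(sum(ue))
  mids <- (nd[edges[, 1L], , drop = FALSE] + nd[edges[, 2L], , drop = FALSE]) / 2
  nodes <- rbind(nd, mids)
  m_of <- function(a, b) mid_id[pmin(a, b) * (n0 + 1) + pmax(a, b)]
  if (d == 2L) {
    a <- cl[, 1L]; b <- cl[, 2L]; c_ <- cl[, 3L]
    mab <- m_of(a, b); mbc <- m_of(b, c_); mca <- m_of(c_, a)
    cells <- rbind(cbind(a, mab, mca), cbind(b, mbc, mab),
                   cbind(c_, mca, mbc), cbind(mab, mbc, mca))
  } else {
    v1 <- cl[, 1L]; v2 <- cl[, 2L]; v3 <- cl[, 3L]; v4 <- cl[, 4L]
    m12 <- m_of(v1, v2); m13 <- m_of(v1, v3); m14 <- m_of(v1, v4)
    m23 <- m_of(v2, v3); m24 <- m_of(v2, v4); m34 <- m_of(v3, v4)
    corner <- rbind(cbind(v1, m12, m13, m14), cbind(v2, m12, m23, m24),
                    cbind(v3, m13, m23, m34), cbind(v4, m14, m24, m34))
    ## octahedron: split along the shortest of the three diagonals
    dlen <- function(i, j) rowSums((nodes[i, , drop = FALSE] -
                                    nodes[j, , drop = FALSE])^2)
    d1 <- dlen(m13, m24); d2 <- dlen(m12, m34); d3 <- dlen(m14, m23)
    choice <- max.col(-cbind(d1, d2, d3), ties.method = "first")
    oct <- matrix(0L, 4L * nrow(cl), 4L)
    for (ch in 1:3) {
      sel <- which(choice == ch)
      if (!length(sel)) next
      if (ch == 1L) { dg <- cbind(m13, m24); cyc <- cbind(m12, m14, m34, m23) }
      if (ch == 2L) { dg <- cbind(m12, m34); cyc <- cbind(m13, m14, m24, m23) }
      if (ch == 3L) { dg <- cbind(m14, m23); cyc <- cbind(m12, m13, m34, m24) }
      for (k in 1:4) {
        k2 <- (k %% 4L) + 1L
        rows <- 4L * (sel - 1L) + k
        oct[rows, ] <- cbind(dg[sel, 1L], dg[sel, 2L],
                             cyc[sel, k], cyc[sel, k2])
      }
    }
    cells <- rbind(corner, oct)
  }
  ## children of boundary faces inherit the parent label
  bf <- mesh$boundary_faces
  if (d == 2L) {
    mab <- m_of(bf[, 1L], bf[, 2L])
    bfaces <- rbind(cbind(bf[, 1L], mab), cbind(mab, bf[, 2L]))
    labels <- rep(mesh$face_labels, 2L)
  } else {
    m12 <- m_of(bf[, 1L], bf[, 2L]); m23 <- m_of(bf[, 2L], bf[, 3L])
    m13 <- m_of(bf[, 1L], bf[, 3L])
    bfaces <- rbind(cbind(bf[, 1L], m12, m13), cbind(bf[, 2L], m23, m12),
                    cbind(bf[, 3L], m13, m23), cbind(m12, m23, m13))
    labels <- rep(mesh$face_labels, 4L)
  }
  ## snap new boundary midpoints onto the surface (walls only; port-plane
  ## coordinates are frozen so ports stay planar)
  L <- params$arm_length
  sdf <- junction_sdf(params)
  bnew <- sort(unique(as.vector(bfaces)))
  bnew <- bnew[bnew > n0]
  port_tol <- 1e-9 * L
  on_port <- abs(abs(nodes[bnew, 1L]) - L) < port_tol |
             abs(abs(nodes[bnew, 2L]) - L) < port_tol
  hx <- sqrt(stats::median(rowSums((nodes[edges[, 1L], , drop = FALSE] -
                                    nodes[edges[, 2L], , drop = FALSE])^2)))
  ## orient on the pure midpoint split (always valid for a valid parent),
  ## THEN snap; inverted children roll their midpoints back
  cells <- orient_cells(nodes, cells, d)
  nodes <- snap_to_surface(nodes, bnew, sdf, 0.5 * hx,
                           freeze_axis = ifelse(on_port,
                             ifelse(abs(abs(nodes[bnew, 1L]) - L) < port_tol,
                                    1L, 2L), 0L))
  for (round in 1:20) {
    vol <- fe_mesh_measures(nodes, cells, d)
    bad <- which(vol <= 1e-12)
    if (!length(bad)) break
    bn_bad <- unique(as.vector(cells[bad, , drop = FALSE]))
    bn_bad <- bn_bad[bn_bad > n0]
    if (!length(bn_bad)) break
    nodes[bn_bad, ] <- mids[bn_bad - n0, , drop = FALSE]
  }
  out <- fe_mesh(nodes, cells, bfaces, labels)
  attr(out, "parent_edges") <- cbind(c(seq_len(n0), edges[, 1L]),
                                     c(seq_len(n0), edges[, 2L]))
  out
}

#' Prolong a nodal solution onto a refined mesh
#'
#' Exact linear interpolation: new midpoint nodes average their parent edge
#' endpoints.
#'
#' @param refined output of [refine_junction_mesh].
#' @param v,p nodal state on the parent mesh.
#' @return List with `v`, `p` on the refined mesh.
#' @export
prolong_nodal_state <- function(refined, v, p) {
  pe <- attr(refined, "parent_edges")
  if (is.null(pe)) stop("prolong_nodal_state: mesh has no parent records")
  list(v = (v[pe[, 1L], , drop = FALSE] + v[pe[, 2L], , drop = FALSE]) / 2,
       p = (p[pe[, 1L]] + p[pe[, 2L]]) / 2)
}
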