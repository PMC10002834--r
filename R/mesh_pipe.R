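#' Structured tetrahedral mesh of a straight circular pipe
#'
#' Builds a cylinder of given diameter and length from a "spiderweb" disk
#' triangulation extruded along the axis (+z), with optional graded boundary
#' layers at the wall: with `n_boundary_layers = n` and thinning ratio `q`,
#' the radial spacing of the k-th layer counted from the interior is
#' `q^k * target_h`, the thinnest layer sitting at the wall.  Prisms are
#' split into tetrahedra with face-compatible diagonals (smallest-global-index
#' rule), so the mesh is conforming and watertight.
#'
#' Face groups: `inlet` (z = 0), `outlet` (z = length), `wall`.
#'
#' @param diameter inner diameter (cm).
#' @param length pipe length (cm).
#' @param target_h isotropic target element size (cm).
#' @param n_boundary_layers number of graded wall layers (default 0).
#' @param bl_ratio per-layer thinning ratio (default 0.5).
#' @return An [fe_mesh] with groups `inlet`, `outlet`, `wall`.
#' @export
make_pipe_mesh <- function(diameter, length, target_h,
                           n_boundary_layers = 0L, bl_ratio = 0.5) {
  if (diameter <= 0 || length <= 0 || target_h <= 0)
    stop("pipe geometry stage: diameter, length and target_h must be positive")
  R <- diameter / 2
  disk <- disk_triangulation(R, target_h, n_boundary_layers, bl_ratio)
  nz <- max(2L, as.integer(ceiling(length / target_h)))
  zs <- seq(0, length, length.out = nz + 1L)
  ex <- extrude_triangulation(disk$nodes, disk$tris, zs)
  nodes <- ex$nodes; cells <- ex$cells
  cells <- orient_cells(nodes, cells, 3L)
  bf <- boundary_faces_of(cells, 3L)
  cz <- (nodes[bf[, 1L], 3L] + nodes[bf[, 2L], 3L] + nodes[bf[, 3L], 3L]) / 3
  tol <- 1e-9 * max(1, length)
  labels <- ifelse(cz < tol, "inlet",
                   ifelse(cz > length - tol, "outlet", "wall"))
  fe_mesh(nodes, cells, bf, labels)
}

## Concentric-ring triangulation of a disk of radius R.
disk_triangulation <- function(R, h, n_layers = 0L, q = 0.5) {
  bl <- if (n_layers > 0L) h * q^seq_len(n_layers) else numeric(0)
  t_bl <- sum(bl)
  if (t_bl >= 0.8 * R)
    stop("pipe geometry stage: boundary layers thicker than the radius")
  core <- R - t_bl
  n_core <- max(2L, as.integer(round(core / h)))
  radii <- seq(0, core, length.out = n_core + 1L)[-1L]
  if (n_layers > 0L) radii <- c(radii, core + cumsum(bl))
  m_outer <- max(8L, as.integer(round(2 * pi * core / h)))
  ring_m <- integer(length(radii))
  for (k in seq_along(radii)) {
    ring_m[k] <- if (radii[k] < core - 1e-12)
      max(6L, as.integer(round(2 * pi * radii[k] / h))) else m_outer
  }
  nodes <- matrix(0, 1L, 2L)  # center
  ring_idx <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    m <- ring_m[k]
    th <- 2 * pi * (seq_len(m) - 1L) / m
    ring_idx[[k]] <- nrow(nodes) + seq_len(m)
    nodes <- rbind(nodes, cbind(radii[k] * cos(th), radii[k] * sin(th)))
  }
  tris <- NULL
  ## center fan
  r1 <- ring_idx[[1L]]
  m1 <- length(r1)
  tris <- cbind(rep(1L, m1), r1, r1[c(2:m1, 1L)])
  for (k in seq_len(length(radii) - 1L)) {
    tris <- rbind(tris, annulus_strip(nodes, ring_idx[[k]], ring_idx[[k + 1L]]))
  }
  ## orient CCW
  a <- nodes[tris[, 1L], , drop = FALSE]
  u <- nodes[tris[, 2L], , drop = FALSE] - a
  v <- nodes[tris[, 3L], , drop = FALSE] - a
  cwsel <- (u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]) < 0
  if (any(cwsel)) tris[cwsel, 2:3] <- tris[cwsel, c(3L, 2L)]
  list(nodes = nodes, tris = tris, outer_ring = ring_idx[[length(radii)]])
}

## Triangulate annulus between an inner and an outer closed ring of nodes
## (each ordered by angle) by a greedy two-pointer walk.
annulus_strip <- function(nodes, inner, outer) {
  ang <- function(idx) atan2(nodes[idx, 2L], nodes[idx, 1L])
  ai <- ang(inner); ao <- ang(outer)
  ni <- length(inner); no <- length(outer)
  i <- 1L; j <- which.min((ao - ai[1L]) %% (2 * pi))
  tris <- matrix(0L, ni + no, 3L)
  cnt <- 0L; si <- 0L; so <- 0L
  unwrap <- function(a, ref) ref + ((a - ref + pi) %% (2 * pi)) - pi
  cur_ai <- ai[i]; cur_ao <- unwrap(ao[j], cur_ai)
  while (si < ni || so < no) {
    next_i <- inner[(i %% ni) + 1L]
    next_o <- outer[(j %% no) + 1L]
    a_next_i <- cur_ai + ((ang(next_i) - cur_ai) %% (2 * pi))
    a_next_o <- cur_ao + ((ang(next_o) - cur_ao) %% (2 * pi))
    advance_inner <- if (si >= ni) FALSE else if (so >= no) TRUE else
      a_next_i <= a_next_o
    cnt <- cnt + 1L
    if (advance_inner) {
      tris[cnt, ] <- c(inner[i], next_i, outer[j])
      i <- (i %% ni) + 1L; si <- si + 1L; cur_ai <- a_next_i
    } else {
      tris[cnt, ] <- c(inner[i], next_o, outer[j])
      j <- (j %% no) + 1L; so <- so + 1L; cur_ao <- a_next_o
    }
  }
  tris[seq_len(cnt), , drop = FALSE]
}

## Extrude a 2D triangulation along z through the given level coordinates,
## splitting each prism into 3 tetrahedra with face-compatible diagonals.
extrude_triangulation <- function(nodes2d, tris, zs) {
  np <- nrow(nodes2d); nl <- length(zs)
  nodes <- cbind(nodes2d[rep(seq_len(np), nl), , drop = FALSE],
                 rep(zs, each = np))
  cells <- vector("list", nl - 1L)
  for (lev in seq_len(nl - 1L)) {
    off_b <- (lev - 1L) * np; off_t <- lev * np
    b <- tris + off_b; t <- tris + off_t
    cells[[lev]] <- split_prisms(b, t)
  }
  list(nodes = nodes, cells = do.call(rbind, cells))
}

## Split prisms (b0,b1,b2 | t0,t1,t2) into 3 tets each.  Quad-face diagonals
## go through the smallest global index of the quad, which is consistent
## between neighboring prisms and never produces the cyclic (untetrahedrizable)
## pattern.
split_prisms <- function(b, t) {
  n <- nrow(b)
  ## diagonal on quad between columns (i,j): TRUE if (b_i, t_j), else (b_j, t_i)
  diag_asc <- function(bi, bj, ti, tj) {
    m <- pmin(bi, pmin(bj, pmin(ti, tj)))
    (m == bi) | (m == tj)
  }
  d01 <- diag_asc(b[, 1L], b[, 2L], t[, 1L], t[, 2L])
  d12 <- diag_asc(b[, 2L], b[, 3L], t[, 2L], t[, 3L])
  d20 <- diag_asc(b[, 3L], b[, 1L], t[, 3L], t[, 1L])
  tets <- matrix(0L, 3L * n, 4L)
  for (k in seq_len(n)) {
    bb <- b[k, ]; tt <- t[k, ]
    dd <- c(d01[k], d12[k], d20[k])
    ## rotate columns so that the prism's min-vertex column is column 1
    perm_list <- list(1:3, c(2L, 3L, 1L), c(3L, 1L, 2L))
    vmin <- which.min(c(bb, tt))
    col0 <- ((vmin - 1L) %% 3L) + 1L
    p <- perm_list[[col0]]
    bb2 <- bb[p]; tt2 <- tt[p]
    ## diagonal flags in rotated frame: quad (1,2), (2,3), (3,1)
    dd2 <- dd[((col0 - 1L + 0:2) %% 3L) + 1L]
    on_bottom <- vmin <= 3L
    if (on_bottom) {
      ## diagonals (b1,t2) on quad12(rot: quad(1,2)) and (b1,t3) on quad(3,1)
      if (dd2[2L]) { # quad(2,3): (b2,t3)
        tet1 <- c(bb2[1L], bb2[2L], bb2[3L], tt2[3L])
        tet2 <- c(bb2[1L], bb2[2L], tt2[3L], tt2[2L])
        tet3 <- c(bb2[1L], tt2[2L], tt2[3L], tt2[1L])
      } else {       # quad(2,3): (b3,t2)
        tet1 <- c(bb2[1L], bb2[2L], bb2[3L], tt2[2L])
        tet2 <- c(bb2[1L], bb2[3L], tt2[3L], tt2[2L])
        tet3 <- c(bb2[1L], tt2[2L], tt2[3L], tt2[1L])
      }
    } else {
      ## min vertex on top: diagonals (b2,t1), (b3,t1)
      if (dd2[2L]) { # quad(2,3): (b2,t3)
        tet1 <- c(tt2[1L], tt2[3L], tt2[2L], bb2[2L])
        tet2 <- c(tt2[1L], tt2[3L], bb2[2L], bb2[3L])
        tet3 <- c(tt2[1L], bb2[2L], bb2[3L], bb2[1L])
      } else {       # quad(2,3): (b3,t2)
        tet1 <- c(tt2[1L], tt2[3L], tt2[2L], bb2[3L])
        tet2 <- c(tt2[1L], tt2[2L], bb2[2L], bb2[3L])
        tet3 <- c(tt2[1L], bb2[2L], bb2[3L], bb2[1L])
      }
    }
    tets[3L * (k - 1L) + 1:3, ] <- rbind(tet1, tet2, tet3)
  }
  tets
}

#' Structured triangular mesh of a 2D channel
#'
#' Rectangle `[0, length] x [0, width]` with groups `inlet` (x = 0),
#' `outlet` (x = length) and `wall` (the two long sides); the cheap planar
#' verification fixture for solver and transport oracles.
#'
#' @param length,width channel dimensions (cm).
#' @param target_h element size (cm).
#' @return An [fe_mesh] (dim = 2).
#' @export
make_channel_mesh <- function(length, width, target_h) {
  if (length <= 0 || width <= 0 || target_h <= 0)
    stop("channel geometry stage: dimensions must be positive")
  nx <- max(2L, as.integer(ceiling(length / target_h)))
  ny <- max(2L, as.integer(ceiling(width / target_h)))
  bg <- background_simplices(list(x = seq(0, length, length.out = nx + 1L),
                                  y = seq(0, width, length.out = ny + 1L)))
  cells <- orient_cells(bg$nodes, bg$cells, 2L)
  bf <- boundary_faces_of(cells, 2L)
  cx <- (bg$nodes[bf[, 1L], 1L] + bg$nodes[bf[, 2L], 1L]) / 2
  tol <- 1e-9 * length
  labels <- ifelse(cx < tol, "inlet",
                   ifelse(cx > length - tol, "outlet", "wall"))
  fe_mesh(bg$nodes, cells, bf, labels)
}
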