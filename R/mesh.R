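#' Labeled simplicial mesh
#'
#' Container for a linear simplicial mesh (triangles in 2D, tetrahedra in 3D)
#' with a labeled boundary, the common currency of the whole pipeline.
#' Coordinates are in cm (CGS units throughout the package).
#'
#' @param nodes numeric matrix, one row per node (`dim` columns, cm).
#' @param cells integer matrix, one row per simplex (`dim + 1` columns,
#'   1-based node indices, positively oriented).
#' @param boundary_faces integer matrix, one row per boundary face
#'   (`dim` columns), oriented so normals point out of the domain.
#' @param face_labels character vector, one group name per boundary face
#'   (e.g. `"inlet_IVC"`, `"outlet_RPA"`, `"wall_housing"`).
#'
#' @return An object of class `fe_mesh` with elements `nodes`, `cells`,
#'   `boundary_faces`, `face_labels` and `dim`.
#' @export
fe_mesh <- function(nodes, cells, boundary_faces, face_labels) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  boundary_faces <- as.matrix(boundary_faces)
  storage.mode(boundary_faces) <- "integer"
  d <- ncol(nodes)
  stopifnot(d %in% c(2L, 3L), ncol(cells) == d + 1L,
            ncol(boundary_faces) == d,
            length(face_labels) == nrow(boundary_faces))
  structure(list(nodes = nodes, cells = cells,
                 boundary_faces = boundary_faces,
                 face_labels = as.character(face_labels), dim = d),
            class = "fe_mesh")
}

#' @export
#' @method print fe_mesh
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %dD, %d nodes, %d cells, %d boundary faces\n",
              x$dim, nrow(x$nodes), nrow(x$cells), nrow(x$boundary_faces)))
  tab <- table(x$face_labels)
  for (g in names(tab)) cat(sprintf("  %-16s %5d faces\n", g, tab[[g]]))
  invisible(x)
}

#' Signed cell measures (area in 2D, volume in 3D)
#'
#' @param mesh an `fe_mesh`.
#' @return Numeric vector of signed measures, positive for well-oriented cells.
#' @export
cell_volumes <- function(mesh) {
  nd <- mesh$nodes; cl <- mesh$cells
  if (mesh$dim == 2L) {
    a <- nd[cl[, 1L], , drop = FALSE]
    u <- nd[cl[, 2L], , drop = FALSE] - a
    v <- nd[cl[, 3L], , drop = FALSE] - a
    (u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]) / 2
  } else {
    a <- nd[cl[, 1L], , drop = FALSE]
    u <- nd[cl[, 2L], , drop = FALSE] - a
    v <- nd[cl[, 3L], , drop = FALSE] - a
    w <- nd[cl[, 4L], , drop = FALSE] - a
    (u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
     u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
     u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])) / 6
  }
}

#' Boundary face areas (lengths in 2D) and outward unit normals
#'
#' @param mesh an `fe_mesh`.
#' @return List with `area` (numeric vector) and `normal` (matrix, one row per
#'   boundary face; unit length, outward by face orientation).
#' @export
face_geometry <- function(mesh) {
  nd <- mesh$nodes; bf <- mesh$boundary_faces
  if (mesh$dim == 2L) {
    e <- nd[bf[, 2L], , drop = FALSE] - nd[bf[, 1L], , drop = FALSE]
    len <- sqrt(rowSums(e^2))
    n <- cbind(e[, 2L], -e[, 1L]) / len
    list(area = len, normal = n)
  } else {
    a <- nd[bf[, 1L], , drop = FALSE]
    u <- nd[bf[, 2L], , drop = FALSE] - a
    v <- nd[bf[, 3L], , drop = FALSE] - a
    cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    nr <- sqrt(rowSums(cr^2))
    list(area = nr / 2, normal = cr / nr)
  }
}

## All faces of all cells, ordered so the induced normal points out of the
## cell (positively oriented parent assumed).
cell_faces <- function(cells, dim) {
  if (dim == 2L) {
    rbind(cells[, c(1L, 2L)], cells[, c(2L, 3L)], cells[, c(3L, 1L)])
  } else {
    rbind(cells[, c(1L, 3L, 2L)], cells[, c(1L, 2L, 4L)],
          cells[, c(1L, 4L, 3L)], cells[, c(2L, 3L, 4L)])
  }
}

## order-invariant numeric key per face (node counts < 2^17 keep the 3-node
## key exact in doubles)
face_key <- function(faces) {
  K <- max(faces) + 1
  if (ncol(faces) == 2L) {
    pmin(faces[, 1L], faces[, 2L]) * K + pmax(faces[, 1L], faces[, 2L])
  } else {
    a <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
    c_ <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
    b <- as.numeric(faces[, 1L]) + faces[, 2L] + faces[, 3L] - a - c_
    (a * K + b) * K + c_
  }
}

#' Extract the oriented boundary of a cell set
#'
#' Faces belonging to exactly one cell, ordered with outward normals
#' (cells must be positively oriented).
#'
#' @param cells integer simplex connectivity matrix.
#' @param dim spatial dimension (2 or 3).
#' @return Integer matrix of boundary faces.
#' @export
boundary_faces_of <- function(cells, dim) {
  f <- cell_faces(cells, dim)
  key <- face_key(f)
  ord <- order(key)
  ks <- key[ord]
  n <- length(ks)
  dup <- c(FALSE, ks[-1L] == ks[-n]) | c(ks[-1L] == ks[-n], FALSE)
  if (anyDuplicated(ks[c(FALSE, ks[-1L] == ks[-n])]))
    stop("non-manifold face detected while extracting the boundary")
  f[ord[!dup], , drop = FALSE]
}

## Flip negative cells into positive orientation (faces as sets unchanged).
orient_cells <- function(nodes, cells, dim) {
  m <- fe_mesh_measures(nodes, cells, dim)
  neg <- m < 0
  if (any(neg)) {
    tmp <- cells[neg, dim, drop = FALSE]
    cells[neg, dim] <- cells[neg, dim + 1L]
    cells[neg, dim + 1L] <- tmp
  }
  cells
}

fe_mesh_measures <- function(nodes, cells, dim) {
  cell_volumes(list(nodes = nodes, cells = cells, dim = dim))
}

#' Audit mesh validity
#'
#' Checks strict positivity of cell measures, watertightness of the boundary
#' (every cell face shared by exactly two cells or labeled as boundary), label
#' completeness, and the closedness of the boundary surface.
#'
#' @param mesh an `fe_mesh`.
#' @return Invisibly, a list of audit quantities (`min_volume`,
#'   `n_unmatched_faces`, `euler_characteristic`, `ok`). Throws on failure if
#'   `strict = TRUE`.
#' @param strict logical; error on failed audit.
#' @export
audit_mesh <- function(mesh, strict = TRUE) {
  vol <- cell_volumes(mesh)
  f <- cell_faces(mesh$cells, mesh$dim)
  key <- sort(face_key(f))
  n <- length(key)
  dup <- c(FALSE, key[-1L] == key[-n]) | c(key[-1L] == key[-n], FALSE)
  once <- key[!dup]
  bkey <- face_key(mesh$boundary_faces)
  unmatched <- sum(!once %in% bkey) + sum(!bkey %in% once)
  dup_labels <- anyDuplicated(bkey) > 0L
  ## Euler characteristic of the boundary surface (3D: V - E + F)
  chi <- NA_real_
  if (mesh$dim == 3L && nrow(mesh$boundary_faces) > 0L) {
    bf <- mesh$boundary_faces
    vb <- length(unique(as.vector(bf)))
    ed <- rbind(bf[, 1:2], bf[, 2:3], bf[, c(3L, 1L)])
    ek <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    eb <- length(unique(ek))
    chi <- vb - eb + nrow(bf)
  }
  ok <- min(vol) > 0 && unmatched == 0L && !dup_labels
  if (strict && !ok)
    stop(sprintf(paste0("mesh audit failed: min volume %.3g, ",
                        "%d unmatched boundary faces, duplicated labels: %s"),
                 min(vol), unmatched, dup_labels))
  invisible(list(min_volume = min(vol), n_unmatched_faces = unmatched,
                 euler_characteristic = chi, ok = ok))
}

#' Mesh quality statistics
#'
#' Aspect ratio (circumradius-based in 2D; longest edge over smallest height
#' in 3D) and minimum dihedral angle, as reported in run manifests.
#'
#' @param mesh an `fe_mesh`.
#' @return List with `mean_aspect_ratio`, `min_dihedral_deg` (3D; NA in 2D).
#' @export
mesh_quality <- function(mesh) {
  nd <- mesh$nodes; cl <- mesh$cells
  vol <- abs(cell_volumes(mesh))
  if (mesh$dim == 2L) {
    e1 <- sqrt(rowSums((nd[cl[, 2L], ] - nd[cl[, 1L], ])^2))
    e2 <- sqrt(rowSums((nd[cl[, 3L], ] - nd[cl[, 2L], ])^2))
    e3 <- sqrt(rowSums((nd[cl[, 1L], ] - nd[cl[, 3L], ])^2))
    lmax <- pmax(e1, e2, e3)
    hmin <- 2 * vol / lmax
    return(list(mean_aspect_ratio = mean(lmax / hmin),
                min_dihedral_deg = NA_real_))
  }
  pairs <- utils::combn(4L, 2L)
  elen <- matrix(0, nrow(cl), 6L)
  for (k in seq_len(6L)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    elen[, k] <- sqrt(rowSums((nd[cl[, j], , drop = FALSE] -
                               nd[cl[, i], , drop = FALSE])^2))
  }
  lmax <- apply(elen, 1L, max)
  ## smallest altitude = 3 V / largest face area
  fa <- matrix(0, nrow(cl), 4L)
  combs <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  for (k in 1:4) {
    idx <- combs[[k]]
    a <- nd[cl[, idx[1L]], , drop = FALSE]
    u <- nd[cl[, idx[2L]], , drop = FALSE] - a
    v <- nd[cl[, idx[3L]], , drop = FALSE] - a
    cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    fa[, k] <- sqrt(rowSums(cr^2)) / 2
  }
  hmin <- 3 * vol / apply(fa, 1L, max)
  ## dihedral angles from face normals: angle between faces sharing an edge
  min_dihedral <- min_dihedral_angles(nd, cl)
  list(mean_aspect_ratio = mean(lmax / hmin),
       min_dihedral_deg = min(min_dihedral))
}

min_dihedral_angles <- function(nd, cl) {
  normal_of <- function(i, j, k) {
    a <- nd[cl[, i], , drop = FALSE]
    u <- nd[cl[, j], , drop = FALSE] - a
    v <- nd[cl[, k], , drop = FALSE] - a
    cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
                u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
                u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    cr / sqrt(rowSums(cr^2))
  }
  ## outward normals per local face (opposite vertex 1..4)
  n1 <- normal_of(2L, 3L, 4L); n2 <- normal_of(1L, 4L, 3L)
  n3 <- normal_of(1L, 2L, 4L); n4 <- normal_of(1L, 3L, 2L)
  ns <- list(n1, n2, n3, n4)
  ang <- matrix(NA_real_, nrow(cl), 6L)
  k <- 0L
  for (i in 1:3) for (j in (i + 1L):4L) {
    k <- k + 1L
    cosang <- rowSums(ns[[i]] * ns[[j]])
    cosang <- pmin(1, pmax(-1, cosang))
    ang[, k] <- 180 - acos(cosang) * 180 / pi
  }
  apply(ang, 1L, min)
}

#' Areas of a labeled boundary group
#'
#' @param mesh an `fe_mesh`.
#' @param group face group name.
#' @return Total area (cm^2; length in 2D) of the group's faces.
#' @export
group_area <- function(mesh, group) {
  sel <- mesh$face_labels == group
  if (!any(sel)) stop(sprintf("face group '%s' has no faces", group))
  fg <- face_geometry(mesh)
  sum(fg$area[sel])
}

#' Node indices belonging to a face group
#' @param mesh an `fe_mesh`.
#' @param group face group name (or vector of names).
#' @return Sorted integer vector of node indices.
#' @export
group_nodes <- function(mesh, group) {
  sel <- mesh$face_labels %in% group
  sort(unique(as.vector(mesh$boundary_faces[sel, , drop = FALSE])))
}

## Largest connected component of the cell set (node-connectivity).
keep_largest_component <- function(nodes, cells, dim) {
  edges <- NULL
  for (j in seq_len(ncol(cells) - 1L))
    edges <- rbind(edges, cells[, c(j, j + 1L), drop = FALSE])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  roots <- memb[cells[, 1L]]
  tab <- table(roots)
  main <- as.integer(names(tab)[which.max(tab)])
  cells[roots == main, , drop = FALSE]
}

## Drop unused nodes, remap cell indices.
compact_mesh_arrays <- function(nodes, cells) {
  used <- sort(unique(as.vector(cells)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  list(nodes = nodes[used, , drop = FALSE],
       cells = matrix(remap[cells], nrow(cells), ncol(cells)))
}
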