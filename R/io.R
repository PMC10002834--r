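#' Write a mesh (with optional point data) as ASCII VTU
#'
#' XML VTK unstructured-grid format; face-group labels are preserved on the
#' boundary faces via a companion `_boundary.vtu` when `boundary = TRUE`.
#'
#' @param mesh an [fe_mesh].
#' @param file output path (`.vtu`).
#' @param point_data named list of per-node vectors/matrices.
#' @param boundary also write the labeled boundary surface alongside.
#' @return Invisibly, the file path.
#' @export
write_vtu <- function(mesh, file, point_data = list(), boundary = FALSE) {
  nd <- mesh$nodes
  if (ncol(nd) == 2L) nd <- cbind(nd, 0)
  cl <- mesh$cells
  vtk_type <- if (mesh$dim == 2L) 5L else 10L  # triangle / tetra
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(nd), nrow(cl)))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(nd, 1L, paste, collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(cl - 1L, 1L, paste, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(nrow(cl)) * ncol(cl)), con)
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(vtk_type, nrow(cl))), con)
  w('</DataArray>')
  w('</Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.null(dim(val))) {
        w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
        writeLines(as.character(val), con)
      } else {
        v3 <- val
        if (ncol(v3) == 2L) v3 <- cbind(v3, 0)
        w(sprintf(paste0('<DataArray type="Float64" Name="%s" ',
                         'NumberOfComponents="3" format="ascii">'), nm))
        writeLines(apply(v3, 1L, paste, collapse = " "), con)
      }
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  if (boundary) {
    bfile <- sub("\\.vtu$", "_boundary.vtu", file)
    write_boundary_vtu(mesh, bfile)
  }
  invisible(file)
}

write_boundary_vtu <- function(mesh, file) {
  nd <- mesh$nodes
  if (ncol(nd) == 2L) nd <- cbind(nd, 0)
  bf <- mesh$boundary_faces
  groups <- sort(unique(mesh$face_labels))
  gid <- match(mesh$face_labels, groups)
  vtk_type <- if (mesh$dim == 2L) 3L else 5L   # line / triangle
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w(sprintf('<!-- face groups: %s -->',
            paste(sprintf("%d=%s", seq_along(groups), groups), collapse = " ")))
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nrow(nd), nrow(bf)))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(nd, 1L, paste, collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(bf - 1L, 1L, paste, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(nrow(bf)) * ncol(bf)), con)
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(vtk_type, nrow(bf))), con)
  w('</DataArray>')
  w('</Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="face_group" format="ascii">')
  writeLines(as.character(gid), con)
  w('</DataArray>')
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

#' Read a VTU file written by [write_vtu]
#'
#' Supports the ASCII subset this package writes (triangles/tetrahedra plus
#' point data).
#'
#' @param file path to a `.vtu` file.
#' @return List with `nodes`, `cells`, `point_data`.
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1L]])
  pts <- num(xml2::xml_text(xml2::xml_find_first(piece,
           ".//Points/DataArray")))
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- num(xml2::xml_text(xml2::xml_find_first(piece,
           ".//Cells/DataArray[@Name='connectivity']")))
  offs <- num(xml2::xml_text(xml2::xml_find_first(piece,
           ".//Cells/DataArray[@Name='offsets']")))
  nen <- offs[1L]
  cells <- matrix(as.integer(conn) + 1L, ncol = nen, byrow = TRUE)
  pd <- list()
  for (da in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(da, "Name")
    ncomp <- xml2::xml_attr(da, "NumberOfComponents")
    val <- num(xml2::xml_text(da))
    pd[[nm]] <- if (is.na(ncomp)) val else matrix(val, ncol = as.integer(ncomp),
                                                  byrow = TRUE)
  }
  if (all(abs(nodes[, 3L]) < 1e-300) && nen == 3L)
    nodes <- nodes[, 1:2, drop = FALSE]
  list(nodes = nodes, cells = cells, point_data = pd)
}

#' Write a labeled mesh in Gmsh 4.1 ASCII format
#'
#' Emits one surface entity per face group (with physical names) and a
#' single volume entity holding the simplices, so group labels round-trip.
#'
#' @param mesh an [fe_mesh].
#' @param file output path (`.msh`).
#' @return Invisibly, the path.
#' @export
write_msh <- function(mesh, file) {
  d <- mesh$dim
  groups <- sort(unique(mesh$face_labels))
  ng <- length(groups)
  nd <- mesh$nodes
  if (ncol(nd) == 2L) nd <- cbind(nd, 0)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(ng + 1L)
  for (k in seq_len(ng)) w(sprintf('%d %d "%s"', d - 1L, k, groups[k]))
  w(sprintf('%d %d "fluid"', d, ng + 1L))
  w("$EndPhysicalNames")
  bb <- apply(nd, 2L, range)
  bbs <- paste(c(bb[1L, ], bb[2L, ]), collapse = " ")
  w("$Entities")
  if (d == 3L) {
    w(sprintf("0 0 %d 1", ng))
    for (k in seq_len(ng)) w(sprintf("%d %s 1 %d 0", k, bbs, k))
    w(sprintf("1 %s 1 %d 0", bbs, ng + 1L))
  } else {
    w(sprintf("0 %d 1 0", ng))
    for (k in seq_len(ng)) w(sprintf("%d %s 1 %d 0", k, bbs, k))
    w(sprintf("1 %s 1 %d 0", bbs, ng + 1L))
  }
  w("$EndEntities")
  n <- nrow(nd)
  w("$Nodes")
  w(sprintf("1 %d 1 %d", n, n))
  w(sprintf("%d 1 0 %d", d, n))
  writeLines(as.character(seq_len(n)), con)
  writeLines(apply(nd, 1L, paste, collapse = " "), con)
  w("$EndNodes")
  etype_face <- if (d == 3L) 2L else 1L   # triangle / line
  etype_cell <- if (d == 3L) 4L else 2L   # tet / triangle
  w("$Elements")
  nblocks <- ng + 1L
  ntot <- nrow(mesh$boundary_faces) + nrow(mesh$cells)
  w(sprintf("%d %d 1 %d", nblocks, ntot, ntot))
  eid <- 0L
  for (k in seq_len(ng)) {
    sel <- which(mesh$face_labels == groups[k])
    w(sprintf("%d %d %d %d", d - 1L, k, etype_face, length(sel)))
    f <- mesh$boundary_faces[sel, , drop = FALSE]
    writeLines(paste(eid + seq_along(sel),
                     apply(f, 1L, paste, collapse = " ")), con)
    eid <- eid + length(sel)
  }
  w(sprintf("%d 1 %d %d", d, etype_cell, nrow(mesh$cells)))
  writeLines(paste(eid + seq_len(nrow(mesh$cells)),
                   apply(mesh$cells, 1L, paste, collapse = " ")), con)
  w("$EndElements")
  invisible(file)
}

#' Read a Gmsh 4.1 ASCII mesh
#'
#' Parses the subset written by [write_msh] (single node block, physical
#' surface groups, one volume block) into an [fe_mesh].
#'
#' @param file path to a `.msh` file.
#' @return An [fe_mesh].
#' @export
read_msh <- function(file) {
  lines <- readLines(file)
  sec <- function(name) {
    i0 <- which(lines == paste0("$", name)) + 1L
    i1 <- which(lines == paste0("$End", name)) - 1L
    if (!length(i0)) stop(sprintf("read_msh: missing section %s", name))
    lines[i0:i1]
  }
  pn <- sec("PhysicalNames")
  npn <- as.integer(pn[1L])
  phys <- data.frame(dim = integer(npn), tag = integer(npn),
                     name = character(npn))
  for (k in seq_len(npn)) {
    parts <- strsplit(pn[k + 1L], " ")[[1L]]
    phys$dim[k] <- as.integer(parts[1L])
    phys$tag[k] <- as.integer(parts[2L])
    phys$name[k] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }
  d <- max(phys$dim)
  nl <- sec("Nodes")
  hdr <- as.numeric(strsplit(nl[1L], " ")[[1L]])
  nn <- hdr[2L]
  tag_lines <- nl[3:(2 + nn)]
  coord_lines <- nl[(3 + nn):(2 + 2 * nn)]
  coords <- matrix(as.numeric(unlist(strsplit(coord_lines, " "))),
                   ncol = 3L, byrow = TRUE)
  nodes <- coords[order(as.integer(tag_lines)), , drop = FALSE]
  if (d == 2L) nodes <- nodes[, 1:2, drop = FALSE]
  el <- sec("Elements")
  hdr <- as.integer(strsplit(el[1L], " ")[[1L]])
  nblocks <- hdr[1L]
  pos <- 2L
  faces <- NULL; labels <- character(0); cells <- NULL
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(el[pos], " ")[[1L]])
    edim <- bh[1L]; etag <- bh[2L]; nel <- bh[4L]
    rows <- el[pos + seq_len(nel)]
    conn <- matrix(as.integer(unlist(strsplit(rows, " "))),
                   nrow = nel, byrow = TRUE)[, -1L, drop = FALSE]
    if (edim == d) {
      cells <- rbind(cells, conn)
    } else if (edim == d - 1L) {
      nm <- phys$name[phys$dim == edim & phys$tag == etag]
      faces <- rbind(faces, conn)
      labels <- c(labels, rep(nm, nel))
    }
    pos <- pos + 1L + nel
  }
  cells <- orient_cells(nodes, cells, d)
  fe_mesh(nodes, cells, faces, labels)
}

#' Export a flow field as a VTU time series
#'
#' One file per snapshot with `velocity` (cm/s) and `pressure` (dyn/cm^2)
#' point data, plus a plain-text index.
#'
#' @param field a `flow_field`.
#' @param dir output directory (created if missing).
#' @param base file-name stem.
#' @return Invisibly, the index file path.
#' @export
export_flow_field <- function(field, dir, base = "flow") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- file.path(dir, paste0(base, "_series.txt"))
  rows <- character(0)
  for (k in seq_along(field$times)) {
    f <- file.path(dir, sprintf("%s_%04d.vtu", base, k - 1L))
    write_vtu(field$mesh, f,
              point_data = list(velocity = field$v[[k]],
                                pressure = field$p[[k]]))
    rows <- c(rows, sprintf("%g %s", field$times[k], basename(f)))
  }
  writeLines(c("# time file", rows), idx)
  invisible(idx)
}

#' Export a washout field as VTU
#'
#' Point data `washout_time_s` and `censored`.
#'
#' @param wf a [washout_time] field.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
export_washout_field <- function(wf, file) {
  write_vtu(wf$mesh, file,
            point_data = list(washout_time_s = wf$T,
                              censored = as.numeric(wf$censored)))
  invisible(file)
}

#' Write an MCL dataset as CSV
#'
#' Columns `case_id`, `CO_L_min`, `model`, `dP_mmHg`, `source`.
#'
#' @param mcl an `mcl_dataset`.
#' @param file path.
#' @return Invisibly, the path.
#' @export
write_mcl_csv <- function(mcl, file) {
  utils::write.csv(mcl[, c("case_id", "CO_L_min", "model", "dP_mmHg",
                           "source")], file, row.names = FALSE)
  invisible(file)
}
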