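# Mesh file formats: Gmsh MSH 2.2 ASCII and a plain two-file node/element
# text format (node: index x y; element: index n1 n2 n3, 1-based).

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' @param mesh a [pnp_mesh].
#' @param path output `.msh` path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- nrow(mesh$nodes); nel <- nrow(mesh$triangles)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(m)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(m),
                     mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nel)), con)
  writeLines(sprintf("%d 2 2 0 1 %d %d %d", seq_len(nel),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh from Gmsh MSH 2.2 ASCII format
#'
#' Triangles (element type 2) are kept; points and lines are ignored.
#'
#' @param path a `.msh` file.
#' @return a [pnp_mesh].
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("missing $", name, " section in ", path)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1L]), "\\s+")[[1L]]
  if (!startsWith(fmt[1L], "2")) {
    stop("unsupported MSH version ", fmt[1L], " (need 2.x ASCII)")
  }
  nl <- sect("Nodes")
  nn <- as.integer(nl[1L])
  ntab <- matrix(as.numeric(unlist(strsplit(trimws(nl[1L + seq_len(nn)]),
                                            "\\s+"))), ncol = 4L, byrow = TRUE)
  ord <- order(ntab[, 1L])
  nodes <- ntab[ord, 2:3, drop = FALSE]
  id_map <- integer(max(ntab[, 1L]))
  id_map[as.integer(ntab[ord, 1L])] <- seq_len(nn)
  el <- sect("Elements")
  ne <- as.integer(el[1L])
  tris <- list()
  for (k in seq_len(ne)) {
    fields <- as.integer(strsplit(trimws(el[1L + k]), "\\s+")[[1L]])
    if (fields[2L] != 2L) next                       # not a triangle
    ntags <- fields[3L]
    conn <- fields[(4L + ntags):(6L + ntags)]
    tris[[length(tris) + 1L]] <- id_map[conn]
  }
  if (length(tris) == 0L) stop("no triangles in ", path)
  pnp_mesh(nodes, do.call(rbind, tris))
}

#' Write a mesh in plain node/element text format
#'
#' Two whitespace-separated files: nodes as `index x y`, elements as
#' `index n1 n2 n3` with 1-based node indices.
#'
#' @param mesh a [pnp_mesh].
#' @param node_path,ele_path output paths.
#' @return invisibly, `c(node_path, ele_path)`.
#' @export
write_mesh_txt <- function(mesh, node_path, ele_path) {
  m <- nrow(mesh$nodes)
  writeLines(sprintf("%d %.17g %.17g", seq_len(m),
                     mesh$nodes[, 1L], mesh$nodes[, 2L]), node_path)
  writeLines(sprintf("%d %d %d %d", seq_len(nrow(mesh$triangles)),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), ele_path)
  invisible(c(node_path, ele_path))
}

#' Read a mesh from plain node/element text files
#'
#' @param node_path,ele_path files written by [write_mesh_txt()].
#' @return a [pnp_mesh].
#' @export
read_mesh_txt <- function(node_path, ele_path) {
  nt <- utils::read.table(node_path)
  et <- utils::read.table(ele_path)
  nodes <- as.matrix(nt[order(nt[[1L]]), 2:3])
  pnp_mesh(nodes, as.matrix(et[, 2:4]))
}

#' Write a legacy-VTK snapshot of nodal fields
#'
#' ASCII unstructured-grid file with one scalar point-data array per field
#' (concentrations in muM, potential in mV), readable by ParaView/VisIt.
#'
#' @param path output `.vtk` path.
#' @param mesh a [pnp_mesh].
#' @param fields named list of nodal vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, mesh, fields) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- nrow(mesh$nodes); nel <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "pnpfem snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", m)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]),
             con)
  writeLines(sprintf("CELLS %d %d", nel, 4L * nel), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                     mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L),
             con)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(rep("5", nel), con)
  writeLines(sprintf("POINT_DATA %d", m), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.17g", fields[[nm]]), con)
  }
  invisible(path)
}
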