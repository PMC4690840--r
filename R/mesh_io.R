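# Mesh, surface and fiber writers (plain-text formats).
#
# CARP text layout, exactly as written/read here:
#   <base>.pts  : line 1 = node count; then "x y z" per node, micrometers,
#                 "%.6f" fields separated by single spaces.
#   <base>.elem : line 1 = element count; then "Tt n0 n1 n2 n3 tag" with
#                 0-based node indices.
#   <base>.lon  : line 1 = number of fiber axes (1 or 2); then 3 (fiber) or
#                 6 (fiber + sheet) "%.8f" numbers per element.
#   <name>.surf : line 1 = face count; then "Tr n0 n1 n2", 0-based.

#' Write a tetrahedral mesh (and optional fibers) in CARP text format
#'
#' @param mesh a \code{tet_mesh}.
#' @param basename output path without extension.
#' @param fibers optional \code{fiber_field}; writes \code{<basename>.lon}
#'   with 2 axes (fiber + sheet).
#' @return character vector of paths written, invisibly.
#' @export
write_carp_mesh <- function(mesh, basename, fibers = NULL) {
  pts <- paste0(basename, ".pts")
  con <- file(pts, "wb")  # "wb": byte-identical output across platforms
  writeLines(as.character(nrow(mesh$nodes)), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$nodes[, 1] * 1000,
                     mesh$nodes[, 2] * 1000, mesh$nodes[, 3] * 1000), con)
  close(con)
  elem <- paste0(basename, ".elem")
  con <- file(elem, "wb")
  writeLines(as.character(nrow(mesh$tets)), con)
  writeLines(sprintf("Tt %d %d %d %d %d",
                     mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L,
                     mesh$element_tags), con)
  close(con)
  paths <- c(pts, elem)
  if (!is.null(fibers)) {
    lon <- paste0(basename, ".lon")
    con <- file(lon, "wb")
    writeLines("2", con)
    writeLines(sprintf("%.8f %.8f %.8f %.8f %.8f %.8f",
                       fibers$f[, 1], fibers$f[, 2], fibers$f[, 3],
                       fibers$s[, 1], fibers$s[, 2], fibers$s[, 3]), con)
    close(con)
    paths <- c(paths, lon)
  }
  invisible(paths)
}

#' Read a CARP text mesh
#'
#' Generic import path for externally generated tetrahedral meshes.
#'
#' @param basename path without extension; reads \code{.pts}, \code{.elem}
#'   and, when present, \code{.lon}.
#' @return a \code{tet_mesh}; fibers, if read, in attribute \code{"fibers"}.
#' @export
read_carp_mesh <- function(basename) {
  pts <- readLines(paste0(basename, ".pts"))
  nn <- as.integer(pts[1])
  nodes <- matrix(scan(text = pts[-1], quiet = TRUE), ncol = 3,
                  byrow = TRUE)[seq_len(nn), , drop = FALSE] / 1000
  el <- readLines(paste0(basename, ".elem"))
  ne <- as.integer(el[1])
  parts <- strsplit(el[-1][seq_len(ne)], "\\s+")
  mat <- do.call(rbind, lapply(parts, function(p) as.integer(p[-1])))
  mesh <- tet_mesh(nodes, mat[, 1:4] + 1L, mat[, 5])
  lonp <- paste0(basename, ".lon")
  if (file.exists(lonp)) {
    lon <- readLines(lonp)
    naxes <- as.integer(lon[1])
    v <- matrix(scan(text = lon[-1], quiet = TRUE), ncol = 3 * naxes,
                byrow = TRUE)
    attr(mesh, "fibers") <- v
  }
  mesh
}

#' Write face sets in CARP .surf format
#'
#' @param fs a \code{face_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_carp_surf <- function(fs, path) {
  con <- file(path, "wb")
  writeLines(as.character(nrow(fs$faces)), con)
  if (nrow(fs$faces))
    writeLines(sprintf("Tr %d %d %d", fs$faces[, 1] - 1L,
                       fs$faces[, 2] - 1L, fs$faces[, 3] - 1L), con)
  close(con)
  invisible(path)
}

#' Write a tagged surface as ASCII STL
#'
#' STL carries no labels; all faces are emitted as one solid.
#'
#' @param surface a \code{tagged_surface}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  nrm <- normalize_rows(cross_rows(b - a, cc - a))
  con <- file(path, "wb")
  writeLines("solid surface", con)
  block <- paste0(
    sprintf("facet normal %.8e %.8e %.8e\n", nrm[, 1], nrm[, 2], nrm[, 3]),
    "outer loop\n",
    sprintf("vertex %.8e %.8e %.8e\n", a[, 1], a[, 2], a[, 3]),
    sprintf("vertex %.8e %.8e %.8e\n", b[, 1], b[, 2], b[, 3]),
    sprintf("vertex %.8e %.8e %.8e\n", cc[, 1], cc[, 2], cc[, 3]),
    "endloop\nendfacet")
  writeLines(block, con)
  writeLines("endsolid surface", con)
  close(con)
  invisible(path)
}

#' Write a tagged surface as legacy ASCII VTK polydata
#'
#' Face labels (inner, outer) are attached as cell data.
#'
#' @param surface a \code{tagged_surface}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vtk_surface <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "wb")
  writeLines(c("# vtk DataFile Version 3.0", "tagged surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(f)),
               "SCALARS tag_inner int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(surface$face_labels[, 1]), con)
  writeLines(c("SCALARS tag_outer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(surface$face_labels[, 2]), con)
  close(con)
  invisible(path)
}

#' Write a tetrahedral mesh as VTU (XML unstructured grid, ASCII)
#'
#' Element tags are written as cell data; fiber and sheet vectors are
#' appended when a \code{fiber_field} is given.
#'
#' @param mesh a \code{tet_mesh}.
#' @param path output path.
#' @param fibers optional \code{fiber_field}.
#' @return \code{path}, invisibly.
#' @export
write_vtu_mesh <- function(mesh, path, fibers = NULL) {
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  con <- file(path, "wb")
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
            mesh$nodes[, 3]))
  w('        </DataArray>', '      </Points>', '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w(sprintf("%d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
            mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L))
  w('        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">')
  w(as.character(seq_len(ne) * 4L))
  w('        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">')
  w(rep("10", ne))  # VTK_TETRA
  w('        </DataArray>', '      </Cells>', '      <CellData>',
    '        <DataArray type="Int32" Name="tag" format="ascii">')
  w(as.character(mesh$element_tags))
  w('        </DataArray>')
  if (!is.null(fibers)) {
    w('        <DataArray type="Float64" Name="fiber" NumberOfComponents="3" format="ascii">')
    w(sprintf("%.8f %.8f %.8f", fibers$f[, 1], fibers$f[, 2], fibers$f[, 3]))
    w('        </DataArray>')
    w('        <DataArray type="Float64" Name="sheet" NumberOfComponents="3" format="ascii">')
    w(sprintf("%.8f %.8f %.8f", fibers$s[, 1], fibers$s[, 2], fibers$s[, 3]))
    w('        </DataArray>')
  }
  w('      </CellData>', '    </Piece>', '  </UnstructuredGrid>',
    '</VTKFile>')
  close(con)
  invisible(path)
}
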