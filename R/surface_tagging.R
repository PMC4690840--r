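#' Canonicalized set of mesh boundary/interface triangles
#'
#' Faces are stored as node-index triples sorted ascending within each face,
#' with duplicates removed, so that set algebra is exact.
#'
#' @param faces m x 3 matrix of node indices.
#' @param mesh the source \code{tet_mesh}.
#' @param name optional set name.
#' @return an object of class \code{face_set}.
#' @export
face_set <- function(faces, mesh, name = NULL) {
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces)) {
    lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
    hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
    mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
    faces <- cbind(lo, mid, hi)
    faces <- faces[!duplicated(face_keys(faces)), , drop = FALSE]
    if (max(faces) > nrow(mesh$nodes)) stop("face references invalid node")
  }
  structure(list(faces = faces, name = name,
                 mesh_sig = mesh_signature(mesh)),
            class = "face_set")
}

mesh_signature <- function(mesh)
  c(nrow(mesh$nodes), nrow(mesh$tets), sum(mesh$element_tags))

face_keys <- function(faces) paste(faces[, 1], faces[, 2], faces[, 3])

#' @export
print.face_set <- function(x, ...) {
  cat(sprintf("face_set%s: %d faces\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$faces)))
  invisible(x)
}

#' @export
length.face_set <- function(x) nrow(x$faces)

#' Boundary faces of a set of element tags
#'
#' Returns the topological boundary of the selected element set: every face
#' belonging to exactly one tetrahedron with tag in \code{tags}. The
#' background region is representable as the complement: \code{tags = 0}
#' yields the boundary of all foreground elements (the global mesh boundary).
#'
#' @param mesh a \code{tet_mesh}.
#' @param tags integer element tags, or 0 for the background complement.
#' @param name optional set name.
#' @return a \code{face_set}.
#' @export
tag_boundary <- function(mesh, tags, name = NULL) {
  tags <- as.integer(tags)
  if (identical(tags, 0L)) {
    sel <- seq_len(nrow(mesh$tets))
  } else {
    unknown <- setdiff(tags, unique(mesh$element_tags))
    if (length(unknown))
      stop(sprintf("unknown tag(s): %s", paste(unknown, collapse = ", ")))
    sel <- which(mesh$element_tags %in% tags)
  }
  bf <- faces_of_tets(mesh$tets[sel, , drop = FALSE], singles_only = TRUE)
  face_set(bf, mesh, name = name)
}

#' Set algebra on face sets
#'
#' @param a,b \code{face_set}s over the same mesh.
#' @param op \code{"union"}, \code{"intersection"} or \code{"difference"}.
#' @return a \code{face_set}.
#' @export
face_set_op <- function(a, b, op = c("union", "intersection", "difference")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "face_set"), inherits(b, "face_set"))
  if (!identical(a$mesh_sig, b$mesh_sig))
    stop("face sets come from different meshes")
  ka <- face_keys(a$faces); kb <- face_keys(b$faces)
  faces <- switch(op,
    union = rbind(a$faces, b$faces[!(kb %in% ka), , drop = FALSE]),
    intersection = a$faces[ka %in% kb, , drop = FALSE],
    difference = a$faces[!(ka %in% kb), , drop = FALSE])
  out <- a
  out$faces <- faces
  out$name <- NULL
  out
}

#' Derive the boundary-condition surfaces for fiber assignment
#'
#' From the tagged mesh, derives by face-set algebra the named anatomical
#' surfaces the Laplace-Dirichlet fiber rule needs: LV/RV endocardium
#' (pool-myocardium interfaces, which on the septum includes RV-pool faces
#' against LV myocardium), biventricular epicardium (per-ventricle
#' intersection of the ventricle boundary with the background boundary,
#' unioned), the base (myocardium against the base tag, or, absent a base
#' tag, myocardial boundary faces on the maximal-z plane), and the apex node
#' (extremal epicardial node along \code{-z}).
#'
#' @param mesh a \code{tet_mesh}.
#' @param roles named integer vector/list mapping roles
#'   (\code{lv_myo}, \code{lv_pool}, and optionally \code{rv_myo},
#'   \code{rv_pool}, \code{base}) to element tags; defaults to the phantom
#'   convention looked up from the mesh tag table by region name.
#' @return named list of \code{face_set}s \code{lv_endo}, \code{rv_endo},
#'   \code{epi}, \code{base}, plus \code{apex_node} (integer node index).
#' @export
derive_bc_surfaces <- function(mesh, roles = NULL) {
  if (is.null(roles)) roles <- roles_from_tags(mesh$tags)
  roles <- lapply(roles, as.integer)
  req <- c("lv_myo", "lv_pool")
  missing <- setdiff(req, names(roles))
  if (length(missing))
    stop(sprintf("derive_bc_surfaces requires tag roles: %s",
                 paste(missing, collapse = ", ")))
  has_rv <- all(c("rv_myo", "rv_pool") %in% names(roles))
  myo <- c(roles$lv_myo, if (has_rv) roles$rv_myo)
  g_myo <- tag_boundary(mesh, myo)
  g_lv <- tag_boundary(mesh, roles$lv_myo)
  g_b <- tag_boundary(mesh, 0L, name = "background")

  lv_endo <- face_set_op(g_myo, tag_boundary(mesh, roles$lv_pool),
                         "intersection")
  lv_endo$name <- "lv_endo"
  if (!nrow(lv_endo$faces)) stop("lv_endo is empty: mis-tagged segmentation")

  if (has_rv) {
    rv_endo <- face_set_op(g_myo, tag_boundary(mesh, roles$rv_pool),
                           "intersection")
    if (!nrow(rv_endo$faces)) stop("rv_endo is empty: mis-tagged segmentation")
    lv_epi <- face_set_op(g_lv, g_b, "intersection")
    rv_epi <- face_set_op(tag_boundary(mesh, roles$rv_myo), g_b,
                          "intersection")
    epi <- face_set_op(lv_epi, rv_epi, "union")
  } else {
    rv_endo <- face_set(matrix(0L, 0, 3), mesh)
    epi <- face_set_op(g_lv, g_b, "intersection")
  }
  rv_endo$name <- "rv_endo"
  epi <- face_set_op(face_set_op(epi, lv_endo, "difference"),
                     rv_endo, "difference")
  epi$name <- "epi"
  if (!nrow(epi$faces)) stop("epi is empty: mis-tagged segmentation")

  if (!is.null(roles$base)) {
    base <- face_set_op(g_myo, tag_boundary(mesh, roles$base), "intersection")
  } else {
    zmax <- max(mesh$nodes[unique(as.vector(g_myo$faces)), 3])
    onplane <- matrix(abs(mesh$nodes[g_myo$faces, 3] - zmax) < 1e-9,
                      ncol = 3)
    base <- face_set(g_myo$faces[rowSums(onplane) == 3L, , drop = FALSE],
                     mesh)
  }
  base$name <- "base"
  if (!nrow(base$faces)) stop("base is empty: mis-tagged segmentation")
  epi <- face_set_op(epi, base, "difference")
  epi$name <- "epi"

  epi_nodes <- unique(as.vector(epi$faces))
  apex_node <- epi_nodes[order(mesh$nodes[epi_nodes, 3], epi_nodes)][1]
  # a point Dirichlet condition has vanishing capacity in 3D, which makes
  # the apicobasal field degenerate; provide a small apex patch (epicardial
  # nodes within 5% of the long-axis extent of the apex) alongside the node
  zext <- diff(range(mesh$nodes[unique(as.vector(g_myo$faces)), 3]))
  apex_p <- mesh$nodes[apex_node, ]
  dist2 <- rowSums(sweep(mesh$nodes[epi_nodes, , drop = FALSE], 2,
                         apex_p)^2)
  apex_region <- epi_nodes[dist2 <= (0.05 * zext)^2]
  list(lv_endo = lv_endo, rv_endo = rv_endo, epi = epi, base = base,
       apex_node = apex_node, apex_region = apex_region)
}

# Map phantom-style region names in a tag table to BC roles.
roles_from_tags <- function(tags) {
  if (is.null(tags)) stop("mesh has no tag table; supply roles explicitly")
  find <- function(nm) {
    hit <- names(tags)[tags == nm]
    if (length(hit)) as.integer(hit[1]) else NULL
  }
  r <- list(lv_myo = find("LV_myo"), rv_myo = find("RV_myo"),
            lv_pool = find("LV_pool"), rv_pool = find("RV_pool"),
            base = find("base"))
  r[!vapply(r, is.null, TRUE)]
}

#' Nodes referenced by a face set
#' @param fs a \code{face_set}.
#' @return sorted integer node indices.
#' @export
face_set_nodes <- function(fs) sort(unique(as.vector(fs$faces)))
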