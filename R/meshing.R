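#' Tagged tetrahedral mesh
#'
#' @param nodes n x 3 matrix of node coordinates (mm).
#' @param tets m x 4 matrix of 1-based node indices, positively oriented.
#' @param element_tags integer label per element.
#' @param tags optional tag table (named character vector).
#' @param spacing optional source voxel spacing (mm), kept for boundary caps.
#' @return an object of class \code{tet_mesh}.
#' @export
tet_mesh <- function(nodes, tets, element_tags, tags = NULL, spacing = NULL) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  tets <- matrix(as.integer(tets), ncol = 4)
  element_tags <- as.integer(element_tags)
  stopifnot(nrow(tets) == length(element_tags))
  structure(list(nodes = nodes, tets = tets, element_tags = element_tags,
                 tags = tags, spacing = spacing),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra\n",
              nrow(x$nodes), nrow(x$tets)))
  tab <- table(x$element_tags)
  for (k in names(tab)) {
    nm <- if (!is.null(x$tags) && k %in% names(x$tags)) x$tags[[k]] else ""
    cat(sprintf("  tag %s %s: %d elements\n", k, nm, tab[[k]]))
  }
  invisible(x)
}

# Signed volumes of all elements.
tet_volumes <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  cc <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  rowSums(a * cross_rows(b, cc)) / 6
}

#' Tetrahedral mesh of a tagged label image
#'
#' Splits every selected foreground voxel into 6 positively oriented Kuhn
#' tetrahedra on the shared corner lattice (the Kuhn/Freudenthal split
#' conforms across voxel faces), carrying the voxel label as element tag.
#' An optional boundary relaxation step applies umbrella smoothing to the
#' boundary nodes under the same half-voxel displacement cap, reverting any
#' move that would invert an element.
#'
#' @param image a \code{label_image}.
#' @param tags labels to mesh (default: all nonzero labels present).
#' @param relax_boundary integer: number of constrained boundary-smoothing
#'   sweeps (default 0 = off).
#' @return a \code{tet_mesh}.
#' @export
mesh_from_label_image <- function(image, tags = NULL, relax_boundary = 0L) {
  stopifnot(inherits(image, "label_image"))
  if (is.null(tags)) {
    tags <- sort(unique(as.vector(image$voxels)))
    tags <- tags[tags != 0L]
  } else tags <- resolve_tags(image, tags)
  d <- dim(image$voxels)
  sel <- which(array(image$voxels %in% tags, dim = d))
  if (!length(sel)) stop("empty selection: no voxel carries the requested tags")
  vi <- (sel - 1L) %% d[1]
  vj <- ((sel - 1L) %/% d[1]) %% d[2]
  vk <- (sel - 1L) %/% (d[1] * d[2])
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  corner <- function(di, dj, dk)
    (vi + di) + (vj + dj) * nx1 + (vk + dk) * nx1 * ny1 + 1L

  offs <- kuhn_tet_offsets()
  m <- length(sel)
  tets <- matrix(0L, nrow = 6L * m, ncol = 4L)
  for (tt in seq_along(offs)) {
    off <- offs[[tt]]
    rows <- seq.int(tt, by = 6L, length.out = m)
    for (cpos in 1:4)
      tets[rows, cpos] <- corner(off[cpos, 1], off[cpos, 2], off[cpos, 3])
  }
  etags <- rep(image$voxels[sel], each = 1L)[rep(seq_len(m), each = 6L)]
  used <- sort(unique(as.vector(tets)))
  tets <- matrix(match(tets, used), ncol = 4L)
  ui <- (used - 1L) %% nx1
  uj <- ((used - 1L) %/% nx1) %% ny1
  uk <- (used - 1L) %/% (nx1 * ny1)
  nodes <- cbind(image$origin[1] + ui * image$spacing[1],
                 image$origin[2] + uj * image$spacing[2],
                 image$origin[3] + uk * image$spacing[3])
  mesh <- tet_mesh(nodes, tets, etags, tags = image$tags,
                   spacing = image$spacing)
  if (relax_boundary > 0L)
    mesh <- relax_mesh_boundary(mesh, sweeps = relax_boundary)
  mesh
}

# Constrained umbrella smoothing of boundary nodes: each sweep moves every
# boundary node halfway toward the mean of its boundary neighbors, clamped to
# +-0.5 voxel from the lattice position; moves that invert an incident
# element are reverted.
relax_mesh_boundary <- function(mesh, sweeps = 1L, cap_voxels = 0.5) {
  sp <- mesh$spacing
  if (is.null(sp)) stop("mesh carries no source spacing")
  bfaces <- boundary_faces_all(mesh)
  bnodes <- sort(unique(as.vector(bfaces)))
  X0 <- mesh$nodes
  e1 <- rbind(bfaces[, c(1, 2)], bfaces[, c(2, 3)], bfaces[, c(3, 1)])
  adj <- Matrix::sparseMatrix(i = c(e1[, 1], e1[, 2]),
                              j = c(e1[, 2], e1[, 1]), x = 1,
                              dims = rep(nrow(X0), 2))
  adj@x <- rep(1, length(adj@x))
  deg <- pmax(Matrix::rowSums(adj), 1)
  for (s in seq_len(sweeps)) {
    X <- mesh$nodes
    mean_nb <- as.matrix(adj %*% X) / deg
    prop <- X
    prop[bnodes, ] <- 0.5 * (X[bnodes, ] + mean_nb[bnodes, ])
    lo <- sweep(X0, 2, cap_voxels * sp, "-")
    hi <- sweep(X0, 2, cap_voxels * sp, "+")
    prop <- pmin(pmax(prop, lo), hi)
    trial <- mesh; trial$nodes <- prop
    vol <- tet_volumes(trial)
    bad <- which(vol <= 0)
    if (length(bad)) {
      bad_nodes <- unique(as.vector(mesh$tets[bad, ]))
      prop[bad_nodes, ] <- X[bad_nodes, ]
    }
    mesh$nodes <- prop
  }
  if (any(tet_volumes(mesh) <= 0)) stop("element inversion after boundary adjustment")
  mesh
}

# All boundary faces of the mesh (faces belonging to exactly one tet),
# as a matrix of canonical (sorted) node triples.
boundary_faces_all <- function(mesh) {
  faces_of_tets(mesh$tets, singles_only = TRUE)
}

# Enumerate the 4 faces of every tet as canonical triples; optionally return
# only those appearing exactly once.
faces_of_tets <- function(tets, singles_only = FALSE) {
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
             tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  cf <- cbind(lo, mid, hi)
  if (!singles_only) return(cf)
  o <- order(lo, mid, hi)
  s <- cf[o, , drop = FALSE]
  n <- nrow(s)
  same_prev <- c(FALSE, rowSums(s[-1, , drop = FALSE] ==
                                s[-n, , drop = FALSE]) == 3L)
  same_next <- c(same_prev[-1], FALSE)
  s[!(same_prev | same_next), , drop = FALSE]
}

#' Mesh quality summary
#'
#' Radius ratio is the normalized ratio \eqn{3 r_{in} / R} (1 for the regular
#' tetrahedron), with \eqn{r_{in}} the inradius and \eqn{R} the circumradius.
#'
#' @param mesh a \code{tet_mesh}.
#' @return list: min/mean radius ratio, min dihedral angle (degrees), edge
#'   length min/mean/max (mm), element count, node count.
#' @export
mesh_quality <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  vol <- tet_volumes(mesh)
  p1 <- n[t[, 1], , drop = FALSE]; p2 <- n[t[, 2], , drop = FALSE]
  p3 <- n[t[, 3], , drop = FALSE]; p4 <- n[t[, 4], , drop = FALSE]
  tri_area <- function(a, b, cc) row_norms(cross_rows(b - a, cc - a)) / 2
  A <- tri_area(p2, p3, p4) + tri_area(p1, p3, p4) +
    tri_area(p1, p2, p4) + tri_area(p1, p2, p3)
  r_in <- 3 * vol / A
  # circumcenter: solve 2 (p_i - p_1) . c = |p_i|^2 - |p_1|^2
  b2 <- p2 - p1; b3 <- p3 - p1; b4 <- p4 - p1
  rhs2 <- rowSums(b2 * b2) / 2
  rhs3 <- rowSums(b3 * b3) / 2
  rhs4 <- rowSums(b4 * b4) / 2
  cr <- cross_rows(b3, b4)
  det <- rowSums(b2 * cr)
  cx <- (rhs2 * cr[, 1] + rhs3 * (b4[, 2] * b2[, 3] - b4[, 3] * b2[, 2]) +
           rhs4 * (b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2])) / det
  cy <- (rhs2 * cr[, 2] + rhs3 * (b4[, 3] * b2[, 1] - b4[, 1] * b2[, 3]) +
           rhs4 * (b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3])) / det
  cz <- (rhs2 * cr[, 3] + rhs3 * (b4[, 1] * b2[, 2] - b4[, 2] * b2[, 1]) +
           rhs4 * (b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])) / det
  R <- sqrt(cx^2 + cy^2 + cz^2)
  ratio <- 3 * r_in / R

  # dihedral angles from the 4 outward face normals
  ctr <- (p1 + p2 + p3 + p4) / 4
  outward <- function(nrm, fa, fb, fc) {
    fc_ <- (fa + fb + fc) / 3
    flip <- rowSums(nrm * (fc_ - ctr)) < 0
    nrm[flip, ] <- -nrm[flip, ]
    nrm
  }
  n1 <- outward(normalize_rows(cross_rows(p3 - p2, p4 - p2)), p2, p3, p4)
  n2 <- outward(normalize_rows(cross_rows(p4 - p3, p1 - p3)), p1, p3, p4)
  n3 <- outward(normalize_rows(cross_rows(p1 - p4, p2 - p4)), p1, p2, p4)
  n4 <- outward(normalize_rows(cross_rows(p2 - p1, p3 - p1)), p1, p2, p3)
  dih <- function(na, nb) 180 - acos(pmin(pmax(rowSums(na * nb), -1), 1)) * 180 / pi
  dmin <- pmin(dih(n1, n2), dih(n1, n3), dih(n1, n4),
               dih(n2, n3), dih(n2, n4), dih(n3, n4))

  e <- rbind(t[, c(1, 2)], t[, c(1, 3)], t[, c(1, 4)],
             t[, c(2, 3)], t[, c(2, 4)], t[, c(3, 4)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(ekey), , drop = FALSE]
  el <- row_norms(n[e[, 1], , drop = FALSE] - n[e[, 2], , drop = FALSE])

  list(min_volume = min(vol),
       min_radius_ratio = min(ratio), mean_radius_ratio = mean(ratio),
       min_dihedral_deg = min(dmin),
       edge_length = c(min = min(el), mean = mean(el), max = max(el)),
       n_elements = nrow(t), n_nodes = nrow(n))
}

#' Restrict a mesh to the elements of selected tags
#'
#' @param mesh a \code{tet_mesh}.
#' @param tags element tags to keep.
#' @return a \code{tet_mesh} with attributes \code{node_map} (new -> old node
#'   index) and \code{elem_map} (new -> old element index).
#' @export
submesh <- function(mesh, tags) {
  keep <- which(mesh$element_tags %in% as.integer(tags))
  if (!length(keep)) stop("no elements carry the requested tags")
  tets <- mesh$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  tets <- matrix(match(tets, used), ncol = 4)
  out <- tet_mesh(mesh$nodes[used, , drop = FALSE], tets,
                  mesh$element_tags[keep], tags = mesh$tags,
                  spacing = mesh$spacing)
  attr(out, "node_map") <- used
  attr(out, "elem_map") <- keep
  out
}

#' Verify mesh conformity and orientation invariants
#'
#' Checks that all signed volumes are positive, every node is referenced,
#' and every interior face is shared by exactly two elements (any face
#' appearing more than twice is non-conforming).
#'
#' @param mesh a \code{tet_mesh}.
#' @return \code{TRUE} invisibly; stops with a diagnostic otherwise.
#' @export
check_mesh <- function(mesh) {
  vol <- tet_volumes(mesh)
  if (any(vol <= 0)) stop("non-positive element volume")
  if (length(unique(as.vector(mesh$tets))) != nrow(mesh$nodes))
    stop("unreferenced nodes present")
  cf <- faces_of_tets(mesh$tets)
  o <- order(cf[, 1], cf[, 2], cf[, 3])
  s <- cf[o, , drop = FALSE]
  same <- rowSums(s[-1, , drop = FALSE] == s[-nrow(s), , drop = FALSE]) == 3L
  runs <- rle(c(FALSE, same))
  if (any(runs$lengths[runs$values] > 1L))
    stop("face shared by more than two elements (non-conforming)")
  invisible(TRUE)
}
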