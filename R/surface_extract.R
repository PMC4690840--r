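# Multi-tag surface extraction.
#
# Per-tag isosurfaces are extracted at isovalue 0.5 on the binary indicator
# sampled at voxel centers, using the marching-tetrahedra variant of marching
# cubes: each lattice cell between 8 voxel centers is split into 6 Kuhn
# tetrahedra and each tetrahedron is triangulated from its binary corner
# pattern. Surface vertices lie at midpoints of lattice edges, so two tags
# sharing an interface produce *identical* vertex positions and face vertex
# sets by construction -- the property the merge step relies on. A "blocky"
# mode emits the raw voxel-face surface (exact volumes) instead.

# 6 Kuhn tetrahedra of the unit cell, as 0-based corner offsets.
# Odd permutations have their last two nodes swapped for positive volume.
kuhn_tet_offsets <- function() {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  signs <- c(1, -1, -1, 1, 1, -1)
  lapply(seq_along(perms), function(i) {
    p <- perms[[i]]
    e <- diag(3)
    v <- rbind(c(0,0,0), e[p[1], ], e[p[1], ] + e[p[2], ], c(1,1,1))
    if (signs[i] < 0) v[c(3,4), ] <- v[c(4,3), ]
    v
  })
}

# Triangulation table: for each of the 16 inside-patterns of a tetrahedron's
# 4 corners, the triangles as triples of cut-edge indices into the edge list
# (1,2),(1,3),(1,4),(2,3),(2,4),(3,4). Complementary patterns share the same
# edge triples (orientation fixed geometrically afterwards), which makes the
# interface triangulation tag-symmetric.
tet_edge_pairs <- rbind(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4))

tet_case_table <- local({
  tab <- vector("list", 16)
  one <- list(`1` = rbind(c(1,2,3)), `2` = rbind(c(1,4,5)),
              `3` = rbind(c(2,4,6)), `4` = rbind(c(3,5,6)))
  quads <- list(`12` = rbind(c(2,3,5), c(2,5,4)),
                `13` = rbind(c(1,3,6), c(1,6,4)),
                `14` = rbind(c(1,2,6), c(1,6,5)))
  for (pat in 0:15) {
    inside <- which(bitwAnd(pat, c(1L, 2L, 4L, 8L)) > 0L)
    s <- length(inside)
    key <- if (s == 1) as.character(inside)
    else if (s == 3) as.character(setdiff(1:4, inside))
    else if (s == 2) {
      pair <- if (1 %in% inside) inside else setdiff(1:4, inside)
      paste0(pair, collapse = "")
    } else NA
    tab[[pat + 1]] <-
      if (s %in% c(0, 4)) NULL
      else if (s %in% c(1, 3)) one[[key]]
      else quads[[key]]
  }
  tab
})

#' Triangulated multi-tag boundary surface
#'
#' @param vertices n x 3 matrix of world coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param face_labels m x 2 integer matrix of (inner tag, outer tag) per face;
#'   outer tag 0 denotes background.
#' @param meta optional list recording the source grid (origin, spacing, dims).
#' @return an object of class \code{tagged_surface}.
#' @export
tagged_surface <- function(vertices, faces, face_labels, meta = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  face_labels <- matrix(as.integer(face_labels), ncol = 2)
  stopifnot(nrow(faces) == nrow(face_labels))
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 face_labels = face_labels, meta = meta),
            class = "tagged_surface")
}

#' @export
print.tagged_surface <- function(x, ...) {
  cat(sprintf("tagged_surface: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  key <- paste0("(", x$face_labels[, 1], ",", x$face_labels[, 2], ")")
  tab <- table(key)
  for (k in names(tab))
    cat(sprintf("  faces %s: %d\n", k, tab[[k]]))
  invisible(x)
}

#' Extract the boundary surface of one tag
#'
#' Applies marching cubes (tetrahedral-decomposition variant) at isovalue 0.5
#' to the binary mask of \code{tag}; the binary indicator is sampled at voxel
#' centers and padded with background, so every connected component yields a
#' closed, consistently outward-oriented surface. Faces are provisionally
#' labelled \code{(tag, 0)}. \code{mode = "blocky"} instead emits the exact
#' voxel-face surface (each square boundary face split into two triangles),
#' whose enclosed volume equals the voxel count times the voxel volume.
#'
#' @param image a \code{label_image}.
#' @param tag integer label or region name.
#' @param mode \code{"marching"} (default) or \code{"blocky"}.
#' @return a \code{tagged_surface}.
#' @export
extract_tag_surface <- function(image, tag, mode = c("marching", "blocky")) {
  mode <- match.arg(mode)
  tag <- resolve_tags(image, tag)
  stopifnot(length(tag) == 1L)
  mask <- image$voxels == tag
  if (!any(mask)) stop("empty mask: tag not present in image")
  meta <- list(origin = image$origin, spacing = image$spacing,
               dims = dim(image$voxels), tags = image$tags)
  if (mode == "blocky") extract_blocky(mask, image, tag, meta)
  else extract_marching(mask, image, tag, meta)
}

extract_marching <- function(mask, image, tag, meta) {
  d <- dim(mask)
  pd <- d + 2L
  S <- array(0L, dim = pd)
  S[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask * 1L
  np1 <- pd[1]; np12 <- pd[1] * pd[2]

  # active cells: mixed 8-corner sums
  cs <- S[1:(pd[1]-1), , ] + S[2:pd[1], , ]
  cs <- cs[, 1:(pd[2]-1), ] + cs[, 2:pd[2], ]
  cs <- cs[, , 1:(pd[3]-1)] + cs[, , 2:pd[3]]
  act <- which(cs > 0L & cs < 8L)
  if (!length(act)) stop("empty mask")
  cd <- pd - 1L
  ci <- (act - 1L) %% cd[1]
  cj <- ((act - 1L) %/% cd[1]) %% cd[2]
  ck <- (act - 1L) %/% (cd[1] * cd[2])
  base_id <- ci + cj * np1 + ck * np12 + 1L  # 1-based padded sample id

  offs <- kuhn_tet_offsets()
  sv <- as.vector(S)
  tri_v1 <- tri_v2 <- tri_v3 <- list()  # edge keys per triangle corner
  tri_ins <- tri_out <- list()          # inside/outside centroids ids
  nt <- 0L
  for (tt in seq_along(offs)) {
    off <- offs[[tt]]
    ids <- cbind(base_id + off[1,1] + off[1,2]*np1 + off[1,3]*np12,
                 base_id + off[2,1] + off[2,2]*np1 + off[2,3]*np12,
                 base_id + off[3,1] + off[3,2]*np1 + off[3,3]*np12,
                 base_id + off[4,1] + off[4,2]*np1 + off[4,3]*np12)
    vals <- matrix(sv[ids], ncol = 4)
    pat <- vals[, 1] + 2L*vals[, 2] + 4L*vals[, 3] + 8L*vals[, 4]
    for (p in 1:14) {
      tris <- tet_case_table[[p + 1]]
      if (is.null(tris)) next
      rows <- which(pat == p)
      if (!length(rows)) next
      idr <- ids[rows, , drop = FALSE]
      valr <- vals[rows, , drop = FALSE]
      nin <- rowSums(valr)
      # centroid sample ids for orientation: mean position of inside vs
      # outside corners (store the corner id matrices + inside mask)
      for (r in seq_len(nrow(tris))) {
        e <- tris[r, ]
        ep <- tet_edge_pairs[e, , drop = FALSE]
        a <- cbind(idr[, ep[1, 1]], idr[, ep[1, 2]])
        b <- cbind(idr[, ep[2, 1]], idr[, ep[2, 2]])
        cc <- cbind(idr[, ep[3, 1]], idr[, ep[3, 2]])
        nt <- nt + 1L
        tri_v1[[nt]] <- a; tri_v2[[nt]] <- b; tri_v3[[nt]] <- cc
        ins <- idr; ins[valr == 0L] <- NA_integer_
        out <- idr; out[valr == 1L] <- NA_integer_
        tri_ins[[nt]] <- ins
        tri_out[[nt]] <- out
      }
    }
  }
  A <- do.call(rbind, tri_v1); B <- do.call(rbind, tri_v2)
  C <- do.call(rbind, tri_v3)
  INS <- do.call(rbind, tri_ins); OUT <- do.call(rbind, tri_out)

  pos_of <- function(id) {
    i <- (id - 1L) %% np1
    j <- ((id - 1L) %/% np1) %% pd[2]
    k <- (id - 1L) %/% np12
    cbind(image$origin[1] + (i - 0.5) * image$spacing[1],
          image$origin[2] + (j - 0.5) * image$spacing[2],
          image$origin[3] + (k - 0.5) * image$spacing[3])
  }
  edge_key <- function(pair) {
    lo <- pmin(pair[, 1], pair[, 2]); hi <- pmax(pair[, 1], pair[, 2])
    (lo - 1) * prod(pd) + hi
  }
  keys <- c(edge_key(A), edge_key(B), edge_key(C))
  uk <- sort(unique(keys))
  idx <- matrix(match(keys, uk), ncol = 3)
  lo <- (uk - 1) %/% prod(pd) + 1; hi <- uk - (lo - 1) * prod(pd)
  verts <- 0.5 * (pos_of(lo) + pos_of(hi))

  # orientation: normal must point from inside-corner centroid to outside
  cin <- matrix(0, nrow(A), 3); cout <- matrix(0, nrow(A), 3)
  nin <- rowSums(!is.na(INS))
  for (cc in 1:4) {
    pi_ <- pos_of(ifelse(is.na(INS[, cc]), 1L, INS[, cc]))
    pi_[is.na(INS[, cc]), ] <- 0
    cin <- cin + pi_
    po_ <- pos_of(ifelse(is.na(OUT[, cc]), 1L, OUT[, cc]))
    po_[is.na(OUT[, cc]), ] <- 0
    cout <- cout + po_
  }
  cin <- cin / nin; cout <- cout / (4 - nin)
  va <- verts[idx[, 1], , drop = FALSE]
  vb <- verts[idx[, 2], , drop = FALSE]
  vc <- verts[idx[, 3], , drop = FALSE]
  nrm <- cross_rows(vb - va, vc - va)
  flip <- rowSums(nrm * (cout - cin)) < 0
  idx[flip, c(2, 3)] <- idx[flip, c(3, 2)]

  tagged_surface(verts, idx,
                 cbind(rep(tag, nrow(idx)), rep(0L, nrow(idx))), meta)
}

extract_blocky <- function(mask, image, tag, meta) {
  d <- dim(mask)
  sp <- image$spacing; or <- image$origin
  P <- array(FALSE, dim = d + 2L)
  P[2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1)] <- mask
  nfv <- (d[1] + 1) * (d[2] + 1) * (d[3] + 1)
  corner_id <- function(i, j, k) i + j * (d[1] + 1L) + k * (d[1] + 1L) * (d[2] + 1L) + 1L
  quads <- list()
  qn <- 0L
  # for each axis and direction, boundary faces where mask & !neighbor
  dirs <- rbind(c(1,1), c(1,-1), c(2,1), c(2,-1), c(3,1), c(3,-1))
  inner <- function(arr) arr[2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1)]
  for (r in seq_len(nrow(dirs))) {
    ax <- dirs[r, 1]; sg <- dirs[r, 2]
    idx <- list(2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1))
    idx[[ax]] <- idx[[ax]] + sg
    nbr <- P[idx[[1]], idx[[2]], idx[[3]]]
    hit <- which(inner(P) & !nbr)
    if (!length(hit)) next
    i <- (hit - 1L) %% d[1]; j <- ((hit - 1L) %/% d[1]) %% d[2]
    k <- (hit - 1L) %/% (d[1] * d[2])
    v <- cbind(i, j, k)
    v[, ax] <- v[, ax] + (sg + 1L) / 2L
    # the 4 corners of the voxel face, ordered so the normal points along sg*ax
    o1 <- (ax %% 3L) + 1L; o2 <- (o1 %% 3L) + 1L
    mk <- function(d1, d2) {
      w <- v; w[, o1] <- w[, o1] + d1; w[, o2] <- w[, o2] + d2
      corner_id(w[, 1], w[, 2], w[, 3])
    }
    c00 <- mk(0L, 0L); c10 <- mk(1L, 0L); c11 <- mk(1L, 1L); c01 <- mk(0L, 1L)
    if (sg > 0) q <- cbind(c00, c10, c11, c01) else q <- cbind(c00, c01, c11, c10)
    qn <- qn + 1L
    quads[[qn]] <- q
  }
  Q <- do.call(rbind, quads)
  used <- sort(unique(as.vector(Q)))
  remap <- match(Q, used)
  dim(remap) <- dim(Q)
  ui <- (used - 1L) %% (d[1] + 1L)
  uj <- ((used - 1L) %/% (d[1] + 1L)) %% (d[2] + 1L)
  uk2 <- (used - 1L) %/% ((d[1] + 1L) * (d[2] + 1L))
  verts <- cbind(or[1] + ui * sp[1], or[2] + uj * sp[2], or[3] + uk2 * sp[3])
  faces <- rbind(remap[, c(1, 2, 3)], remap[, c(1, 3, 4)])
  tagged_surface(verts, faces,
                 cbind(rep(tag, nrow(faces)), rep(0L, nrow(faces))), meta)
}

#' Combine per-tag surfaces, removing redundant interfaces
#'
#' Vertices coincident within \code{tol} are merged; faces with identical
#' vertex sets extracted from two different tags (the duplicated interface)
#' are collapsed to a single face labelled \code{(tag_a, tag_b)}, keeping the
#' orientation of the lower-tag copy so that normals point from inner to
#' outer tag.
#'
#' @param surfaces list of \code{tagged_surface} extracted from the same image.
#' @param image optional source \code{label_image} (metadata cross-check).
#' @param tol vertex coincidence tolerance in mm.
#' @return a merged \code{tagged_surface}.
#' @export
merge_tag_surfaces <- function(surfaces, image = NULL, tol = 1e-6) {
  if (inherits(surfaces, "tagged_surface")) surfaces <- list(surfaces)
  stopifnot(length(surfaces) >= 1L)
  V <- do.call(rbind, lapply(surfaces, `[[`, "vertices"))
  offs <- cumsum(c(0L, vapply(surfaces, function(s) nrow(s$vertices), 1L)))
  F_ <- do.call(rbind, lapply(seq_along(surfaces), function(i)
    surfaces[[i]]$faces + offs[i]))
  L <- do.call(rbind, lapply(surfaces, `[[`, "face_labels"))

  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  uk <- !duplicated(key)
  vmap <- match(key, key[uk])
  verts <- V[uk, , drop = FALSE]
  faces <- matrix(vmap[F_], ncol = 3)
  if (length(surfaces) > 1L && nrow(verts) == nrow(V) && nrow(V) > 0)
    warning("no coincident vertices between surfaces; incompatible grids?")

  lo3 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid3 <- faces[, 1] + faces[, 2] + faces[, 3] - lo3 - hi3
  fkey <- paste(lo3, mid3, hi3)
  first <- match(fkey, fkey)
  dup <- which(first != seq_along(fkey))
  if (length(dup)) {
    keep <- first[dup]
    if (any(table(first) > 2L)) stop("more than two tags share a face")
    ka <- L[keep, 1]; kb <- L[dup, 1]
    swap <- kb < ka
    # keep orientation of the lower tag's copy
    faces[keep[swap], ] <- faces[dup[swap], ]
    inner <- pmin(ka, kb); outer <- pmax(ka, kb)
    L[keep, 1] <- inner; L[keep, 2] <- outer
    faces <- faces[-dup, , drop = FALSE]
    L <- L[-dup, , drop = FALSE]
  }
  meta <- surfaces[[1]]$meta
  if (!is.null(image))
    meta <- list(origin = image$origin, spacing = image$spacing,
                 dims = dim(image$voxels), tags = image$tags)
  tagged_surface(verts, faces, L, meta)
}

#' Extract and merge the surfaces of all (or selected) tags of an image
#'
#' Convenience wrapper: per-tag extraction followed by
#' \code{\link{merge_tag_surfaces}}.
#'
#' @param image a \code{label_image}.
#' @param tags labels to extract (default: all labels in the tag table).
#' @param mode extraction mode, see \code{\link{extract_tag_surface}}.
#' @return a merged \code{tagged_surface}.
#' @export
extract_surfaces <- function(image, tags = NULL, mode = "marching") {
  if (is.null(tags)) tags <- as.integer(names(image$tags))
  tags <- resolve_tags(image, tags)
  tags <- tags[vapply(tags, function(t) any(image$voxels == t), TRUE)]
  if (!length(tags)) stop("empty mask: no requested tag present")
  merge_tag_surfaces(lapply(tags, function(t)
    extract_tag_surface(image, t, mode = mode)), image = image)
}

# --- surface measures & checks -------------------------------------------

# The closed, outward-oriented surface of one tag from a merged surface:
# faces with inner == tag as stored, faces with outer == tag reversed.
tag_closed_surface <- function(surface, tag) {
  f1 <- surface$faces[surface$face_labels[, 1] == tag, , drop = FALSE]
  f2 <- surface$faces[surface$face_labels[, 2] == tag, c(1, 3, 2),
                      drop = FALSE]
  rbind(f1, f2)
}

#' Surface area and enclosed volume
#'
#' Area is the triangle-area sum; volume uses the divergence theorem on the
#' outward-oriented closed surface of \code{tag} (all faces if \code{tag} is
#' \code{NULL} and the surface is single-tag).
#'
#' @param surface a \code{tagged_surface}.
#' @param tag tag whose closed surface to measure; default: first inner tag.
#' @return list with \code{area} (mm^2) and \code{volume} (mm^3, signed).
#' @export
surface_measures <- function(surface, tag = NULL) {
  if (is.null(tag)) tag <- surface$face_labels[1, 1]
  f <- tag_closed_surface(surface, tag)
  a <- surface$vertices[f[, 1], , drop = FALSE]
  b <- surface$vertices[f[, 2], , drop = FALSE]
  cc <- surface$vertices[f[, 3], , drop = FALSE]
  cr <- cross_rows(b - a, cc - a)
  area <- sum(row_norms(cr)) / 2
  volume <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
                a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
                a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  list(area = area, volume = volume)
}

#' Check that a tag's surface is closed (and optionally 2-manifold)
#'
#' Closedness is the parity-defining property: every directed edge of the
#' tag's outward-oriented surface must be matched by the opposite directed
#' edge the same number of times (the surface bounds a volume). With
#' \code{manifold = TRUE} the stricter invariant is enforced: every edge
#' shared by exactly two faces. Degenerate faces (area below \code{1e-12}
#' mm^2) are rejected in both modes. Voxel-face ("blocky") surfaces of masks
#' with edge-contact configurations are closed but not manifold.
#'
#' @param surface a \code{tagged_surface}.
#' @param tag tag to check (default: every inner tag present).
#' @param manifold require the exactly-two-faces-per-edge property.
#' @param allow_degenerate tolerate zero-area faces (constrained smoothing
#'   may collapse adjacent vertices; such faces are parity-neutral).
#' @return \code{TRUE} invisibly; stops with a diagnostic otherwise.
#' @export
check_surface_closed <- function(surface, tag = NULL, manifold = FALSE,
                                 allow_degenerate = FALSE) {
  tags <- if (is.null(tag)) unique(surface$face_labels[, 1]) else tag
  for (t in tags) {
    f <- tag_closed_surface(surface, t)
    a <- surface$vertices[f[, 1], , drop = FALSE]
    b <- surface$vertices[f[, 2], , drop = FALSE]
    cc <- surface$vertices[f[, 3], , drop = FALSE]
    ar <- row_norms(cross_rows(b - a, cc - a)) / 2
    if (!allow_degenerate && any(ar < 1e-12))
      stop(sprintf("degenerate face(s) for tag %d", t))
    he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed edges
    k1 <- paste(he[, 1], he[, 2])
    k2 <- paste(he[, 2], he[, 1])
    t1 <- table(k1)
    t2 <- table(k2)[names(t1)]
    if (any(is.na(t2)) || any(t1 != t2))
      stop(sprintf("tag %d: surface is not closed", t))
    if (manifold && any(duplicated(k1)))
      stop(sprintf("tag %d: duplicated directed edge (non-manifold)", t))
  }
  invisible(TRUE)
}

# Euler characteristic V - E + F of a face set.
euler_characteristic <- function(faces) {
  v <- length(unique(as.vector(faces)))
  e <- unique(paste(pmin(faces[, 1], faces[, 2]), pmax(faces[, 1], faces[, 2])))
  e <- length(unique(c(e,
        paste(pmin(faces[, 2], faces[, 3]), pmax(faces[, 2], faces[, 3])),
        paste(pmin(faces[, 3], faces[, 1]), pmax(faces[, 3], faces[, 1])))))
  v - e + nrow(faces)
}
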