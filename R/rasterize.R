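#' Render a tagged surface into a label image at arbitrary resolution
#'
#' Each target voxel center is classified against every tag's closed surface
#' by parity of ray crossings along +x (with a deterministic sub-voxel ray
#' offset that rules out degenerate edge/vertex hits). A voxel inside exactly
#' one tag receives that tag; inside none, background; inside several
#' (possible only through numerical overlap of smoothed surfaces), the tag
#' whose surface is nearest wins, ties going to the lowest label.
#'
#' @param surface a merged \code{tagged_surface} with closed per-tag surfaces.
#' @param target_spacing target voxel spacing in mm (scalar or length 3).
#' @param bounds optional list(lower, upper) world-space box; defaults to the
#'   source image bounds (from the surface metadata) padded by one target
#'   voxel.
#' @return a \code{label_image}; the tag table is copied from the surface
#'   metadata.
#' @export
rasterize_surfaces <- function(surface, target_spacing, bounds = NULL) {
  stopifnot(inherits(surface, "tagged_surface"))
  sp <- rep_len(as.numeric(target_spacing), 3L)
  stopifnot(all(sp > 0))
  if (is.null(bounds)) {
    if (is.null(surface$meta$origin))
      stop("no bounds given and no source-image metadata on surface")
    lower <- surface$meta$origin - sp
    upper <- surface$meta$origin + surface$meta$dims * surface$meta$spacing + sp
    bounds <- list(lower = lower, upper = upper)
  }
  ext <- bounds$upper - bounds$lower
  if (any(ext <= 0)) stop("degenerate bounds")
  dims <- pmax(as.integer(ceiling(ext / sp - 1e-9)), 1L)
  origin <- bounds$lower

  tags <- sort(unique(surface$face_labels[, 1]))
  tags <- unique(c(tags, surface$face_labels[surface$face_labels[, 2] != 0L, 2]))
  tags <- sort(tags[tags != 0L])
  check_surface_closed(surface, allow_degenerate = TRUE)

  nvox <- prod(dims)
  count <- integer(nvox)
  lab <- integer(nvox)
  inside_list <- vector("list", length(tags))
  for (s in seq_along(tags)) {
    f <- tag_closed_surface(surface, tags[s])
    ins <- cpp_classify_parity(surface$vertices, f,
                               origin[1], sp[1], dims[1],
                               origin[2], sp[2], dims[2],
                               origin[3], sp[3], dims[3])
    inside_list[[s]] <- ins
    count <- count + ins
    lab[ins == 1L & count == 1L] <- tags[s]
  }
  conflict <- which(count > 1L)
  if (length(conflict)) {
    pts <- voxel_index_to_world(conflict, origin, sp, dims)
    best <- rep(Inf, length(conflict))
    for (s in seq_along(tags)) {
      hit <- inside_list[[s]][conflict] == 1L
      if (!any(hit)) next
      f <- tag_closed_surface(surface, tags[s])
      dd <- point_surface_distance(pts[hit, , drop = FALSE],
                                   surface$vertices, f)
      upd <- which(hit)[dd < best[hit] - 1e-12]
      lab[conflict[upd]] <- tags[s]  # tags ascending: ties keep lowest label
      best[hit] <- pmin(best[hit], dd)
    }
  }
  tt <- surface$meta$tags
  if (!is.null(tt)) tt <- tt[names(tt) %in% as.character(tags)]
  label_image(array(lab, dim = dims), spacing = sp, origin = origin,
              tags = tt)
}

voxel_index_to_world <- function(idx, origin, sp, dims) {
  i <- (idx - 1L) %% dims[1]
  j <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k <- (idx - 1L) %/% (dims[1] * dims[2])
  cbind(origin[1] + (i + 0.5) * sp[1],
        origin[2] + (j + 0.5) * sp[2],
        origin[3] + (k + 0.5) * sp[3])
}

# Minimum unsigned distance from each point to a triangle soup (exact
# point-triangle distance; brute force, intended for small point sets).
point_surface_distance <- function(points, V, F_) {
  points <- matrix(points, ncol = 3)
  out <- rep(Inf, nrow(points))
  a <- V[F_[, 1], , drop = FALSE]
  b <- V[F_[, 2], , drop = FALSE]
  cc <- V[F_[, 3], , drop = FALSE]
  for (p in seq_len(nrow(points))) {
    out[p] <- sqrt(min(point_tri_dist2(points[p, ], a, b, cc)))
  }
  out
}

point_tri_dist2 <- function(p, a, b, cc) {
  # Ericson-style closest point on triangle, vectorized over triangles.
  ab <- b - a; ac <- cc - a
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-cc, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- pmax(va + vb + vc, 1e-300)
  v <- vb / denom; w <- vc / denom
  # start from interior projection, then clamp to edges/vertices
  v1 <- pmin(pmax(v, 0), 1); w1 <- pmin(pmax(w, 0), 1 - v1)
  q <- a + v1 * ab + w1 * ac
  # vertex regions
  q[d1 <= 0 & d2 <= 0, ] <- a[d1 <= 0 & d2 <= 0, ]
  reg_b <- d3 >= 0 & d4 <= d3
  q[reg_b, ] <- b[reg_b, ]
  reg_c <- d6 >= 0 & d5 <= d6
  q[reg_c, ] <- cc[reg_c, ]
  # edge AB
  reg_ab <- vc <= 0 & d1 >= 0 & d3 <= 0
  tab <- d1 / pmax(d1 - d3, 1e-300)
  q[reg_ab, ] <- (a + tab * ab)[reg_ab, ]
  # edge AC
  reg_ac <- vb <= 0 & d2 >= 0 & d6 <= 0
  tac <- d2 / pmax(d2 - d6, 1e-300)
  q[reg_ac, ] <- (a + tac * ac)[reg_ac, ]
  # edge BC
  reg_bc <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  tbc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
  q[reg_bc, ] <- (b + tbc * (cc - b))[reg_bc, ]
  rowSums(sweep(q, 2, p)^2)
}

#' 6-connected components of a tag's voxel set
#'
#' @param image a \code{label_image}.
#' @param tags labels or region names defining the foreground.
#' @return list with \code{labels} (integer array) and \code{n} components.
#' @export
connected_components <- function(image, tags) {
  mask <- binary_mask(image, tags)$voxels
  d <- dim(mask)
  lab <- cpp_label_components(as.vector(mask), d[1], d[2], d[3])
  list(labels = array(lab, dim = d), n = attr(lab, "ncomp"))
}
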