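# Idealized boundary-fitted geometries for verification of the Laplace
# solver and the fiber rule (closed-form harmonic coordinates exist on both).

#' Structured tetrahedral mesh of a thick-walled cylindrical annulus
#'
#' Boundary-fitted idealized LV-annulus geometry: nodes on a cylindrical
#' lattice, hexahedral cells split into 6 Kuhn tetrahedra (conforming,
#' including across the angular seam). The transmural harmonic coordinate on
#' this geometry has the closed form \eqn{\ln(r/r_1)/\ln(r_2/r_1)}.
#'
#' @param r_inner,r_outer wall radii (mm).
#' @param height extent along z (mm), base at \code{z = height}.
#' @param nr,ntheta,nz number of element layers radially, angularly, axially.
#' @return a \code{tet_mesh} with all elements tagged 1; attribute
#'   \code{"annulus"} records the construction parameters.
#' @export
annulus_mesh <- function(r_inner = 10, r_outer = 16, height = 12,
                         nr = 6, ntheta = 48, nz = 12) {
  stopifnot(r_outer > r_inner, r_inner > 0, nr >= 1, ntheta >= 3, nz >= 1)
  rs <- seq(r_inner, r_outer, length.out = nr + 1)
  ths <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  zs <- seq(0, height, length.out = nz + 1)
  # node id for lattice (ir, ith, iz), 0-based, theta periodic
  nid <- function(ir, ith, iz)
    ir + (ith %% ntheta) * (nr + 1L) + iz * (nr + 1L) * ntheta + 1L
  grid <- expand.grid(ir = 0:nr, ith = 0:(ntheta - 1), iz = 0:nz)
  nodes <- cbind(rs[grid$ir + 1] * cos(ths[grid$ith + 1]),
                 rs[grid$ir + 1] * sin(ths[grid$ith + 1]),
                 zs[grid$iz + 1])
  cells <- expand.grid(ir = 0:(nr - 1), ith = 0:(ntheta - 1),
                       iz = 0:(nz - 1))
  offs <- kuhn_tet_offsets()
  tets <- matrix(0L, nrow = 6L * nrow(cells), ncol = 4L)
  for (tt in seq_along(offs)) {
    off <- offs[[tt]]
    rows <- seq.int(tt, by = 6L, length.out = nrow(cells))
    for (cpos in 1:4)
      tets[rows, cpos] <- nid(cells$ir + off[cpos, 1],
                              cells$ith + off[cpos, 2],
                              cells$iz + off[cpos, 3])
  }
  mesh <- tet_mesh(nodes, tets, rep(1L, nrow(tets)),
                   tags = c("1" = "LV_myo"))
  vol <- tet_volumes(mesh)
  if (any(vol <= 0)) stop("degenerate annulus resolution (inverted elements)")
  attr(mesh, "annulus") <- list(r_inner = r_inner, r_outer = r_outer,
                                height = height, nr = nr, ntheta = ntheta,
                                nz = nz)
  mesh
}

#' Boundary face sets of an annulus mesh for fiber assignment
#'
#' Derives \code{lv_endo} (inner wall), \code{epi} (outer wall), \code{base}
#' (top, z = height) and \code{apex} (all bottom-rim nodes, giving a clean
#' axial apicobasal field) from an \code{\link{annulus_mesh}}.
#'
#' @param mesh an \code{\link{annulus_mesh}} result.
#' @return named list of \code{face_set}s / node sets as accepted by
#'   \code{\link{assign_fibers}}.
#' @export
annulus_surfaces <- function(mesh) {
  an <- attr(mesh, "annulus")
  if (is.null(an)) stop("not an annulus_mesh")
  g <- tag_boundary(mesh, 1L)
  rad <- matrix(sqrt(mesh$nodes[g$faces, 1]^2 + mesh$nodes[g$faces, 2]^2),
                ncol = 3)
  zc <- matrix(mesh$nodes[g$faces, 3], ncol = 3)
  rmid <- (an$r_inner + an$r_outer) / 2
  side <- !(rowSums(zc < 1e-9) == 3L) &
    !(rowSums(abs(zc - an$height) < 1e-9) == 3L)
  inner <- face_set(g$faces[rowSums(rad < rmid) == 3L & side, , drop = FALSE],
                    mesh, "lv_endo")
  outer <- face_set(g$faces[rowSums(rad > rmid) == 3L & side, , drop = FALSE],
                    mesh, "epi")
  top <- face_set(g$faces[rowSums(abs(zc - an$height) < 1e-9) == 3L, ,
                          drop = FALSE], mesh, "base")
  bot_nodes <- which(abs(mesh$nodes[, 3]) < 1e-9)
  list(lv_endo = inner, rv_endo = face_set(matrix(0L, 0, 3), mesh, "rv_endo"),
       epi = outer, base = top, apex = bot_nodes)
}

#' Voxelized spherical annulus (concentric shell) label image
#'
#' Verification geometry for the Laplace solver: the harmonic field between
#' concentric spheres has the closed form
#' \eqn{u(r) = (1/r_1 - 1/r)/(1/r_1 - 1/r_2)}.
#'
#' @param r_inner,r_outer shell radii (mm).
#' @param spacing voxel spacing (mm).
#' @return a \code{label_image} with the shell tagged 1.
#' @export
spherical_shell_image <- function(r_inner = 10, r_outer = 15, spacing = 1) {
  ext <- r_outer + 2 * spacing
  n <- ceiling(2 * ext / spacing)
  xs <- (-n / 2 + seq_len(n) - 0.5) * spacing
  X <- array(rep(xs, n * n), dim = c(n, n, n))
  Y <- array(rep(rep(xs, each = n), n), dim = c(n, n, n))
  Z <- array(rep(xs, each = n * n), dim = c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  arr <- array(0L, dim = c(n, n, n))
  arr[r >= r_inner & r < r_outer] <- 1L
  label_image(arr, spacing = spacing, origin = rep(-n / 2 * spacing, 3),
              tags = c("1" = "shell"))
}
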