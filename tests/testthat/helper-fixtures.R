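# Shared fixture builders: all geometry is generated in code.

# Small, fast biventricular phantom (coarse spacing).
small_phantom_spec <- function(spacing = 2, noise = 0, seed = 1L, ...) {
  phantom_spec(spacing = spacing, noise_probability = noise, seed = seed, ...)
}

# Label image of a voxelized sphere of radius r centered at the origin.
sphere_image <- function(r = 10, spacing = 0.5, pad = 2) {
  n <- ceiling(2 * (r + pad * spacing) / spacing)
  xs <- (-n / 2 + seq_len(n) - 0.5) * spacing
  X <- array(rep(xs, n * n), dim = c(n, n, n))
  Y <- array(rep(rep(xs, each = n), n), dim = c(n, n, n))
  Z <- array(rep(xs, each = n * n), dim = c(n, n, n))
  arr <- array(0L, dim = c(n, n, n))
  arr[X^2 + Y^2 + Z^2 < r^2] <- 1L
  label_image(arr, spacing = spacing, origin = rep(-n / 2 * spacing, 3),
              tags = c("1" = "sphere"))
}

# Single foreground voxel in a 3x3x3 grid.
single_voxel_image <- function(spacing = 1) {
  arr <- array(0L, dim = c(3, 3, 3))
  arr[2, 2, 2] <- 1L
  label_image(arr, spacing = spacing)
}

# L-tromino of voxels: small closed surface with a binding optimum for the
# constrained smoothing problem.
tromino_image <- function() {
  arr <- array(0L, dim = c(4, 4, 3))
  arr[2, 2, 2] <- 1L; arr[3, 2, 2] <- 1L; arr[2, 3, 2] <- 1L
  label_image(arr, spacing = 1)
}

# Rectangular slab (all voxels foreground).
slab_mesh <- function(nx = 6, ny = 4, nz = 3, spacing = 1) {
  img <- label_image(array(1L, dim = c(nx, ny, nz)), spacing = spacing,
                     origin = c(0, 0, 0))
  mesh_from_label_image(img)
}

# Quadratic-time coincident-face enumeration between two surfaces: counts
# face pairs whose sorted vertex-coordinate triples match within tol.
count_coincident_faces <- function(sa, sb, tol = 1e-9) {
  centset <- function(s) {
    v <- s$vertices
    f <- s$faces
    cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
              v[f[, 3], , drop = FALSE]) / 3
    cen
  }
  ca <- centset(sa); cb <- centset(sb)
  hits <- 0L
  for (i in seq_len(nrow(ca))) {
    d <- abs(cb[, 1] - ca[i, 1]) + abs(cb[, 2] - ca[i, 2]) +
      abs(cb[, 3] - ca[i, 3])
    if (any(d < tol)) hits <- hits + 1L
  }
  hits
}

# Per-tag voxel volume of a label image.
tag_volume <- function(image, tag) sum(image$voxels == tag) * prod(image$spacing)
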