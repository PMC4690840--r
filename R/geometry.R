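# Vector helpers and exact point-to-ellipsoid distance.

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m, eps = 1e-300) m / pmax(row_norms(m), eps)

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Signed distance to an axis-aligned ellipsoid
#'
#' Exact (to machine precision) signed Euclidean distance from points to the
#' surface of the ellipsoid \eqn{\sum_i (x_i - c_i)^2 / a_i^2 = 1}, negative
#' inside. The foot point is found by bisection on the standard Lagrange
#' parameter; this is the evaluator backing the phantom's analytic surfaces.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param radii length-3 semi-axes (mm).
#' @param center length-3 center (mm).
#' @return numeric vector of signed distances (mm).
#' @export
ellipsoid_distance <- function(points, radii, center = c(0, 0, 0)) {
  points <- matrix(points, ncol = 3)
  p <- abs(sweep(points, 2, center))
  a2 <- radii^2
  n <- nrow(p)
  # Solve sum_i (a_i^2 p_i^2)/(t + a_i^2)^2 = 1 for t in (-min(a_i^2), inf);
  # the closest surface point is then x_i = a_i^2 p_i / (t + a_i^2).
  f <- function(t) {
    s <- numeric(length(t))
    for (i in 1:3) s <- s + (a2[i] * p[, i]^2) / (t + a2[i])^2
    s - 1
  }
  lo <- rep(-min(a2) * (1 - 1e-12), n)
  hi <- pmax(row_norms(p) * max(radii), min(a2)) + max(a2)
  # expand hi until f(hi) < 0
  for (rep in 1:60) {
    bad <- f(hi) > 0
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2 + max(a2)
  }
  for (iter in 1:200) {
    mid <- 0.5 * (lo + hi)
    pos <- f(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
    if (max(hi - lo) < 1e-14 * max(a2)) break
  }
  t <- 0.5 * (lo + hi)
  foot <- sweep(p, 2, a2, "*") / (t + matrix(a2, n, 3, byrow = TRUE))
  d <- row_norms(p - foot)
  inside <- rowSums(sweep(p^2, 2, a2, "/")) < 1
  d[inside] <- -d[inside]
  # points exactly at the center
  deg <- rowSums(p^2) == 0
  d[deg] <- -min(radii)
  d
}

# Volume of the part of an ellipsoid with z <= z0 (closed form, cap formula).
ellipsoid_volume_below <- function(radii, center_z, z0) {
  zt <- (z0 - center_z) / radii[3]
  zt <- min(max(zt, -1), 1)
  pi * radii[1] * radii[2] * radii[3] * (2 / 3 + zt - zt^3 / 3)
}
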