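#' Configuration of the rule-based fiber architecture
#'
#' Helix angle varies linearly with transmural depth d (0 endocardium, 1
#' epicardium): \eqn{\alpha(d) = \alpha_{endo}(1-d) + \alpha_{epi} d}; the
#' sheet angle \eqn{\beta(d)} interpolates analogously. The conventional
#' +60/-60 degree defaults are configuration values, not constants of the
#' method.
#'
#' @param alpha_endo,alpha_epi helix angles (degrees) at endo/epicardium.
#' @param beta_endo,beta_epi sheet angles (degrees).
#' @param interpolation LV/RV frame blending: \code{"bislerp"}
#'   (quaternion spherical-linear with sign disambiguation, default) or
#'   \code{"linear-frame"} (per-axis blend + re-orthonormalization).
#' @param gradient_smoothing number of face-neighbor averaging passes applied
#'   to the per-element field gradients before frames are built (default 2);
#'   attenuates lattice-boundary staircase jitter, 0 disables.
#' @return an object of class \code{fiber_config}.
#' @export
fiber_config <- function(alpha_endo = 60, alpha_epi = -60,
                         beta_endo = 0, beta_epi = 0,
                         interpolation = c("bislerp", "linear-frame"),
                         gradient_smoothing = 2L) {
  alpha_endo <- as.numeric(alpha_endo); alpha_epi <- as.numeric(alpha_epi)
  beta_endo <- as.numeric(beta_endo); beta_epi <- as.numeric(beta_epi)
  for (a in c(alpha_endo, alpha_epi, beta_endo, beta_epi))
    if (a <= -90 || a > 90) stop("angles must lie in (-90, 90]")
  structure(list(alpha_endo = alpha_endo, alpha_epi = alpha_epi,
                 beta_endo = beta_endo, beta_epi = beta_epi,
                 interpolation = match.arg(interpolation),
                 gradient_smoothing = as.integer(gradient_smoothing)),
            class = "fiber_config")
}

#' Assign orthotropic fiber/sheet/normal triads by the Laplace-Dirichlet rule
#'
#' Solves four Laplace-Dirichlet problems on the myocardial submesh with a
#' shared Dirichlet node set for the transmural fields: \code{phi_epi}
#' (epicardium 1, both endocardia 0), \code{phi_lv} (LV endocardium 1,
#' others 0), \code{phi_rv} (RV endocardium 1, others 0), and the apicobasal
#' field \code{psi} (apex 0, base 1; the apex condition uses a small
#' epicardial patch because a point condition has vanishing capacity in 3D).
#' Per element, an LV frame is built from \eqn{\nabla\psi} (apicobasal) and
#' the transmural candidate \eqn{\nabla(\phi_{epi}-\phi_{lv})} (the harmonic
#' contrast stays non-degenerate in the apical plug and the opposite free
#' wall), the RV frame analogously; the apicobasal direction is
#' orthonormalized against the transmural one and the circumferential axis
#' completes the right-handed (circumferential, apicobasal, transmural)
#' frame. Degenerate element gradients (elements with all nodes on one
#' Dirichlet surface) are repaired from face neighbors, and a configurable
#' number of neighbor-averaging passes damps lattice-boundary jitter. Each
#' frame is rotated about its transmural axis by the helix angle
#' \eqn{\alpha(d)} (and the sheet axes about the fiber by \eqn{\beta(d)}),
#' with d the element's transmural coordinate \code{phi_epi}; LV- and
#' RV-derived frames are then blended with the relative transmural weight
#' \eqn{w = \phi_{rv}/(\phi_{lv}+\phi_{rv})}.
#'
#' @param mesh the full \code{tet_mesh}.
#' @param surfaces output of \code{\link{derive_bc_surfaces}} (an
#'   \code{apex} entry may be an integer node vector to override the single
#'   apex node).
#' @param config a \code{\link{fiber_config}}.
#' @param myo_tags element tags treated as myocardium (default: the
#'   \code{LV_myo}/\code{RV_myo} labels from the mesh tag table).
#' @return an object of class \code{fiber_field}: per-element unit triads
#'   \code{f} (fiber), \code{s} (sheet), \code{n} (sheet normal) as m x 3
#'   matrices, with \code{det[f s n] = +1} on myocardial elements and zero
#'   rows (flagged by the logical \code{myocardial} element) elsewhere.
#'   Attributes \code{d} (transmural coordinate) and \code{frame}
#'   (unrotated axes) support diagnostics.
#' @export
assign_fibers <- function(mesh, surfaces, config = fiber_config(),
                          myo_tags = NULL) {
  if (is.null(myo_tags)) {
    r <- roles_from_tags(mesh$tags)
    myo_tags <- c(r$lv_myo, r$rv_myo)
  }
  myo_tags <- as.integer(myo_tags)
  sub <- submesh(mesh, myo_tags)
  nmap <- attr(sub, "node_map")
  to_sub <- integer(nrow(mesh$nodes))
  to_sub[nmap] <- seq_along(nmap)
  remap_nodes <- function(nodes) {
    s <- to_sub[nodes]
    s[s > 0L]
  }
  lv_nodes <- remap_nodes(face_set_nodes(surfaces$lv_endo))
  rv_nodes <- if (length(surfaces$rv_endo))
    remap_nodes(face_set_nodes(surfaces$rv_endo)) else integer(0)
  epi_nodes <- remap_nodes(face_set_nodes(surfaces$epi))
  base_nodes <- remap_nodes(face_set_nodes(surfaces$base))
  apex <- if (!is.null(surfaces$apex)) surfaces$apex
  else if (!is.null(surfaces$apex_region)) surfaces$apex_region
  else surfaces$apex_node
  apex_nodes <- remap_nodes(as.integer(apex))
  if (!length(lv_nodes) || !length(epi_nodes) || !length(base_nodes) ||
      !length(apex_nodes))
    stop("boundary surfaces do not touch the myocardial submesh")
  # shared Dirichlet set: transmural problems differ only in values
  endo_nodes <- setdiff(union(lv_nodes, rv_nodes), epi_nodes)
  lv_only <- setdiff(lv_nodes, union(rv_nodes, epi_nodes))
  rv_only <- setdiff(rv_nodes, union(lv_nodes, epi_nodes))

  geo <- p1_gradients(sub)
  K <- assemble_stiffness(sub, geo)
  phi_epi <- solve_laplace(sub, list(list(epi_nodes, value = 1),
                                     list(endo_nodes, value = 0)),
                           stiffness = K)
  phi_lv <- solve_laplace(sub, list(list(lv_only, value = 1),
                                    list(setdiff(union(rv_only, epi_nodes),
                                                 lv_only), value = 0)),
                          stiffness = K)
  phi_rv <- if (length(rv_only))
    solve_laplace(sub, list(list(rv_only, value = 1),
                            list(setdiff(union(lv_only, epi_nodes),
                                         rv_only), value = 0)),
                  stiffness = K)
  else NULL
  psi <- solve_laplace(sub, list(list(setdiff(base_nodes, apex_nodes),
                                      value = 1),
                                 list(apex_nodes, value = 0)),
                       stiffness = K)

  m <- nrow(sub$tets)
  d <- pmin(pmax(element_means(sub, phi_epi$values), 0), 1)
  adj <- element_adjacency(sub)
  g_psi <- smooth_element_gradients(repair_degenerate_gradients(
    element_gradients(sub, psi$values, geo), adj), adj,
    config$gradient_smoothing)
  # transmural candidate: gradient of the harmonic contrast phi_epi - phi_lv
  # (+1 on epicardium, -1 on LV endocardium); unlike -grad(phi_lv) alone it
  # stays non-degenerate in the apical plug and the RV free wall
  g_lv <- smooth_element_gradients(repair_degenerate_gradients(
    element_gradients(sub, phi_epi$values - phi_lv$values, geo), adj), adj,
    config$gradient_smoothing)
  alpha <- (config$alpha_endo * (1 - d) + config$alpha_epi * d) * pi / 180
  beta <- (config$beta_endo * (1 - d) + config$beta_epi * d) * pi / 180

  Q_lv <- build_frame(g_psi, g_lv, alpha, beta)
  if (!is.null(phi_rv)) {
    g_rv <- smooth_element_gradients(repair_degenerate_gradients(
      element_gradients(sub, phi_epi$values - phi_rv$values, geo), adj), adj,
      config$gradient_smoothing)
    Q_rv <- build_frame(g_psi, g_rv, alpha, beta)
    wl <- element_means(sub, phi_lv$values)
    wr <- element_means(sub, phi_rv$values)
    s_ <- wl + wr
    w <- ifelse(s_ < 1e-8, 0.5, wr / pmax(s_, 1e-300))
    w <- pmin(pmax(w, 0), 1)
    Q <- if (config$interpolation == "bislerp")
      blend_frames_slerp(Q_lv, Q_rv, w) else blend_frames_linear(Q_lv, Q_rv, w)
  } else {
    Q <- Q_lv
  }

  emap <- attr(sub, "elem_map")
  M <- nrow(mesh$tets)
  zero <- matrix(0, M, 3)
  f <- s <- n_ <- zero
  f[emap, ] <- Q$f; s[emap, ] <- Q$s; n_[emap, ] <- Q$n
  myocardial <- logical(M)
  myocardial[emap] <- TRUE
  dfull <- rep(NA_real_, M)
  dfull[emap] <- d
  structure(list(f = f, s = s, n = n_, myocardial = myocardial),
            class = "fiber_field",
            d = dfull,
            frame = list(e_c = Q$e_c, e_l = Q$e_l, e_t = Q$e_t,
                         elem_map = emap),
            fields = list(phi_epi = phi_epi, phi_lv = phi_lv,
                          phi_rv = phi_rv, psi = psi))
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf("fiber_field: %d elements (%d myocardial)\n",
              nrow(x$f), sum(x$myocardial)))
  invisible(x)
}

# Face-adjacency element pairs (e1, e2) of a tet mesh.
element_adjacency <- function(mesh) {
  cf <- faces_of_tets(mesh$tets)
  owner <- rep(seq_len(nrow(mesh$tets)), times = 4)
  o <- order(cf[, 1], cf[, 2], cf[, 3])
  s <- cf[o, , drop = FALSE]
  own <- owner[o]
  same <- rowSums(s[-1, , drop = FALSE] == s[-nrow(s), , drop = FALSE]) == 3L
  cbind(own[c(same, FALSE)], own[c(FALSE, same)])
}

# Boundary tetrahedra can have all four nodes on one Dirichlet surface, where
# any harmonic field is constant and its element gradient exactly zero.
# Replace such degenerate gradients by the mean of face-adjacent element
# gradients (a local repair; all other elements keep their own gradient).
repair_degenerate_gradients <- function(g, adj, tol_rel = 1e-6) {
  n <- nrow(g)
  A <- Matrix::sparseMatrix(i = c(adj[, 1], adj[, 2]),
                            j = c(adj[, 2], adj[, 1]), x = 1,
                            dims = c(n, n))
  deg <- pmax(Matrix::rowSums(A), 1)
  nrm <- row_norms(g)
  tol <- tol_rel * stats::median(nrm)
  for (it in 1:10) {
    bad <- nrm < tol
    if (!any(bad)) break
    gm <- as.matrix(A %*% g) / deg
    g[bad, ] <- gm[bad, , drop = FALSE]
    nrm <- row_norms(g)
  }
  g
}

# Mild diffusion of an element-gradient field (each pass averages an element
# with its face neighbors). Attenuates the staircase jitter that lattice
# boundaries imprint on the surface element layer; the underlying harmonic
# fields are smooth, so interior directions are essentially unchanged. The
# LV/RV frame blend is governed by the interpolation weight, not by the
# individual fields, so this does not smear the septal junction.
smooth_element_gradients <- function(g, adj, passes = 2L) {
  if (passes < 1L) return(g)
  n <- nrow(g)
  A <- Matrix::sparseMatrix(i = c(adj[, 1], adj[, 2]),
                            j = c(adj[, 2], adj[, 1]), x = 1,
                            dims = c(n, n))
  deg <- pmax(Matrix::rowSums(A), 1)
  for (p in seq_len(passes))
    g <- 0.5 * g + 0.5 * as.matrix(A %*% g) / deg
  g
}

# Build rotated orthonormal frames from apicobasal and transmural gradient
# candidates. Returns fiber/sheet/normal plus the unrotated axes.
build_frame <- function(g_long, g_trans, alpha, beta) {
  e_l0 <- normalize_rows(g_long)
  bad_l <- row_norms(g_long) < 1e-12
  # deterministic fallback for degenerate apicobasal gradients
  e_l0[bad_l, ] <- matrix(rep(c(0, 0, 1), sum(bad_l)), ncol = 3, byrow = TRUE)
  gt <- g_trans - e_l0 * rowSums(g_trans * e_l0)
  bad_t <- row_norms(gt) < 1e-12
  if (any(bad_t)) {
    # pick the world axis least aligned with e_l
    alt <- matrix(0, sum(bad_t), 3)
    ax <- apply(abs(e_l0[bad_t, , drop = FALSE]), 1, which.min)
    alt[cbind(seq_len(sum(bad_t)), ax)] <- 1
    alt <- alt - e_l0[bad_t, , drop = FALSE] *
      rowSums(alt * e_l0[bad_t, , drop = FALSE])
    gt[bad_t, ] <- alt
  }
  e_t <- normalize_rows(gt)
  e_c <- cross_rows(e_l0, e_t)
  ca <- cos(alpha); sa <- sin(alpha)
  f <- ca * e_c + sa * e_l0
  l2 <- -sa * e_c + ca * e_l0
  cb <- cos(beta); sb <- sin(beta)
  s <- cb * e_t + sb * l2
  n <- cross_rows(f, s)
  list(f = f, s = s, n = n, e_c = e_c, e_l = e_l0, e_t = e_t)
}

# --- quaternion utilities (row-wise) --------------------------------------

# rotation matrices (rows f,s,n as columns of R = [f s n]) -> quaternions
frames_to_quat <- function(fr) {
  # R[, 1] = f, R[, 2] = s, R[, 3] = n; standard Shepperd extraction
  r11 <- fr$f[, 1]; r21 <- fr$f[, 2]; r31 <- fr$f[, 3]
  r12 <- fr$s[, 1]; r22 <- fr$s[, 2]; r32 <- fr$s[, 3]
  r13 <- fr$n[, 1]; r23 <- fr$n[, 2]; r33 <- fr$n[, 3]
  m <- length(r11)
  q <- matrix(0, m, 4)  # (w, x, y, z)
  tr <- r11 + r22 + r33
  c1 <- tr > r11 & tr > r22 & tr > r33
  s1 <- sqrt(pmax(tr[c1] + 1, 0)) * 2
  q[c1, 1] <- s1 / 4
  q[c1, 2] <- (r32[c1] - r23[c1]) / s1
  q[c1, 3] <- (r13[c1] - r31[c1]) / s1
  q[c1, 4] <- (r21[c1] - r12[c1]) / s1
  c2 <- !c1 & r11 >= r22 & r11 >= r33
  s2 <- sqrt(pmax(1 + r11[c2] - r22[c2] - r33[c2], 1e-300)) * 2
  q[c2, 1] <- (r32[c2] - r23[c2]) / s2
  q[c2, 2] <- s2 / 4
  q[c2, 3] <- (r12[c2] + r21[c2]) / s2
  q[c2, 4] <- (r13[c2] + r31[c2]) / s2
  c3 <- !c1 & !c2 & r22 >= r33
  s3 <- sqrt(pmax(1 + r22[c3] - r11[c3] - r33[c3], 1e-300)) * 2
  q[c3, 1] <- (r13[c3] - r31[c3]) / s3
  q[c3, 2] <- (r12[c3] + r21[c3]) / s3
  q[c3, 3] <- s3 / 4
  q[c3, 4] <- (r23[c3] + r32[c3]) / s3
  c4 <- !c1 & !c2 & !c3
  s4 <- sqrt(pmax(1 + r33[c4] - r11[c4] - r22[c4], 1e-300)) * 2
  q[c4, 1] <- (r21[c4] - r12[c4]) / s4
  q[c4, 2] <- (r13[c4] + r31[c4]) / s4
  q[c4, 3] <- (r23[c4] + r32[c4]) / s4
  q[c4, 4] <- s4 / 4
  q / pmax(sqrt(rowSums(q^2)), 1e-300)
}

quat_to_frames <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  f <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y))
  s <- cbind(2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x))
  n <- cbind(2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  list(f = f, s = s, n = n)
}

# Spherical-linear interpolation between per-element frames with quaternion
# sign disambiguation (simplified bislerp).
blend_frames_slerp <- function(Qa, Qb, w) {
  qa <- frames_to_quat(Qa)
  qb <- frames_to_quat(Qb)
  dt <- rowSums(qa * qb)
  qb[dt < 0, ] <- -qb[dt < 0, , drop = FALSE]
  dt <- abs(dt)
  dt <- pmin(dt, 1)
  th <- acos(dt)
  sth <- sin(th)
  wa <- ifelse(sth > 1e-8, sin((1 - w) * th) / sth, 1 - w)
  wb <- ifelse(sth > 1e-8, sin(w * th) / sth, w)
  q <- wa * qa + wb * qb
  q <- q / pmax(sqrt(rowSums(q^2)), 1e-300)
  out <- quat_to_frames(q)
  out$e_c <- Qa$e_c * (1 - w) + Qb$e_c * w
  out$e_l <- Qa$e_l * (1 - w) + Qb$e_l * w
  out$e_t <- Qa$e_t * (1 - w) + Qb$e_t * w
  out
}

# Per-axis linear blend followed by Gram-Schmidt re-orthonormalization.
blend_frames_linear <- function(Qa, Qb, w) {
  sgn <- sign(rowSums(Qa$f * Qb$f))
  sgn[sgn == 0] <- 1
  f <- normalize_rows(Qa$f * (1 - w) + Qb$f * (w * sgn))
  s0 <- Qa$s * (1 - w) + Qb$s * (w * sgn)
  s <- normalize_rows(s0 - f * rowSums(s0 * f))
  n <- cross_rows(f, s)
  list(f = f, s = s, n = n,
       e_c = Qa$e_c * (1 - w) + Qb$e_c * w,
       e_l = Qa$e_l * (1 - w) + Qb$e_l * w,
       e_t = Qa$e_t * (1 - w) + Qb$e_t * w)
}

#' Transmural helix-angle profile
#'
#' Bins myocardial elements by transmural coordinate and reports the mean
#' helix angle per bin: the signed angle between the fiber direction
#' projected on the local circumferential-apicobasal plane and the
#' circumferential axis. Local axes are rebuilt from the supplied transmural
#' Laplace field (gradient = transmural axis) and the mesh long axis
#' (+z by default), so the profile is an independent read-out of the
#' assigned fibers.
#'
#' @param mesh the \code{tet_mesh} the field lives on (myocardial submesh).
#' @param fibers a \code{fiber_field} (full-mesh or submesh sized).
#' @param field transmural \code{laplace_field} (0 endo, 1 epi).
#' @param n_bins number of equal-width d-bins.
#' @param long_axis length-3 apicobasal direction (default +z).
#' @return data.frame with columns \code{d_mid}, \code{mean_helix_deg},
#'   \code{n}; empty bins are reported with \code{n = 0} and \code{NA} angle.
#' @export
helix_angle_profile <- function(mesh, fibers, field, n_bins = 10,
                                long_axis = c(0, 0, 1)) {
  m <- nrow(mesh$tets)
  f <- fibers$f
  if (nrow(f) != m) {
    emap <- attr(fibers, "frame")$elem_map
    if (is.null(emap) || length(emap) != m)
      stop("fiber field does not match mesh")
    f <- f[emap, , drop = FALSE]
  } else if (!is.null(fibers$myocardial) && !all(fibers$myocardial)) {
    keep <- fibers$myocardial
    if (sum(keep) != m) stop("fiber field does not match mesh")
  }
  d <- pmin(pmax(element_means(mesh, field$values), 0), 1)
  g_t <- element_gradients(mesh, field$values)
  e_l0 <- matrix(rep(long_axis / sqrt(sum(long_axis^2)), m), ncol = 3,
                 byrow = TRUE)
  e_t <- g_t - e_l0 * rowSums(g_t * e_l0)
  e_t <- normalize_rows(e_t)
  e_l <- e_l0
  e_c <- cross_rows(e_l, e_t)
  ang <- atan2(rowSums(f * e_l), rowSums(f * e_c)) * 180 / pi
  # fiber sign is a convention: fold into (-90, 90]
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(d, br, rightmost.closed = TRUE), n_bins)
  out <- data.frame(d_mid = (br[-1] + br[-(n_bins + 1)]) / 2,
                    mean_helix_deg = NA_real_, n = 0L)
  agg <- tapply(ang, bin, mean)
  cnt <- table(bin)
  idx <- as.integer(names(agg))
  out$mean_helix_deg[idx] <- as.numeric(agg)
  out$n[idx] <- as.integer(cnt)
  out
}

#' Element-wise helix angles against local frames stored in a fiber field
#'
#' Uses the unrotated frame axes recorded by \code{\link{assign_fibers}}.
#'
#' @param fibers a \code{fiber_field} from \code{\link{assign_fibers}}.
#' @return numeric vector (degrees) over myocardial elements, with the
#'   transmural coordinate attached as attribute \code{d}.
#' @export
helix_angles <- function(fibers) {
  fr <- attr(fibers, "frame")
  emap <- fr$elem_map
  f <- fibers$f[emap, , drop = FALSE]
  ang <- atan2(rowSums(f * fr$e_l), rowSums(f * fr$e_c)) * 180 / pi
  ang[ang > 90] <- ang[ang > 90] - 180
  ang[ang <= -90] <- ang[ang <= -90] + 180
  attr(ang, "d") <- attr(fibers, "d")[emap]
  ang
}
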