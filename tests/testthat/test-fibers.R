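# Analytic helix-angle read-out on the idealized annulus: the transmural
# harmonic coordinate is ln(r/r1)/ln(r2/r1) in closed form, the local
# circumferential direction is z-hat x r-hat, and the apicobasal axis is z.
annulus_helix_readout <- function(mesh, fib, r1, r2) {
  t <- mesh$tets
  cen <- (mesh$nodes[t[, 1], ] + mesh$nodes[t[, 2], ] +
            mesh$nodes[t[, 3], ] + mesh$nodes[t[, 4], ]) / 4
  rc <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  d <- log(rc / r1) / log(r2 / r1)
  ec <- cbind(-cen[, 2], cen[, 1], 0) / rc
  ha <- atan2(fib$f[, 3], rowSums(fib$f * ec)) * 180 / pi
  ha[ha > 90] <- ha[ha > 90] - 180
  ha[ha <= -90] <- ha[ha <= -90] + 180
  list(d = d, helix = ha)
}

test_that("fiber triads are orthonormal right-handed unit frames", {
  m <- annulus_mesh(nr = 4, ntheta = 24, nz = 6)
  fib <- assign_fibers(m, annulus_surfaces(m), fiber_config(), myo_tags = 1L)
  expect_lt(max(abs(sqrt(rowSums(fib$f^2)) - 1)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(fib$s^2)) - 1)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(fib$n^2)) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fib$f * fib$s))), 1e-9)
  expect_lt(max(abs(rowSums(fib$f * fib$n))), 1e-9)
  dets <- rowSums(fib$f * cardiomesh:::cross_rows(fib$s, fib$n))
  expect_lt(max(abs(dets - 1)), 1e-9)
  d <- attr(fib, "d")
  expect_true(all(d[fib$myocardial] >= 0 & d[fib$myocardial] <= 1))
})

test_that("helix angle recovers the configured linear transmural rule", {
  cfg <- fiber_config(alpha_endo = 60, alpha_epi = -60)
  m <- annulus_mesh()
  an <- attr(m, "annulus")
  fib <- assign_fibers(m, annulus_surfaces(m), cfg, myo_tags = 1L)
  ro <- annulus_helix_readout(m, fib, an$r_inner, an$r_outer)
  fit <- lm(ro$helix ~ ro$d)
  slope_target <- cfg$alpha_epi - cfg$alpha_endo
  expect_lt(abs(coef(fit)[2] - slope_target) / abs(slope_target), 0.10)
  expect_gt(summary(fit)$r.squared, 0.95)
  mid <- abs(ro$d - 0.5) < 0.05
  expect_lt(abs(mean(ro$helix[mid]) -
                  (cfg$alpha_endo + cfg$alpha_epi) / 2), 2)
})

test_that("asymmetric angle configurations are honored symbolically", {
  cfg <- fiber_config(alpha_endo = 40, alpha_epi = -70)
  m <- annulus_mesh(nr = 4, ntheta = 32, nz = 8)
  an <- attr(m, "annulus")
  fib <- assign_fibers(m, annulus_surfaces(m), cfg, myo_tags = 1L)
  ro <- annulus_helix_readout(m, fib, an$r_inner, an$r_outer)
  fit <- lm(ro$helix ~ ro$d)
  expect_lt(abs(coef(fit)[2] - (cfg$alpha_epi - cfg$alpha_endo)) /
              abs(cfg$alpha_epi - cfg$alpha_endo), 0.10)
  expect_lt(abs(coef(fit)[1] - cfg$alpha_endo), 3)
})

test_that("fiber continuity: face-adjacent myocardial triads stay within 45 deg", {
  ph <- make_biventricular_phantom(phantom_spec())
  m <- mesh_from_label_image(ph)
  bc <- derive_bc_surfaces(m)
  fib <- assign_fibers(m, bc)
  myo_elems <- which(fib$myocardial)
  sub <- submesh(m, c(1L, 2L))
  cf <- cardiomesh:::faces_of_tets(sub$tets)
  owner <- rep(seq_len(nrow(sub$tets)), times = 4)
  o <- order(cf[, 1], cf[, 2], cf[, 3])
  cfo <- cf[o, , drop = FALSE]
  own_o <- owner[o]
  same <- rowSums(cfo[-1, , drop = FALSE] ==
                    cfo[-nrow(cfo), , drop = FALSE]) == 3L
  e1 <- own_o[c(same, FALSE)]
  e2 <- own_o[c(FALSE, same)]
  emap <- attr(sub, "elem_map")
  f <- fib$f[emap, , drop = FALSE]
  dots <- abs(rowSums(f[e1, , drop = FALSE] * f[e2, , drop = FALSE]))
  ang <- acos(pmin(dots, 1)) * 180 / pi
  expect_lt(quantile(ang, 0.999), 45)
})

test_that("non-myocardial elements carry flagged null triads", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  bc <- derive_bc_surfaces(m)
  fib <- assign_fibers(m, bc)
  non <- !fib$myocardial
  expect_identical(sum(non), sum(!(m$element_tags %in% c(1L, 2L))))
  expect_true(all(fib$f[non, ] == 0))
})

test_that("helix profile is flat for a constant field on constant frames", {
  m <- slab_mesh(6, 4, 3)
  xmin <- which(abs(m$nodes[, 1]) < 1e-12)
  xmax <- which(abs(m$nodes[, 1] - 6) < 1e-12)
  u <- solve_laplace(m, list(list(xmin, value = 0), list(xmax, value = 1)))
  ne <- nrow(m$tets)
  fib <- structure(list(
    f = matrix(rep(c(0, 1, 0), each = ne), ncol = 3),
    s = matrix(rep(c(1, 0, 0), each = ne), ncol = 3),
    n = matrix(rep(c(0, 0, 1), each = ne), ncol = 3),
    myocardial = rep(TRUE, ne)), class = "fiber_field")
  prof <- helix_angle_profile(m, fib, u, n_bins = 5)
  filled <- !is.na(prof$mean_helix_deg)
  expect_true(any(filled))
  expect_lt(diff(range(prof$mean_helix_deg[filled])), 1e-9)
})

test_that("single-bin profile equals the global mean helix angle", {
  m <- annulus_mesh(nr = 3, ntheta = 16, nz = 4)
  fib <- assign_fibers(m, annulus_surfaces(m), fiber_config(), myo_tags = 1L)
  tf <- attr(fib, "fields")$phi_epi
  p1 <- helix_angle_profile(m, fib, tf, n_bins = 1)
  pN <- helix_angle_profile(m, fib, tf, n_bins = 8)
  total <- sum(pN$mean_helix_deg * pN$n, na.rm = TRUE) / sum(pN$n)
  expect_equal(p1$mean_helix_deg[1], total, tolerance = 1e-9)
  expect_identical(p1$n[1], nrow(m$tets))
})

test_that("annulus profile runs approximately linearly endo to epi", {
  cfg <- fiber_config()
  m <- annulus_mesh()
  fib <- assign_fibers(m, annulus_surfaces(m), cfg, myo_tags = 1L)
  prof <- helix_angle_profile(m, fib, attr(fib, "fields")$phi_epi,
                              n_bins = 8)
  expect_true(all(diff(prof$mean_helix_deg) < 0))
  expect_gt(prof$mean_helix_deg[1], 30)
  expect_lt(prof$mean_helix_deg[8], -30)
})

test_that("angle configuration bounds are validated", {
  expect_error(fiber_config(alpha_endo = 95), "angles")
  expect_error(fiber_config(alpha_epi = -90), "angles")
})
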