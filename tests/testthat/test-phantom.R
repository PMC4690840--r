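test_that("phantom generation is deterministic and correctly labelled", {
  s <- small_phantom_spec()
  a <- make_biventricular_phantom(s)
  b <- make_biventricular_phantom(s)
  expect_identical(a$voxels, b$voxels)
  expect_setequal(setdiff(unique(as.vector(a$voxels)), 0L), 1:5)
})

test_that("phantom regions are 6-connected at clinical resolution", {
  ph <- make_biventricular_phantom(phantom_spec(spacing = 1))
  for (tag in 1:5)
    expect_equal(connected_components(ph, tag)$n, 1L)
})

test_that("voxelized LV shell volume matches the closed-form truncated shell", {
  spec <- phantom_spec(rv_outer_radii = NULL, spacing = 1)
  ph <- make_biventricular_phantom(spec)
  v_vox <- tag_volume(ph, 1L)
  v_an <- cardiomesh:::phantom_lv_shell_volume(spec)
  expect_lt(abs(v_vox - v_an) / v_an, 0.05)
})

test_that("voxelized volumes approach the analytic volume as spacing shrinks", {
  spec1 <- phantom_spec(rv_outer_radii = NULL, spacing = 1)
  spec2 <- phantom_spec(rv_outer_radii = NULL, spacing = 0.5)
  v_an <- cardiomesh:::phantom_lv_shell_volume(spec1)
  e1 <- abs(tag_volume(make_biventricular_phantom(spec1), 1L) - v_an) / v_an
  e2 <- abs(tag_volume(make_biventricular_phantom(spec2), 1L) - v_an) / v_an
  expect_lt(e2, e1 + 0.005)
  expect_lt(e2, 0.025)
})

test_that("unresolvable shells are rejected", {
  expect_error(
    make_biventricular_phantom(phantom_spec(lv_wall_thickness = 0.4,
                                            spacing = 1)),
    "not resolvable")
})

test_that("analytic signed-distance evaluators are exact on the ellipsoids", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  an <- attr(ph, "analytic")
  r <- an$lv_outer$radii
  # points constructed on the surface: distance must vanish
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  pts <- cbind(r[1] * cos(th) * sin(1), r[2] * sin(th) * sin(1),
               r[3] * cos(1))
  expect_lt(max(abs(phantom_surface_distance(ph, pts, "lv_outer"))), 1e-9)
  # sphere special case: distance has closed form |p| - r
  d <- ellipsoid_distance(cbind(c(0.5, 3, 12), 0, 0), radii = c(5, 5, 5))
  expect_equal(d, c(0.5, 3, 12) - 5, tolerance = 1e-9)
})

test_that("boundary noise: identity at p = 0 and full swap on a 2-voxel pair", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  expect_identical(add_boundary_noise(ph, 0, 1L)$voxels, ph$voxels)
  two <- label_image(array(c(1L, 2L), dim = c(2, 1, 1)),
                     tags = c("1" = "a", "2" = "b"))
  out <- add_boundary_noise(two, 1, 5L)
  expect_identical(as.vector(out$voxels), c(2L, 1L))
})

test_that("boundary noise changes ~p of boundary voxels (binomial bounds)", {
  ph <- make_biventricular_phantom(phantom_spec(spacing = 1))
  v <- ph$voxels
  d <- dim(v)
  differs <- array(FALSE, d)
  for (ax in 1:3) {
    idx <- lapply(d, seq_len)
    i1 <- idx; i1[[ax]] <- 1:(d[ax] - 1)
    i2 <- idx; i2[[ax]] <- 2:d[ax]
    ne <- v[i1[[1]], i1[[2]], i1[[3]]] != v[i2[[1]], i2[[2]], i2[[3]]]
    differs[i1[[1]], i1[[2]], i1[[3]]] <-
      differs[i1[[1]], i1[[2]], i1[[3]]] | ne
    differs[i2[[1]], i2[[2]], i2[[3]]] <-
      differs[i2[[1]], i2[[2]], i2[[3]]] | ne
  }
  nb <- sum(differs)
  expect_gt(nb, 1000)
  p <- 0.2
  out <- add_boundary_noise(ph, p, 11L)
  changed <- sum(out$voxels != ph$voxels)
  ci <- qbinom(c(0.005, 0.995), nb, p)
  expect_gte(changed, ci[1])
  expect_lte(changed, ci[2])
})

test_that("noise is reproducible for a fixed seed and leaves the RNG alone", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  set.seed(99)
  before <- .Random.seed
  a <- add_boundary_noise(ph, 0.3, 7L)
  expect_identical(.Random.seed, before)
  b <- add_boundary_noise(ph, 0.3, 7L)
  expect_identical(a$voxels, b$voxels)
  c_ <- add_boundary_noise(ph, 0.3, 8L)
  expect_false(identical(a$voxels, c_$voxels))
})
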