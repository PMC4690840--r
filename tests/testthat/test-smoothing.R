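# The umbrella-weight oracle: a triangular bipyramid (5 vertices, 6 faces)
# whose Laplacian rows can be written down by hand from the adjacency:
# equatorial vertices 1:3 neighbor everything else (degree 4), apexes 4:5
# neighbor the equator only (degree 3).
bipyramid_surface <- function() {
  v <- rbind(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 2, 4), c(2, 3, 4), c(3, 1, 4),
             c(2, 1, 5), c(3, 2, 5), c(1, 3, 5))
  tagged_surface(v, f, cbind(rep(1L, 6), rep(0L, 6)))
}

test_that("uniform Laplacian matches hand-computed umbrella weights", {
  L <- as.matrix(build_surface_laplacian(bipyramid_surface()))
  expected <- rbind(
    c(1, -1/4, -1/4, -1/4, -1/4),
    c(-1/4, 1, -1/4, -1/4, -1/4),
    c(-1/4, -1/4, 1, -1/4, -1/4),
    c(-1/3, -1/3, -1/3, 1, 0),
    c(-1/3, -1/3, -1/3, 0, 1))
  expect_equal(L, expected, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Laplacian annihilates constant fields (rows sum to zero)", {
  for (kind in c("uniform-graph", "cotangent")) {
    s <- extract_tag_surface(tromino_image(), 1)
    L <- build_surface_laplacian(s, kind)
    const <- matrix(1, nrow(s$vertices), 3)
    expect_lt(max(abs(as.matrix(L %*% const))), 1e-12)
  }
})

test_that("zero box half-width leaves the surface unchanged", {
  s <- extract_tag_surface(tromino_image(), 1)
  out <- smooth_surface(s, 1, smoothing_config(box_halfwidth_voxels = 0))
  expect_identical(out$surface$vertices, s$vertices)
  expect_identical(out$report$max_displacement_voxels, 0)
})

test_that("both solvers match a dense box-constrained QP oracle to 1e-6", {
  s <- extract_tag_surface(tromino_image(), 1)
  expect_lte(nrow(s$vertices), 40)
  L <- as.matrix(build_surface_laplacian(s))
  X0 <- s$vertices
  h <- 0.5
  G <- 2 * crossprod(L)
  oracle <- 0
  for (a in 1:3) {
    o <- optim(X0[, a], function(x) sum((L %*% x)^2),
               function(x) as.vector(G %*% x),
               method = "L-BFGS-B", lower = X0[, a] - h, upper = X0[, a] + h,
               control = list(maxit = 5000, factr = 1))
    oracle <- oracle + o$value
  }
  for (solver in c("projected-gradient", "admm")) {
    sm <- smooth_surface(s, 1, smoothing_config(
      solver = solver, tolerance = 1e-13, max_iterations = 50000))
    expect_lt(abs(sm$report$final_objective - oracle) / oracle, 1e-6,
              label = solver)
    # feasibility is exact
    expect_lte(max(abs(sm$surface$vertices - X0)), h + 1e-12)
  }
})

test_that("objective decreases and the box constraint holds on the phantom", {
  ph <- make_biventricular_phantom(small_phantom_spec(noise = 0.2, seed = 3))
  s <- extract_surfaces(ph)
  sm <- smooth_surface(s, ph$spacing)
  expect_lte(sm$report$final_objective, sm$report$initial_objective)
  expect_lte(sm$report$max_displacement_voxels, 0.5 + 1e-9)
  expect_lte(max(abs(sm$surface$vertices - s$vertices)),
             0.5 * max(ph$spacing) + 1e-9)
  expect_identical(sm$surface$faces, s$faces)
  expect_identical(sm$surface$face_labels, s$face_labels)
})

test_that("different solver paths agree on the convex optimum", {
  s <- extract_tag_surface(tromino_image(), 1)
  a <- smooth_surface(s, 1, smoothing_config(
    tolerance = 1e-12, max_iterations = 50000))$report$final_objective
  b <- smooth_surface(s, 1, smoothing_config(
    solver = "admm", tolerance = 1e-12,
    max_iterations = 50000))$report$final_objective
  expect_lt(abs(a - b) / a, 10 * 1e-6)
})

test_that("smoothed marching-cubes sphere is closer to the analytic sphere", {
  img <- sphere_image(10, 1)
  s <- merge_tag_surfaces(list(extract_tag_surface(img, 1)), image = img)
  sm <- smooth_surface(s, 1)
  dev_raw <- max(abs(sqrt(rowSums(s$vertices^2)) - 10))
  dev_sm <- max(abs(sqrt(rowSums(sm$surface$vertices^2)) - 10))
  expect_lt(dev_sm, dev_raw)
})

test_that("Euclidean-ball constraint variant also stays feasible", {
  s <- extract_tag_surface(tromino_image(), 1)
  sm <- smooth_surface(s, 1, smoothing_config(constraint = "ball"))
  disp <- sqrt(rowSums((sm$surface$vertices - s$vertices)^2))
  expect_lte(max(disp), 0.5 + 1e-9)
})
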