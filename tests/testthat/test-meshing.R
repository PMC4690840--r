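test_that("a single voxel splits into 6 tets of exactly the voxel volume", {
  img <- label_image(array(1L, dim = c(1, 1, 1)), spacing = c(0.8, 1.1, 1.3))
  m <- mesh_from_label_image(img)
  vol <- cardiomesh:::tet_volumes(m)
  expect_identical(nrow(m$tets), 6L)
  expect_true(all(vol > 0))
  expect_equal(sum(vol), 0.8 * 1.1 * 1.3, tolerance = 1e-14)
  expect_true(check_mesh(m))
})

test_that("two-voxel image meshes conformingly across the shared face", {
  img <- label_image(array(1L, dim = c(2, 1, 1)))
  m <- mesh_from_label_image(img)
  expect_identical(nrow(m$tets), 12L)
  expect_true(check_mesh(m))
  # brute-force: every face on the shared plane x = 1 appears exactly twice
  cf <- cardiomesh:::faces_of_tets(m$tets)
  keys <- apply(cf, 1, paste, collapse = " ")
  onplane <- apply(cf, 1, function(f) all(abs(m$nodes[f, 1] - 1) < 1e-12))
  counts <- table(keys[onplane])
  expect_true(all(counts == 2L))
  expect_gt(length(counts), 0L)
})

test_that("per-tag mesh volume equals voxel count x voxel volume", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  vol <- cardiomesh:::tet_volumes(m)
  for (tag in 1:5)
    expect_equal(sum(vol[m$element_tags == tag]), tag_volume(ph, tag),
                 tolerance = 1e-9)
  # tag conservation: 6 elements per foreground voxel
  expect_identical(as.vector(table(m$element_tags)),
                   as.vector(table(ph$voxels[ph$voxels != 0L])) * 6L)
})

test_that("Kuhn-split quality matches direct geometry on one tetrahedron", {
  # reference values computed from the unit-cube Kuhn tet
  # (0,0,0)-(1,0,0)-(1,1,0)-(1,1,1) by elementary formulas
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  vol <- abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) / 6
  tri_area <- function(a, b, cc)
    sqrt(sum(crossprod_vec(b - a, cc - a)^2)) / 2
  crossprod_vec <- function(u, v)
    c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])
  A <- tri_area(p[2, ], p[3, ], p[4, ]) + tri_area(p[1, ], p[3, ], p[4, ]) +
    tri_area(p[1, ], p[2, ], p[4, ]) + tri_area(p[1, ], p[2, ], p[3, ])
  r_in <- 3 * vol / A
  # circumcenter of this tet is the cube center
  R <- sqrt(sum((c(0.5, 0.5, 0.5) - p[1, ])^2))
  ratio_ref <- 3 * r_in / R

  m <- mesh_from_label_image(label_image(array(1L, dim = c(1, 1, 1))))
  q <- mesh_quality(m)
  expect_equal(q$min_radius_ratio, ratio_ref, tolerance = 1e-12)
  expect_equal(q$mean_radius_ratio, ratio_ref, tolerance = 1e-12)
  expect_gt(q$min_volume, 0)
})

test_that("edge lengths of the lattice split lie in [h, 2h]", {
  h <- 1.5
  ph <- make_biventricular_phantom(small_phantom_spec(spacing = h))
  q <- mesh_quality(mesh_from_label_image(ph))
  expect_gte(q$edge_length[["min"]], h - 1e-12)
  expect_lte(q$edge_length[["max"]], 2 * h)
  expect_gte(q$edge_length[["mean"]], h)
})

test_that("watertight per-tag boundaries and no unreferenced nodes", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  expect_identical(length(unique(as.vector(m$tets))), nrow(m$nodes))
  for (tag in c(1L, 3L)) {
    bf <- tag_boundary(m, tag)$faces
    edges <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(1, 3)])
    keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    expect_true(all(table(keys) %% 2 == 0))
  }
})

test_that("constrained boundary relaxation keeps elements valid and capped", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m0 <- mesh_from_label_image(ph)
  m1 <- mesh_from_label_image(ph, relax_boundary = 2L)
  expect_true(all(cardiomesh:::tet_volumes(m1) > 0))
  expect_lte(max(abs(m1$nodes - m0$nodes)), 0.5 * max(ph$spacing) + 1e-12)
})

test_that("CARP writer/reader round-trips mesh and fibers", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph, tags = 1L)
  base <- withr::local_tempfile()
  fake_fib <- list(f = cardiomesh:::normalize_rows(
    matrix(1, nrow(m$tets), 3)),
    s = matrix(rep(c(0, 1, 0) / sqrt(2) * c(sqrt(2), 1, 1), each = nrow(m$tets)), ncol = 3))
  fake_fib$s <- cardiomesh:::normalize_rows(fake_fib$s)
  write_carp_mesh(m, base, fibers = fake_fib)
  back <- read_carp_mesh(base)
  expect_equal(back$nodes, m$nodes, tolerance = 1e-6)
  expect_identical(back$tets, m$tets)
  expect_identical(back$element_tags, m$element_tags)
  expect_equal(attr(back, "fibers")[, 1:3], fake_fib$f, tolerance = 1e-6,
               ignore_attr = TRUE)
})
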