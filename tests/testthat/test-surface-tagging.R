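test_that("an isolated single-voxel region has 12 boundary triangles", {
  arr <- array(0L, dim = c(3, 3, 3))
  arr[2, 2, 2] <- 1L
  arr[1, 1, 1] <- 2L
  img <- label_image(arr)
  m <- mesh_from_label_image(img)
  expect_identical(nrow(tag_boundary(m, 1L)$faces), 12L)
  expect_error(tag_boundary(m, 7L), "unknown tag")
})

test_that("boundary of all foreground equals the global mesh boundary", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  all_fg <- tag_boundary(m, 1:5)
  glob <- tag_boundary(m, 0L)
  expect_identical(nrow(face_set_op(all_fg, glob, "difference")$faces), 0L)
  expect_identical(nrow(all_fg$faces), nrow(glob$faces))
})

test_that("face-set algebra satisfies the set identities", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  a <- tag_boundary(m, 1L)
  b <- tag_boundary(m, 3L)
  expect_identical(nrow(face_set_op(a, a, "intersection")$faces),
                   nrow(a$faces))
  expect_identical(nrow(face_set_op(a, a, "difference")$faces), 0L)
  ab <- nrow(face_set_op(a, b, "intersection")$faces)
  expect_identical(nrow(face_set_op(a, b, "union")$faces),
                   nrow(a$faces) + nrow(b$faces) - ab)
  # constructively disjoint sets intersect empty
  lv_pool_only <- face_set_op(b, a, "difference")
  expect_identical(nrow(face_set_op(lv_pool_only, a, "intersection")$faces),
                   0L)
  # mismatched meshes are rejected
  m2 <- mesh_from_label_image(ph, tags = 1L)
  expect_error(face_set_op(a, tag_boundary(m2, 1L), "union"),
               "different meshes")
})

test_that("derived BC surfaces are nonempty, disjoint, and cover the wall", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  bc <- derive_bc_surfaces(m)
  sets <- bc[c("lv_endo", "rv_endo", "epi", "base")]
  for (s in sets) expect_gt(nrow(s$faces), 0L)
  nm <- names(sets)
  for (i in seq_along(sets)) for (j in seq_along(sets)) if (i < j)
    expect_identical(nrow(face_set_op(sets[[i]], sets[[j]],
                                      "intersection")$faces), 0L)
  # coverage: union of the four sets equals the myocardial boundary
  u <- Reduce(function(x, y) face_set_op(x, y, "union"), sets)
  g_myo <- tag_boundary(m, c(1L, 2L))
  expect_identical(nrow(face_set_op(u, g_myo, "difference")$faces), 0L)
  expect_identical(nrow(face_set_op(g_myo, u, "difference")$faces), 0L)
  # apex is the lowest epicardial node
  epi_nodes <- face_set_nodes(bc$epi)
  expect_equal(m$nodes[bc$apex_node, 3], min(m$nodes[epi_nodes, 3]))
})

test_that("every epicardial face is carried by exactly one myocardial tet", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  bc <- derive_bc_surfaces(m)
  cf <- cardiomesh:::faces_of_tets(m$tets)
  keys <- paste(cf[, 1], cf[, 2], cf[, 3])
  owner <- rep(seq_len(nrow(m$tets)), times = 4)
  epi_keys <- cardiomesh:::face_keys(bc$epi$faces)
  idx <- split(owner, keys)[epi_keys]
  counts <- lengths(idx)
  expect_true(all(counts == 1L))
  adj_tags <- m$element_tags[unlist(idx)]
  expect_true(all(adj_tags %in% c(1L, 2L)))
})

test_that("missing required roles are reported by name", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  expect_error(derive_bc_surfaces(m, roles = list(rv_myo = 2L, rv_pool = 4L)),
               "lv_myo")
})

test_that("LV-only phantoms yield an empty RV endocardium", {
  ph <- make_biventricular_phantom(small_phantom_spec(rv_outer_radii = NULL))
  m <- mesh_from_label_image(ph)
  bc <- derive_bc_surfaces(m)
  expect_identical(nrow(bc$rv_endo$faces), 0L)
  expect_gt(nrow(bc$lv_endo$faces), 0L)
})

test_that(".surf export writes the advertised layout", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  m <- mesh_from_label_image(ph)
  bc <- derive_bc_surfaces(m)
  p <- withr::local_tempfile(fileext = ".surf")
  write_carp_surf(bc$base, p)
  txt <- readLines(p)
  expect_identical(as.integer(txt[1]), nrow(bc$base$faces))
  expect_true(all(grepl("^Tr \\d+ \\d+ \\d+$", txt[-1])))
})
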