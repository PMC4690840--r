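test_that("an isolated voxel yields a closed topological sphere", {
  s <- extract_tag_surface(single_voxel_image(), 1)
  expect_true(check_surface_closed(s, manifold = TRUE))
  expect_identical(cardiomesh:::euler_characteristic(s$faces), 2L)
  # positive enclosed volume = consistent outward orientation
  expect_gt(surface_measures(s, 1)$volume, 0)
})

test_that("empty and absent masks are rejected", {
  img <- single_voxel_image()
  expect_error(extract_tag_surface(img, 2), "unknown tag")
  img2 <- label_image(array(0L, c(2, 2, 2)), tags = c("1" = "x"))
  expect_error(extract_tag_surface(img2, 1), "empty mask")
})

test_that("sphere surface area is resolution-stable within 3%", {
  a_coarse <- surface_measures(extract_tag_surface(sphere_image(10, 0.5), 1))$area
  a_ref <- surface_measures(extract_tag_surface(sphere_image(10, 0.25), 1))$area
  expect_lt(abs(a_coarse - a_ref) / a_ref, 0.03)
})

test_that("blocky surface volume is exactly voxel count x voxel volume", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  for (tag in c(1L, 2L)) {
    sb <- extract_tag_surface(ph, tag, mode = "blocky")
    expect_equal(surface_measures(sb, tag)$volume, tag_volume(ph, tag),
                 tolerance = 1e-12)
  }
})

test_that("merging a single-tag surface is the identity", {
  s <- extract_tag_surface(single_voxel_image(), 1)
  m <- merge_tag_surfaces(list(s))
  expect_equal(m$vertices, s$vertices)
  expect_identical(m$faces, s$faces)
  expect_identical(m$face_labels, s$face_labels)
})

test_that("two abutting voxels of different tags share one interface wall", {
  arr <- array(0L, dim = c(4, 3, 3))
  arr[2, 2, 2] <- 1L
  arr[3, 2, 2] <- 2L
  img <- label_image(arr, spacing = 1, tags = c("1" = "a", "2" = "b"))
  sa <- extract_tag_surface(img, 1, mode = "blocky")
  sb <- extract_tag_surface(img, 2, mode = "blocky")
  shared <- count_coincident_faces(sa, sb)
  expect_identical(shared, 2L)  # the square wall, split into 2 triangles
  merged <- merge_tag_surfaces(list(sa, sb), image = img)
  expect_identical(nrow(merged$faces),
                   nrow(sa$faces) + nrow(sb$faces) - shared)
  expect_identical(sum(merged$face_labels[, 1] == 1L &
                         merged$face_labels[, 2] == 2L), shared)
  expect_true(check_surface_closed(merged))
})

test_that("abutting blocks: merged interface equals brute-force coincidence", {
  arr <- array(0L, dim = c(8, 5, 5))
  arr[2:4, 2:4, 2:4] <- 1L
  arr[5:7, 2:4, 2:4] <- 2L
  img <- label_image(arr, spacing = 1, tags = c("1" = "a", "2" = "b"))
  sa <- extract_tag_surface(img, 1)
  sb <- extract_tag_surface(img, 2)
  shared <- count_coincident_faces(sa, sb)
  expect_gt(shared, 0L)
  merged <- merge_tag_surfaces(list(sa, sb), image = img)
  expect_identical(nrow(merged$faces),
                   nrow(sa$faces) + nrow(sb$faces) - shared)
  expect_identical(sum(merged$face_labels[, 1] == 1L &
                         merged$face_labels[, 2] == 2L), shared)
})

test_that("phantom LV/RV interface faces equal the brute-force pair count", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  s1 <- extract_tag_surface(ph, 1)
  s2 <- extract_tag_surface(ph, 2)
  shared <- count_coincident_faces(s1, s2)
  merged <- extract_surfaces(ph, tags = c(1, 2))
  n12 <- sum(merged$face_labels[, 1] == 1L & merged$face_labels[, 2] == 2L)
  expect_gt(n12, 0L)
  expect_identical(n12, shared)
})

test_that("per-tag surfaces of the merged phantom are closed and oriented", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  merged <- extract_surfaces(ph)
  expect_true(check_surface_closed(merged))
  for (tag in 1:5)
    expect_gt(surface_measures(merged, tag)$volume, 0)
})

test_that("surface export writers produce parseable files", {
  s <- extract_tag_surface(single_voxel_image(), 1)
  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, stl)
  txt <- readLines(stl)
  expect_identical(sum(grepl("^facet normal", txt)), nrow(s$faces))
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_surface(s, vtk)
  txt <- readLines(vtk)
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(s$vertices)), txt)))
  expect_true(any(grepl("SCALARS tag_inner int 1", txt)))
})
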