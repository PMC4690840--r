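test_that("blocky extract -> rasterize at source spacing is the identity", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  sb <- extract_surfaces(ph, mode = "blocky")
  r <- rasterize_surfaces(sb, target_spacing = ph$spacing,
                          bounds = list(lower = ph$origin,
                                        upper = ph$origin +
                                          dim(ph$voxels) * ph$spacing))
  expect_identical(r$voxels, ph$voxels)
  expect_identical(r$tags, ph$tags)
})

test_that("analytic-sphere surface rasterized at 0.25 mm recovers the volume", {
  img <- sphere_image(10, 0.5)
  s <- merge_tag_surfaces(list(extract_tag_surface(img, 1)), image = img)
  r <- rasterize_surfaces(s, 0.25)
  v <- sum(r$voxels == 1L) * 0.25^3
  v_true <- 4 / 3 * pi * 1000
  expect_lt(abs(v - v_true) / v_true, 0.01)
})

test_that("tenfold upsampling preserves per-tag topology", {
  # well-resolved regions only: a one-voxel-thick base cap can legitimately
  # pinch under half-voxel smoothing, so it is left off here
  ph <- make_biventricular_phantom(phantom_spec(rv_outer_radii = NULL,
                                                spacing = 2,
                                                base_cap = FALSE))
  s <- extract_surfaces(ph)
  sm <- smooth_surface(s, ph$spacing)
  hi <- rasterize_surfaces(sm$surface, 0.2)
  expect_gt(prod(dim(hi$voxels)) / prod(dim(ph$voxels)), 900)
  for (tag in as.integer(names(ph$tags)))
    expect_identical(connected_components(hi, tag)$n,
                     connected_components(ph, tag)$n)
})

test_that("per-tag volume change is bounded by the half-voxel surface shell", {
  ph <- make_biventricular_phantom(small_phantom_spec())
  s <- extract_surfaces(ph)
  sm <- smooth_surface(s, ph$spacing)
  hi <- rasterize_surfaces(sm$surface, 1)
  for (tag in 1:4) {
    shell <- surface_measures(s, tag)$area * 0.5 * max(ph$spacing)
    dv <- abs(tag_volume(hi, tag) - tag_volume(ph, tag))
    expect_lt(dv, shell)
  }
})

test_that("smoothing brings the upsampled boundary closer to the analytic surface", {
  spec <- phantom_spec(rv_outer_radii = NULL, noise_probability = 0.2,
                       seed = 7)
  ph <- make_biventricular_phantom(spec)
  an <- attr(ph, "analytic")
  s0 <- extract_surfaces(ph)
  sm <- smooth_surface(s0, ph$spacing)
  mean_bd <- function(surface) {
    r <- rasterize_surfaces(surface, 0.5)
    sr <- extract_tag_surface(r, 1)
    v <- sr$vertices
    keep <- v[, 3] < an$base_plane_z - 1.5 &
      ellipsoid_distance(v, an$lv_inner$radii, an$lv_inner$center) > 1.5
    mean(abs(ellipsoid_distance(v[keep, , drop = FALSE],
                                an$lv_outer$radii, an$lv_outer$center)))
  }
  expect_lt(mean_bd(sm$surface), mean_bd(s0))
})

test_that("degenerate bounds and open surfaces are rejected", {
  img <- single_voxel_image()
  s <- merge_tag_surfaces(list(extract_tag_surface(img, 1)), image = img)
  expect_error(rasterize_surfaces(s, 0.5,
                                  bounds = list(lower = c(0, 0, 0),
                                                upper = c(1, 1, 0))),
               "degenerate bounds")
  open_s <- s
  open_s$faces <- s$faces[-1, , drop = FALSE]
  open_s$face_labels <- s$face_labels[-1, , drop = FALSE]
  expect_error(rasterize_surfaces(open_s, 0.5), "not closed")
})
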