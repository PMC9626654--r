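make_scene <- function(spacing = 0.5) {
  s <- lesion_spec(1, A = 8, B = 10, C = 4, D = 2)
  rasterize_scene(wall_model(10, c(16, 16)), list(s), spacing)
}

test_that("noise-free rendering is piecewise constant with three levels", {
  sc <- make_scene()
  img <- render_mri(sc$mask, border_width = 1, noise_sd = 0)
  expect_setequal(unique(as.vector(img$values)), c(0.9, 0.15, 0.55))
  ## border rim voxels exist and wrap the core
  expect_gt(sum(img$values == 0.15), 0)
  img0 <- render_mri(sc$mask, border_width = 0, noise_sd = 0)
  expect_setequal(unique(as.vector(img0$values)), c(0.9, 0.55))
})

test_that("rendering is bit-reproducible for a fixed seed", {
  sc <- make_scene()
  i1 <- render_mri(sc$mask, noise_sd = 0.05, seed = 77)
  i2 <- render_mri(sc$mask, noise_sd = 0.05, seed = 77)
  expect_identical(i1, i2)
  i3 <- render_mri(sc$mask, noise_sd = 0.05, seed = 78)
  expect_false(identical(i1$values, i3$values))
  expect_error(render_mri(sc$mask, noise_sd = 0.05), "seed")
})

test_that("isointense lesions are invisible to detection", {
  sc <- make_scene()
  flat <- c(core = 0.55, border = 0.55, myocardium = 0.55)
  img <- render_mri(sc$mask, flat, border_width = 1, noise_sd = 0.02, seed = 5)
  det <- detect_lesions(img, min_contrast = 0.15, min_size = 2)
  expect_true(all(det$labels == 0L))
})

test_that("thick-slice sectioning exposes the expected faces", {
  ## lesion spanning 9 mm along z, cut perpendicular to z in 3-mm slabs:
  ## faces at 0, 3, 6 mm -> on at most 3 consecutive faces
  s <- lesion_spec(1, A = 9, B = 10, C = 4, D = 2)
  sc <- rasterize_scene(wall_model(9, c(16, 16)), list(s), 0.5)
  stk <- emulate_patho(sc$mask, 3, slice_axis = "z")
  hit <- vapply(stk$faces, function(f) any(f > 0), logical(1))
  expect_lte(sum(hit), 3L)
  expect_equal(stk$face_positions, c(0, 3, 6))
  ## 5-mm slabs on an 8-mm-deep lesion -> 2 faces
  s8 <- lesion_spec(1, A = 8, B = 10, C = 4, D = 2)
  sc8 <- rasterize_scene(wall_model(8, c(16, 16)), list(s8), 0.5)
  stk8 <- emulate_patho(sc8$mask, 5, slice_axis = "z")
  expect_equal(sum(vapply(stk8$faces, function(f) any(f > 0), logical(1))), 2L)
})

test_that("slab thickness is confined to the sectioning range", {
  sc <- make_scene()
  expect_error(emulate_patho(sc$mask, 2.5), "\\[3, 5\\]")
  expect_error(emulate_patho(sc$mask, 5.5), "\\[3, 5\\]")
})

test_that("face cross-sections never exceed the analytic axial section", {
  s <- lesion_spec(1, A = 9, B = 11, C = 5, D = 2)
  sc <- rasterize_scene(wall_model(10, c(18, 18)), list(s), 0.25)
  ## analytic area of the plane through the axis: integral of 2 r(z) dz
  a_max <- 2 * integrate(function(z) radius_profile(s, z), 0, 9,
                         subdivisions = 400)$value
  areas <- function(t) {
    stk <- emulate_patho(sc$mask, t, slice_axis = "x")
    max(vapply(stk$faces, function(f) sum(f > 0), numeric(1))) *
      prod(stk$in_plane_spacing)
  }
  a3 <- areas(3); a5 <- areas(5)
  expect_lte(a3, a_max * 1.02)
  expect_lte(a5, a_max * 1.02)
})

test_that("an offset first cut shortens the first slab only", {
  sc <- make_scene()
  stk <- emulate_patho(sc$mask, 3, slice_axis = "z", offset = 1.2)
  widths <- stk$slab_ends - stk$slab_starts
  expect_equal(widths[1], 1.2)
  expect_true(all(abs(widths[-c(1, length(widths))] - 3) < 1e-9))
})
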