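## small hand-built masks -----------------------------------------------------

box_mask <- function(nx, ny, nz, spacing = 1, at = NULL) {
  a <- array(0L, c(max(nx, 12L), max(ny, 12L), max(nz, 6L)))
  a[seq_len(nx), seq_len(ny), seq_len(nz)] <- 1L
  lesion_mask(a, spacing)
}

test_that("depth of a single surface voxel spans one voxel", {
  a <- array(0L, c(5, 5, 4))
  a[3, 3, 1] <- 1L
  m <- lesion_mask(a, 1)
  surf <- surface_ref(plane_z = 0)
  expect_equal(measure_depth(m, surf), 1.0)  # voxel spans [0, 1)
  expect_equal(as.numeric(measure_estuary(m, surf)), 1.0)
  bc <- measure_width_and_C(m, surf)
  expect_equal(unname(bc["B"]), 1.0)  # single voxel: one voxel extent
  expect_equal(unname(bc["C"]), 0.5)  # that voxel's centre depth
})

test_that("an axis-aligned bar is measured exactly", {
  m <- box_mask(11, 1, 4)  # 11 voxels wide: caliper + one voxel extent = 11
  surf <- surface_ref()
  bc <- measure_width_and_C(m, surf)
  expect_equal(unname(bc["B"]), 11.0)
  ## uniformly wide over depth: C reported at the middle of the tied run
  expect_equal(unname(bc["C"]), mean(c(0.5, 1.5, 2.5, 3.5)))
  expect_equal(measure_depth(m, surf), 4.0)
})

test_that("masks above the endocardial plane are rejected", {
  a <- array(0L, c(4, 4, 4)); a[2, 2, 1:2] <- 1L
  m <- lesion_mask(a, 1)
  expect_error(measure_depth(m, surface_ref(plane_z = 10)), "above")
  expect_error(measure_depth(m, surface_ref(plane_z = 0), label = 5),
               "empty")
})

test_that("a lesion detached from the surface has estuary 0, flagged", {
  a <- array(0L, c(6, 6, 6)); a[2:4, 2:4, 3:5] <- 1L
  m <- lesion_mask(a, 1)
  d <- measure_estuary(m, surface_ref())
  expect_equal(as.numeric(d), 0)
  expect_false(attr(d, "reaches_surface"))
})

test_that("hemi-ellipsoid lesions have estuary close to width", {
  s <- lesion_spec(1, A = 8, B = 9, C = 0.9, D = 9)
  sc <- raster_phantom(s, 0.2, jitter = FALSE)
  rec <- measure_lesion(sc$mask, surface_ref(), "full3d")
  expect_equal(rec$D, rec$B, tolerance = 0.05)
})

test_that("width equals a brute-force per-layer Feret oracle on small masks", {
  set.seed(31)
  surf <- surface_ref()
  for (i in 1:20) {
    a <- array(0L, c(15, 15, 8))
    n <- sample(20:80, 1)
    idx <- cbind(sample(15, n, TRUE), sample(15, n, TRUE), sample(8, n, TRUE))
    a[idx] <- 1L
    sp <- c(0.7, 0.7, 0.5)
    m <- lesion_mask(a, sp)
    got <- measure_width_and_C(m, surf)[["B"]]
    ## oracle: exhaustive max pairwise centre distance per layer + 1 voxel
    ai <- which(a == 1L, arr.ind = TRUE)
    oracle <- max(vapply(split.data.frame(ai, ai[, 3]), function(layer) {
      p <- sweep(layer[, 1:2, drop = FALSE] - 0.5, 2, sp[1:2], `*`)
      max(sqrt(outer(p[, 1], p[, 1], `-`)^2 +
               outer(p[, 2], p[, 2], `-`)^2)) + sp[1]
    }, numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("dilation never decreases depth, width or estuary", {
  set.seed(17)
  surf <- surface_ref()
  for (i in 1:10) {
    a <- array(0L, c(14, 14, 10))
    ctr <- c(sample(5:10, 2, TRUE), sample(2:5, 1))
    idx <- which(array(TRUE, dim(a)))
    ai <- arrayInd(idx, dim(a))
    ball <- rowSums(sweep(ai, 2, ctr, `-`)^2) <= sample(4:9, 1)
    a[idx[ball]] <- 1L
    m <- lesion_mask(a, 0.8)
    dil <- m
    dil$labels[rflesion:::dilate_mm(m$labels > 0, m$spacing, 0.9)] <- 1L
    r0 <- measure_lesion(m, surf, "full3d")
    r1 <- measure_lesion(dil, surf, "full3d")
    expect_gte(r1$A, r0$A)
    expect_gte(r1$B, r0$B)
    expect_gte(r1$D, r0$D)
  }
})

test_that("the restricted slice never widens the lesion", {
  set.seed(23)
  surf <- surface_ref()
  for (i in 1:50) {
    sp <- rand_spec()
    sc <- raster_phantom(sp, c(0.8, 0.4, 0.4))
    ## anisotropic in-plane spacing deliberately triggers the extent warning
    f3 <- suppressWarnings(measure_lesion(sc$mask, surf, "full3d"))
    f2 <- measure_lesion(sc$mask, surf, "slice2d", "x")
    expect_lte(f2$B, f3$B + 1e-9)
  }
})

test_that("the maximum-parameter slice is found", {
  s <- lesion_spec(1, A = 9, B = 10, C = 4, D = 2)
  sc <- raster_phantom(s, 0.5, jitter = FALSE)
  dims <- dim(sc$mask$labels)
  ## solid of revolution: the slice through the axis has the largest section
  for (ax in c("x", "y")) {
    k <- select_max_slice(sc$mask, ax)
    centre <- (dims[rflesion:::axis_index(ax)] + 1) / 2
    expect_lte(abs(k - centre), 1)
  }
  ## a one-slice lesion selects that slice
  a <- array(0L, c(8, 8, 8)); a[5, 2:6, 2:5] <- 1L
  m1 <- lesion_mask(a, 1)
  expect_equal(select_max_slice(m1, "x"), 5L)
  expect_error(select_max_slice(lesion_mask(array(0L, c(4, 4, 4)), 1), "x"),
               "empty")
})

test_that("slice2d mode requires a lateral slicing axis", {
  s <- lesion_spec(1, A = 8, B = 9, C = 4, D = 2)
  sc <- raster_phantom(s, 0.5, jitter = FALSE)
  expect_error(measure_lesion(sc$mask, surface_ref(), "slice2d", "z"),
               "lateral")
})

test_that("detection recovers a rendered lesion with high overlap", {
  s <- lesion_spec(1, A = 9, B = 11, C = 5, D = 2)
  sc <- rasterize_scene(wall_model(12, c(18, 18)), list(s), 0.4)
  img <- render_mri(sc$mask, border_width = 0, noise_sd = 0.02, seed = 3)
  det <- detect_lesions(img, min_contrast = 0.15, min_size = 2)
  truth <- sc$mask$labels > 0L
  got <- det$labels == 1L
  dice <- 2 * sum(truth & got) / (sum(truth) + sum(got))
  expect_gte(dice, 0.95)
  ## a min_size above the lesion volume suppresses detection
  det2 <- detect_lesions(img, 0.15, min_size = 2 * voxel_volume(sc$mask))
  expect_true(all(det2$labels == 0L))
})

test_that("thick-slice face measurement matches the slice measurement", {
  s <- lesion_spec(1, A = 9, B = 11, C = 5, D = 2)
  sc <- rasterize_scene(wall_model(10, c(18, 18)), list(s), 0.3)
  surf <- surface_ref()
  ## a 3-mm stack whose face passes through the axis
  off <- (0 - sc$mask$origin[1]) %% 3
  stk <- emulate_patho(sc$mask, 3, "x", offset = off)
  rec <- measure_patho_stack(stk, surf)
  f3 <- measure_lesion(sc$mask, surf, "full3d")
  expect_lt(abs(rec$A - f3$A), 0.35)
  expect_lt(abs(rec$B - f3$B), 0.45)
  expect_error(measure_patho_stack(stk, surf, label = 9), "not visible")
})
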