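test_that("formula volume evaluates its closed form", {
  expect_equal(formula_volume(0, 0, 0, 0), 0)
  expect_equal(formula_volume(10, 10, 5, 0), 0.75 * pi * 25 * 5)  # 294.524
  expect_equal(formula_volume(10, 10, 5, 0), 294.5243, tolerance = 1e-6)
  expect_error(formula_volume(-1, 10, 5, 0), "non-negative")
  ## inconsistent observer dims (D > B) can flip the sign; the value is
  ## returned as-is with a warning, never clamped
  expect_warning(v <- formula_volume(10, 1, 1, 10), "negative")
  expect_lt(v, 0)
})

test_that("polygon slice summation uses the shoelace area", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(as.numeric(pointbypoint_volume(list(sq), 1)), 100)
  tri <- cbind(c(0, 4, 0), c(0, 0, 3))
  expect_equal(as.numeric(pointbypoint_volume(list(tri, tri), 2)), 24)
  bow <- cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))  # self-intersecting
  expect_error(pointbypoint_volume(list(bow), 1), "self-intersect")
  expect_error(pointbypoint_volume(list(), 1), "at least one")
})

test_that("mask-mode summation over native slices is the voxel volume", {
  set.seed(5)
  for (i in 1:5) {
    sp <- rand_spec(i)
    sc <- raster_phantom(sp, c(0.5, 0.5, 0.4))
    for (ax in c("x", "z")) {
      v <- pointbypoint_volume(sc$mask, axis = ax, label = sp$lesion_id)
      expect_identical(as.numeric(v), voxel_volume(sc$mask, sp$lesion_id))
    }
  }
})

test_that("slice summation at fine spacing approaches the true volume", {
  s <- lesion_spec(1, A = 9, B = 11, C = 5, D = 2)
  sc <- raster_phantom(s, 0.2, jitter = FALSE)
  v <- as.numeric(pointbypoint_volume(sc$mask, axis = "z"))
  expect_equal(v, s$V_true, tolerance = 0.02)
})

test_that("voxel volume is count times voxel size", {
  a <- array(0L, c(20, 10, 10)); a[1:10, 1:10, 1:10] <- 1L
  m <- lesion_mask(a, 0.5)
  expect_equal(voxel_volume(m), 1000 * 0.125)
  expect_equal(voxel_volume(lesion_mask(array(0L, c(3, 3, 3)), 1)), 0)
})

test_that("Cavalieri subsampling error shrinks toward the exact sum", {
  set.seed(11)
  err <- sapply(1:10, function(i) {
    sp <- rand_spec(i)
    sc <- raster_phantom(sp, 0.4)
    v0 <- voxel_volume(sc$mask, sp$lesion_id)
    vapply(c(1L, 2L, 5L), function(k) {
      abs(as.numeric(pointbypoint_volume(sc$mask, axis = "z", every = k,
                                         label = sp$lesion_id)) - v0) / v0
    }, numeric(1))
  })
  expect_true(all(err[1, ] == 0))            # exact at native sampling
  expect_lt(mean(err[2, ]), mean(err[3, ]))  # k = 2 beats k = 5 on average
})

test_that("formula error on smooth lesions stays within the frozen band", {
  ## the closed formula approximates the ovoid-with-neck family from below;
  ## its relative error over the valid dimension region has supremum ~0.94
  ## (grid search; attained as C -> A with a minimal estuary), with typical
  ## cohort draws around 0.45 - frozen here as a regression guard
  set.seed(77)
  err <- vapply(1:60, function(i) {
    s <- rand_spec()
    abs(formula_volume(s$A, s$B, s$C, s$D) - s$V_true) / s$V_true
  }, numeric(1))
  expect_lt(max(err), 0.95)
  expect_gt(median(err), 0.25)  # the underestimate is systematic, not noise
  expect_lt(median(err), 0.60)
})
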