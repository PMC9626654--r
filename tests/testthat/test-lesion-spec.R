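test_that("radius profile matches the landmark dimensions", {
  s <- lesion_spec(1, A = 10, B = 10, C = 5, D = 2)
  expect_equal(radius_profile(s, 5), 5.0)    # r(C) = B/2
  expect_equal(radius_profile(s, 0), 1.0)    # r(0) = D/2
  expect_equal(radius_profile(s, 10), 0.0)   # apex
  expect_equal(radius_profile(s, -1), 0.0)
  expect_equal(radius_profile(s, 11), 0.0)
})

test_that("r(C) is the maximum B/2 for random valid specs", {
  set.seed(101)
  for (i in 1:100) {
    d <- draw_dims()
    s <- lesion_spec(i, d[["A"]], d[["B"]], d[["C"]], d[["D"]])
    z <- seq(0, s$A, length.out = 801)
    r <- radius_profile(s, z)
    expect_lte(max(r), s$B / 2 + 1e-12)
    expect_equal(radius_profile(s, s$C), s$B / 2)
    ## continuity: no jump exceeds what the profile slope allows
    expect_lt(max(abs(diff(r))), s$B)
  }
})

test_that("invalid specs are rejected", {
  expect_error(lesion_spec(1, A = 5, B = 10, C = 6, D = 2), "C < A")
  expect_error(lesion_spec(1, A = 5, B = 10, C = 5, D = 2), "C < A")
  expect_error(lesion_spec(1, A = 5, B = 10, C = 2, D = 12), "D <= B")
  expect_error(lesion_spec(1, A = -1, B = 10, C = 2, D = 2))
})

test_that("true volume approaches the hemi-ellipsoid in the D=B, C->0 limit", {
  B <- 10; A <- 10
  s <- lesion_spec(1, A, B, C = 0.01, D = B)
  expect_equal(s$V_true, (2 / 3) * pi * (B / 2)^2 * A, tolerance = 0.005)
})

test_that("true volume reduces to the lower body as A -> C", {
  d <- c(A = 9, B = 11.1, C = 4.8, D = 2)
  s <- lesion_spec(1, d[["C"]] + 1e-3, d[["B"]], d[["C"]], d[["D"]])
  lower <- pi * integrate(function(z) radius_profile(s, z)^2, 0, d[["C"]],
                          subdivisions = 400)$value
  expect_equal(s$V_true, lower, tolerance = 1e-3)
})

test_that("quadrature volume agrees with an independent voxel count", {
  s <- lesion_spec(1, A = 10, B = 10, C = 5, D = 2)
  ## independent brute-force voxelization on a fine grid
  sp <- 0.1
  xs <- seq(-6 + sp / 2, 6, by = sp)
  zs <- seq(sp / 2, 10, by = sp)
  r2 <- radius_profile(s, zs)^2
  rho2 <- outer(xs^2, xs^2, `+`)
  count <- sum(vapply(r2, function(r) sum(rho2 <= r), numeric(1)))
  expect_equal(count * sp^3, s$V_true, tolerance = 0.01)
})

test_that("steam-pop perturbation behaves as specified", {
  s <- lesion_spec(1, A = 9, B = 11.1, C = 4.8, D = 2)
  expect_identical(perturb_steam_pop(s, 0, 3, seed = 1), s)  # identity
  p1 <- perturb_steam_pop(s, 0.5, 3, seed = 42)
  p2 <- perturb_steam_pop(s, 0.5, 3, seed = 42)
  expect_identical(p1, p2)                                   # determinism
  expect_gt(p1$V_true, s$V_true)   # positive modulation adds volume
  expect_gt(p1$B_true, s$B_true)   # rupture spreads the width...
  expect_identical(p1$A_true, s$A_true)  # ...but not the depth
  expect_identical(p1$D_true, s$D_true)  # estuary untouched
  expect_error(perturb_steam_pop(s, 1.5, 3, 1), "amplitude")
  expect_error(perturb_steam_pop(s, 0.5, 0, 1), "n_lobes")
})

test_that("perturbed quadrature volume matches a voxelization oracle", {
  s <- perturb_steam_pop(lesion_spec(1, 9, 11.1, 4.8, 2), 0.5, 3, seed = 9)
  sp <- 0.1
  xs <- seq(-10 + sp / 2, 10, by = sp)
  zs <- seq(sp / 2, 9, by = sp)
  g <- expand.grid(x = xs, y = xs)
  rho <- sqrt(g$x^2 + g$y^2)
  th <- atan2(g$y, g$x)
  count <- 0
  for (z in zs) {
    r <- lesion_radius(s, rep(z, nrow(g)), th)
    count <- count + sum(rho <= r)
  }
  expect_equal(count * sp^3, s$V_true, tolerance = 0.02)
})
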