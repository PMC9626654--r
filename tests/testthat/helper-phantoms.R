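## shared fixtures: cohort-range dimension draws and local phantom rasters

draw_dims <- function() {
  repeat {
    A <- rnorm(1, 9.008, 2.823)
    B <- rnorm(1, 11.125, 2.801)
    C <- rnorm(1, 4.783, 1.648)
    D <- rnorm(1, 2.001, 0.872)
    if (A > 3.2 && A < 15.5 && B > 4.5 && B < 17.5 &&
        C > 0.8 && C < A - 0.8 && D > 0.3 && D < B - 1)
      return(c(A = A, B = B, C = C, D = D))
  }
}

rand_spec <- function(id = 1L) {
  d <- draw_dims()
  lesion_spec(id, d[["A"]], d[["B"]], d[["C"]], d[["D"]])
}

## rasterize one lesion on a local grid with random sub-voxel alignment
raster_phantom <- function(spec, spacing, margin = 3, jitter = TRUE) {
  spacing <- rep_len(spacing, 3L)
  ext <- 2 * ceiling(spec$B / 2 * 1.6 + margin)
  if (jitter)
    spec$contact_point <- runif(2, -spacing[1:2] / 2, spacing[1:2] / 2)
  wall <- wall_model(max(16, ceiling(spec$A) + 1), c(ext, ext))
  rasterize_scene(wall, list(spec), spacing)
}

## balanced measurement table: n lesions x 2 methods x n_obs x n_rep,
## value = lesion intercept + optional fixed effects + residual noise
balanced_records <- function(n_lesions, method_effect = 0, observer_effect = 0,
                             sd_lesion = 2, sd_noise = 0.3,
                             n_obs = 2L, n_rep = 3L) {
  base <- rnorm(n_lesions, 9, sd_lesion)
  grid <- expand.grid(lesion_id = seq_len(n_lesions),
                      method = c("mri", "patho"),
                      observer_id = seq_len(n_obs),
                      repeat_index = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  grid$A <- base[grid$lesion_id] +
    method_effect * (grid$method == "patho") +
    observer_effect * (grid$observer_id == 2L) +
    rnorm(nrow(grid), 0, sd_noise)
  grid
}
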