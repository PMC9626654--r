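#' Rasterize lesions into a labelled voxel grid
#'
#' Builds a [lesion_mask()] covering the wall slab and labels every voxel
#' whose centre lies inside a lesion solid. Overlapping (fused) lesions are
#' resolved in favour of the lowest lesion id. The accompanying ground-truth
#' table records the exact per-lesion dimensions and volume.
#'
#' The grid spans the wall's lateral extent (centred on the origin) and
#' `0 <= z <= wall_thickness`; the voxel-centre convention of
#' [volume_image()] applies.
#'
#' @param wall a [wall_model()].
#' @param specs list of [lesion_spec()]s (pairwise valid; ids unique).
#' @param spacing voxel spacing in mm, scalar or length 3 (dx, dy, dz).
#' @return list with components `mask` (a `lesion_mask` whose labels are the
#'   lesion ids) and `truth` (data.frame with columns `lesion_id`,
#'   `heart_id`, `A_true`, `B_true`, `C_true`, `D_true`, `V_true`,
#'   `perturbation`).
#' @export
rasterize_scene <- function(wall, specs, spacing) {
  stopifnot(inherits(wall, "wall_model"), is.list(specs))
  if (inherits(specs, "lesion_spec")) specs <- list(specs)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  ids <- vapply(specs, function(s) s$lesion_id, integer(1))
  if (anyDuplicated(ids)) stop("lesion ids must be unique")
  specs <- specs[order(ids)]

  Lx <- wall$lateral_extent[1]; Ly <- wall$lateral_extent[2]
  origin <- c(-Lx / 2, -Ly / 2, 0)
  dims <- c(max(1L, round(Lx / spacing[1])),
            max(1L, round(Ly / spacing[2])),
            max(1L, ceiling(wall$wall_thickness / spacing[3])))
  labels <- array(0L, dims)
  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]

  for (spec in specs) {
    rmax <- max_lateral_radius(spec)
    if (spec$A_true > wall$wall_thickness)
      stop(sprintf("lesion %d (depth %.2f mm) extends beyond the %.2f mm wall",
                   spec$lesion_id, spec$A_true, wall$wall_thickness))
    cp <- spec$contact_point
    if (abs(cp[1]) + rmax > Lx / 2 || abs(cp[2]) + rmax > Ly / 2)
      stop(sprintf("lesion %d extends outside the lateral wall extent",
                   spec$lesion_id))
    ix <- which(abs(xs - cp[1]) <= rmax + spacing[1])
    iy <- which(abs(ys - cp[2]) <= rmax + spacing[2])
    iz <- which(zs >= 0 & zs <= spec$A)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dxm <- matrix(xs[ix] - cp[1], length(ix), length(iy))
    dym <- matrix(ys[iy] - cp[2], length(ix), length(iy), byrow = TRUE)
    rho <- sqrt(dxm^2 + dym^2)
    perturbed <- !is.null(spec$perturbation) &&
      identical(spec$perturbation$type, "steam_pop")
    theta <- if (perturbed) atan2(dym, dxm)
    for (k in iz) {
      r <- radius_profile(spec, zs[k])
      if (r <= 0) next
      inside <- if (perturbed) {
        rho <= r * steam_pop_modulation(spec$perturbation, spec$A, zs[k], theta)
      } else rho <= r
      if (!any(inside)) next
      sub <- labels[ix, iy, k]
      sub[inside & sub == 0L] <- spec$lesion_id  # lowest id wins
      labels[ix, iy, k] <- sub
    }
  }

  truth <- do.call(rbind, lapply(specs, function(s) {
    data.frame(lesion_id = s$lesion_id, heart_id = s$heart_id,
               A_true = s$A_true, B_true = s$B_true,
               C_true = s$C_true, D_true = s$D_true, V_true = s$V_true,
               perturbation = perturbation_label(s))
  }))
  if (is.null(truth))
    truth <- data.frame(lesion_id = integer(), heart_id = integer(),
                        A_true = numeric(), B_true = numeric(),
                        C_true = numeric(), D_true = numeric(),
                        V_true = numeric(), perturbation = character())
  list(mask = lesion_mask(labels, spacing, origin), truth = truth)
}

max_lateral_radius <- function(spec) {
  p <- spec$perturbation
  amp <- if (!is.null(p) && identical(p$type, "steam_pop")) p$amplitude else 0
  (spec$B / 2) * (1 + amp)
}

perturbation_label <- function(spec) {
  p <- spec$perturbation
  base <- if (is.null(p)) "none"
  else sprintf("steam_pop(a=%.2f,lobes=%d,seed=%d)",
               p$amplitude, p$n_lobes, p$seed)
  if (!is.null(spec$fused_with))
    base <- paste0(base, sprintf("+fused(%d)", spec$fused_with))
  base
}
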