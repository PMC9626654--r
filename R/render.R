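#' Render an MRI-like grayscale volume from a lesion mask
#'
#' Emulates the appearance of ablation lesions on ex vivo proton-density
#' weighted images: the necrotic core is rendered at `core` intensity, a rim
#' of `border_width` mm around it at the (darkest) `border` intensity - the
#' low-signal border zone that delineates lesions on such scans - and the
#' remaining myocardium at `myocardium` intensity, with optional additive
#' Gaussian noise. Intensities are arbitrary units; only their contrasts
#' matter for detection.
#'
#' The border rim is the exact Euclidean dilation of the lesion by
#' `border_width` mm (an ellipsoidal structuring element in voxel units,
#' so anisotropic spacing is handled), minus the lesion itself.
#'
#' @param mask a [lesion_mask()].
#' @param contrast named numeric with entries `core`, `border`, `myocardium`
#'   (non-negative).
#' @param border_width border-zone thickness in mm (>= 0; 0 disables the rim).
#' @param noise_sd standard deviation of additive Gaussian noise (0 for a
#'   noise-free, piecewise-constant image).
#' @param seed integer seed making the noise reproducible; required when
#'   `noise_sd > 0`.
#' @return A [volume_image()] congruent with `mask`.
#' @export
render_mri <- function(mask,
                       contrast = c(core = 0.9, border = 0.15,
                                    myocardium = 0.55),
                       border_width = 1.0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  need <- c("core", "border", "myocardium")
  if (!all(need %in% names(contrast)) || any(contrast[need] < 0))
    stop("contrast must supply non-negative core, border and myocardium")
  if (border_width < 0) stop("border_width must be >= 0")
  core <- mask$labels > 0L
  vals <- array(contrast[["myocardium"]], dim(mask$labels))
  if (border_width > 0) {
    rim <- dilate_mm(core, mask$spacing, border_width) & !core
    vals[rim] <- contrast[["border"]]
  }
  vals[core] <- contrast[["core"]]
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    noise <- withr::with_seed(as.integer(seed),
                              stats::rnorm(length(vals), 0, noise_sd))
    vals <- vals + array(noise, dim(vals))
  }
  volume_image(vals, mask$spacing, mask$origin)
}

## binary dilation by a Euclidean ball of radius `radius_mm`
dilate_mm <- function(a, spacing, radius_mm) {
  nmax <- pmin(floor(radius_mm / spacing), dim(a) - 1L)
  offs <- expand.grid(ox = -nmax[1]:nmax[1], oy = -nmax[2]:nmax[2],
                      oz = -nmax[3]:nmax[3])
  keep <- (offs$ox * spacing[1])^2 + (offs$oy * spacing[2])^2 +
    (offs$oz * spacing[3])^2 <= radius_mm^2
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offs)))
    out <- out | shift3d(a, c(offs$ox[i], offs$oy[i], offs$oz[i]))
  out
}

## shift a logical array by integer offset o (out[x + o] = a[x])
shift3d <- function(a, o) {
  d <- dim(a)
  dst <- lapply(1:3, function(i) max(1L, 1L + o[i]):min(d[i], d[i] + o[i]))
  if (any(vapply(1:3, function(i) o[i] >= d[i] || o[i] <= -d[i], logical(1))))
    return(array(FALSE, d))
  src <- lapply(1:3, function(i) dst[[i]] - o[i])
  out <- array(FALSE, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Emulate gross-pathology sectioning of a specimen
#'
#' Partitions the volume along `slice_axis` into consecutive slabs of the
#' given thickness - the 3-5 mm hand-cut sections produced on a macrotome
#' before photographing - and returns the lesion cross-section exposed on
#' each slab's proximal cut face, together with the mm-per-pixel calibration
#' that a photographed 1-cm caliper would provide.
#'
#' Slabs are half-open intervals `[k t, (k+1) t)` starting at
#' `origin + offset`; when `offset > 0` the first slab is correspondingly
#' thinner, and the final slab may be thinner than `t` (a real specimen
#' rarely divides evenly). The imaged face of each slab is its proximal cut
#' face (the first voxel layer whose centre lies in the slab); distal faces
#' are the same planes indexed from the following slab.
#'
#' @param mask a [lesion_mask()].
#' @param slice_thickness slab thickness in mm, within `[3, 5]` (the
#'   gross-sectioning convention this emulates).
#' @param slice_axis axis to cut along ("x", "y" or "z", or 1:3).
#' @param offset position of the first cut relative to the volume start, in
#'   `[0, slice_thickness)` mm.
#' @return An object of class `patho_stack`: a list with `faces` (2D integer
#'   label matrices), `face_positions` (mm along the cut axis),
#'   `slab_starts`/`slab_ends`, `axis`, `in_plane_axes`, `in_plane_spacing`,
#'   `in_plane_origin`, `slice_thickness`, and `calibration`
#'   (`mm_per_px` per in-plane axis, from the emulated 1-cm caliper).
#' @export
emulate_patho <- function(mask, slice_thickness, slice_axis = "x",
                          offset = 0) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (slice_thickness < 3 || slice_thickness > 5)
    stop("slice_thickness must lie in [3, 5] mm, the gross-sectioning range")
  ax <- axis_index(slice_axis)
  sp <- mask$spacing[ax]
  n <- dim(mask$labels)[ax]
  len <- n * sp
  if (offset < 0 || offset >= slice_thickness)
    stop("offset must lie in [0, slice_thickness)")
  cuts <- offset + slice_thickness * (0:ceiling(len / slice_thickness))
  cuts <- cuts[cuts < len - 1e-9]
  starts <- sort(unique(c(0, cuts)))
  ends <- c(starts[-1], len)
  ## proximal face layer: first voxel layer whose centre is inside the slab
  face_layer <- pmin(n, floor(starts / sp + 0.5 - 1e-9) + 1L)
  inplane <- setdiff(1:3, ax)
  faces <- lapply(face_layer, function(k) {
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[ax]] <- k
    do.call(`[`, c(list(mask$labels), idx, list(drop = TRUE)))
  })
  structure(list(faces = faces,
                 face_positions = mask$origin[ax] + starts,
                 slab_starts = mask$origin[ax] + starts,
                 slab_ends = mask$origin[ax] + ends,
                 axis = ax,
                 in_plane_axes = inplane,
                 in_plane_spacing = mask$spacing[inplane],
                 in_plane_origin = mask$origin[inplane],
                 slice_thickness = slice_thickness,
                 calibration = list(mm_per_px = mask$spacing[inplane],
                                    caliper_mm = 10)),
            class = "patho_stack")
}

#' @export
print.patho_stack <- function(x, ...) {
  cat(sprintf(
    "<patho_stack> %d faces, %.1f mm slabs along axis %d, %.3g x %.3g mm/px\n",
    length(x$faces), x$slice_thickness, x$axis,
    x$in_plane_spacing[1], x$in_plane_spacing[2]))
  invisible(x)
}
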