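#' Detect lesions in a grayscale volume
#'
#' Emulates lesion recognizability: voxels whose intensity differs from the
#' myocardial background (the volume median) by at least `min_contrast` are
#' grouped into 26-connected components, and components smaller than
#' `min_size` mm^3 are discarded. Lesions whose core is isointense with
#' myocardium ("ghost" lesions) are therefore not detected at any threshold
#' above the noise floor.
#'
#' Components are labelled 1, 2, ... in order of decreasing voxel count.
#'
#' @param image a [volume_image()] whose grid is the wall region.
#' @param min_contrast minimum absolute intensity difference from the
#'   myocardium median.
#' @param min_size minimum component volume in mm^3.
#' @return A [lesion_mask()]; empty (all zero) when nothing is detected.
#' @export
detect_lesions <- function(image, min_contrast, min_size = 0) {
  stopifnot(inherits(image, "volume_image"))
  med <- stats::median(image$values)
  cand <- which(abs(image$values - med) >= min_contrast)
  labels <- array(0L, dim(image$values))
  if (length(cand)) {
    comp <- label_components(cand, dim(image$values))
    voxvol <- prod(image$spacing)
    sizes <- tabulate(comp)
    keep <- which(sizes * voxvol >= min_size)
    if (length(keep)) {
      ## relabel kept components by decreasing size (ties: first occurrence)
      ord <- keep[order(-sizes[keep])]
      newlab <- integer(max(comp))
      newlab[ord] <- seq_along(ord)
      lab <- newlab[comp]
      labels[cand[lab > 0L]] <- lab[lab > 0L]
    }
  }
  lesion_mask(labels, image$spacing, image$origin)
}

## 26-connected components of a voxel index set, via igraph
label_components <- function(cand, dims) {
  m <- length(cand)
  pos <- match(seq_len(prod(dims)), cand)  # linear index -> candidate rank
  ai <- arrayInd(cand, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 3] > 0 |
           (offs[, 3] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 1] > 0)))), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    ok <- ai[, 1] + o[1] >= 1L & ai[, 1] + o[1] <= dims[1] &
          ai[, 2] + o[2] >= 1L & ai[, 2] + o[2] <= dims[2] &
          ai[, 3] + o[3] >= 1L & ai[, 3] + o[3] <= dims[3]
    nb <- pos[cand[ok] + sum(o * strides)]
    hit <- !is.na(nb)
    edges[[i]] <- rbind(which(ok)[hit], nb[hit])
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(e) && ncol(e))
    g <- igraph::add_edges(g, as.vector(e))
  igraph::components(g)$membership
}

## physical voxel-centre coordinates of one labelled lesion
lesion_coords <- function(mask, label) {
  idx <- which(mask$labels == label)
  if (!length(idx)) stop(sprintf("lesion %s: mask is empty", label))
  ai <- arrayInd(idx, dim(mask$labels))
  list(ijk = ai,
       xyz = sweep(sweep(ai - 0.5, 2, mask$spacing, `*`), 2, mask$origin, `+`))
}

## maximum caliper (Feret) extent of a point set plus one in-plane voxel.
## `pts` has 1 column (a slice-restricted row) or 2 (a full depth layer);
## the constant one-voxel extent correction assumes isotropic in-plane
## spacing and makes the extent exact for axis-aligned boxes while keeping
## the per-layer width monotone under set inclusion.
feret_extent <- function(pts, sp_in) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) == 1L) return(max(pts) - min(pts) + sp_in)
  if (nrow(pts) > 3L) {
    h <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2L) pts <- pts[h, , drop = FALSE]
  }
  if (nrow(pts) == 1L) return(sp_in)
  d2 <- max(outer(pts[, 1], pts[, 1], `-`)^2 + outer(pts[, 2], pts[, 2], `-`)^2)
  sqrt(d2) + sp_in
}

in_plane_spacing <- function(spacing) {
  if (abs(spacing[1] - spacing[2]) > 1e-6 * mean(spacing[1:2]))
    warning("anisotropic in-plane spacing; using the mean for the ",
            "one-voxel extent correction")
  mean(spacing[1:2])
}

#' Measure maximum lesion depth (A)
#'
#' The maximal distance between the endocardial plane and the lesion apex,
#' estimated as the largest signed voxel-centre depth along the depth axis
#' plus half a voxel (a voxel's extent spans half a spacing beyond its
#' centre; the correction makes the estimate exact for axis-aligned blocks).
#'
#' @param mask a [lesion_mask()].
#' @param surface a [surface_ref()].
#' @param label lesion label to measure.
#' @return depth A in mm.
#' @export
measure_depth <- function(mask, surface, label = 1L) {
  lc <- lesion_coords(mask, label)
  d <- lc$xyz[, 3] - surface$plane_z
  if (max(d) < 0)
    stop("lesion lies entirely above the endocardial plane")
  max(d) + mask$spacing[3] / 2
}

#' Measure maximum width (B) and its depth (C)
#'
#' For each constant-depth voxel layer the lesion cross-section's maximum
#' caliper (Feret) diameter is computed on voxel centres and corrected by one
#' in-plane voxel extent. `B` is the maximum over layers; `C` is the
#' layer-centre depth of the layer attaining it.
#'
#' Because caliper extents on a voxel grid change in discrete jumps, several
#' adjacent layers near a flat maximum can tie exactly. Ties are resolved
#' deterministically by a refinement chain: among width-tied layers the one
#' with the largest cross-section area (voxel count, a much finer monotone
#' statistic) wins; a remaining tied run is reported at its mean layer-centre
#' depth (its middle). On a lesion that is uniformly wide over a depth range
#' this places `C` at the centre of that range.
#'
#' @inheritParams measure_depth
#' @return named numeric `c(B = , C = )` in mm.
#' @export
measure_width_and_C <- function(mask, surface, label = 1L) {
  lc <- lesion_coords(mask, label)
  sp_in <- in_plane_spacing(mask$spacing)
  layers <- split(seq_len(nrow(lc$xyz)), lc$ijk[, 3])
  zc <- mask$origin[3] + (as.integer(names(layers)) - 0.5) * mask$spacing[3]
  W <- vapply(layers, function(ii)
    feret_extent(lc$xyz[ii, 1:2, drop = FALSE], sp_in), numeric(1))
  N <- lengths(layers)
  tied <- which(W == max(W))
  tied <- tied[N[tied] == max(N[tied])]
  c(B = max(W), C = mean(zc[tied]) - surface$plane_z)
}

#' Measure the estuary diameter (D)
#'
#' The lesion's surface opening: the maximum caliper extent of the lesion
#' cross-section within the voxel layer containing the endocardial plane.
#' Returns 0 with attribute `reaches_surface = FALSE` when the lesion does
#' not reach the surface layer.
#'
#' @inheritParams measure_depth
#' @return estuary D in mm, with logical attribute `reaches_surface`.
#' @export
measure_estuary <- function(mask, surface, label = 1L) {
  lc <- lesion_coords(mask, label)
  k0 <- floor((surface$plane_z - mask$origin[3]) / mask$spacing[3]) + 1L
  ii <- which(lc$ijk[, 3] == k0)
  if (!length(ii))
    return(structure(0, reaches_surface = FALSE))
  sp_in <- in_plane_spacing(mask$spacing)
  structure(feret_extent(lc$xyz[ii, 1:2, drop = FALSE], sp_in),
            reaches_surface = TRUE)
}

#' Select the slice where the lesion reaches its maximum cross-section
#'
#' Index of the slice perpendicular to `slicing_axis` with the largest
#' lesion cross-section area (voxel count), emulating an observer's choice
#' of the slice "where the lesion reaches its maximum parameters". Ties are
#' broken toward the smallest index.
#'
#' @param mask a [lesion_mask()].
#' @param slicing_axis axis perpendicular to the slices ("x", "y", "z" or 1:3).
#' @param label lesion label, or `NULL` for all lesion voxels.
#' @return integer slice index.
#' @export
select_max_slice <- function(mask, slicing_axis = "x", label = NULL) {
  ax <- axis_index(slicing_axis)
  sel <- if (is.null(label)) mask$labels > 0L else mask$labels == label
  if (!any(sel)) stop("mask is empty")
  counts <- apply(sel, ax, sum)
  which.max(counts)
}

#' Measure the four lesion dimensions
#'
#' Computes the depth `A`, maximum width `B`, depth at the maximum diameter
#' `C` and estuary `D` of one lesion, either from the full 3D mask
#' (`mode = "full3d"`) or from the single best slice
#' (`mode = "slice2d"`, emulating an observer measuring on the slice where
#' the lesion reaches its maximum parameters). In slice mode the slicing
#' axis must be lateral ("x" or "y") so that the slice plane contains the
#' depth axis, and widths reduce to within-row extents on the slice.
#'
#' The mask must contain only the necrotic core; border-zone voxels are never
#' part of a lesion mask and hence never enter a measurement.
#'
#' @param mask a [lesion_mask()].
#' @param surface a [surface_ref()].
#' @param mode `"full3d"` or `"slice2d"`.
#' @param slicing_axis lateral slicing axis for `slice2d` mode.
#' @param label lesion label to measure.
#' @return One-row data.frame (a measurement record) with columns
#'   `lesion_id`, `method`, `observer_id`, `repeat_index`, `A`, `B`, `C`,
#'   `D` (mm), `slice_index_used`, `reaches_surface`, `flag_consistent`
#'   (FALSE when the recorded values violate `C <= A` or `D <= B`, which is
#'   flagged rather than rejected).
#' @export
measure_lesion <- function(mask, surface, mode = c("full3d", "slice2d"),
                           slicing_axis = "x", label = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "lesion_mask"), inherits(surface, "surface_ref"))
  if (mode == "full3d") {
    A <- measure_depth(mask, surface, label)
    BC <- measure_width_and_C(mask, surface, label)
    D <- measure_estuary(mask, surface, label)
    rec <- measurement_record(label, A, BC[["B"]], BC[["C"]], as.numeric(D),
                              NA_integer_, attr(D, "reaches_surface"))
    return(rec)
  }
  ax <- axis_index(slicing_axis)
  if (ax == 3L)
    stop("slice2d requires a lateral slicing axis (x or y) so the slice ",
         "plane contains the depth axis")
  k <- select_max_slice(mask, ax, label)
  lc <- lesion_coords(mask, label)
  keep <- lc$ijk[, ax] == k
  if (!any(keep)) stop("selected slice contains no lesion voxels")
  lat <- setdiff(1:2, ax)  # the in-slice lateral axis
  measure_section(u = lc$xyz[keep, lat], zidx = lc$ijk[keep, 3],
                  sp_u = mask$spacing[lat], sp_z = mask$spacing[3],
                  origin_z = mask$origin[3], surface = surface,
                  label = label, slice_index = k)
}

## shared 2D section measurement: `u` lateral coordinate, `zidx` depth layer
measure_section <- function(u, zidx, sp_u, sp_z, origin_z, surface, label,
                            slice_index) {
  zc_all <- origin_z + (zidx - 0.5) * sp_z
  d <- zc_all - surface$plane_z
  if (max(d) < 0) stop("lesion lies entirely above the endocardial plane")
  A <- max(d) + sp_z / 2
  layers <- split(u, zidx)
  zc <- origin_z + (as.integer(names(layers)) - 0.5) * sp_z
  W <- vapply(layers, function(v) max(v) - min(v) + sp_u, numeric(1))
  N <- lengths(layers)
  tied <- which(W == max(W))
  tied <- tied[N[tied] == max(N[tied])]  # same tie chain as the 3D measure
  B <- max(W); C <- mean(zc[tied]) - surface$plane_z
  k0 <- floor((surface$plane_z - origin_z) / sp_z) + 1L
  srow <- which(zidx == k0)
  reaches <- length(srow) > 0L
  D <- if (reaches) max(u[srow]) - min(u[srow]) + sp_u else 0
  measurement_record(label, A, B, C, D, slice_index, reaches)
}

measurement_record <- function(label, A, B, C, D, slice_index, reaches) {
  data.frame(lesion_id = as.integer(label), method = NA_character_,
             observer_id = NA_integer_, repeat_index = NA_integer_,
             A = A, B = B, C = C, D = D,
             slice_index_used = as.integer(slice_index),
             reaches_surface = isTRUE(reaches),
             flag_consistent = (C <= A + 1e-9) && (D <= B + 1e-9))
}

#' Measure a lesion on thick-slice pathology faces
#'
#' Observer-style measurement on an [emulate_patho()] stack: the face with
#' the largest lesion cross-section is selected (ties toward the first face)
#' and the four dimensions are measured on that 2D section exactly as in
#' `slice2d` mode of [measure_lesion()].
#'
#' @param stack a `patho_stack` from [emulate_patho()].
#' @param surface a [surface_ref()].
#' @param label lesion label to measure.
#' @return One-row measurement record data.frame; `slice_index_used` is the
#'   face index.
#' @export
measure_patho_stack <- function(stack, surface, label = 1L) {
  stopifnot(inherits(stack, "patho_stack"))
  if (stack$axis == 3L)
    stop("faces perpendicular to the depth axis cannot carry a depth ",
         "measurement; cut along a lateral axis")
  areas <- vapply(stack$faces, function(f) sum(f == label), numeric(1))
  if (all(areas == 0)) stop(sprintf("lesion %s: not visible on any face", label))
  k <- which.max(areas)
  f <- stack$faces[[k]]
  idx <- which(f == label, arr.ind = TRUE)
  ## in-plane axes of a lateral cut are (other lateral axis, z), in order
  u <- stack$in_plane_origin[1] + (idx[, 1] - 0.5) * stack$in_plane_spacing[1]
  zidx <- idx[, 2]
  measure_section(u = u, zidx = zidx, sp_u = stack$in_plane_spacing[1],
                  sp_z = stack$in_plane_spacing[2],
                  origin_z = stack$in_plane_origin[2], surface = surface,
                  label = label, slice_index = k)
}
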