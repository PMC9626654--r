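#' 3D scalar volume on a millimetre grid
#'
#' A `volume_image` is a plain 3D numeric array together with its voxel
#' spacing and physical origin, the minimal container needed to carry an
#' ex vivo imaging stack (e.g. a proton-density-weighted MRI volume) through
#' the measurement pipeline. Axis order is fixed as (x, y, z); for lesion
#' phantoms z is the depth axis pointing into the ventricular wall from the
#' endocardial surface.
#'
#' The voxel-centre convention is used throughout: the physical centre of
#' voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing voxel spacing in mm, a positive length-3 numeric (or a
#'   scalar, recycled).
#' @param origin physical position (mm) of the grid corner, length 3.
#' @return An object of class `volume_image`.
#' @seealso [lesion_mask()], [read_volume()], [write_volume()]
#' @export
volume_image <- function(values, spacing, origin = c(0, 0, 0)) {
  check_grid(values, spacing, origin)
  structure(list(values = values, spacing = rep_len(as.numeric(spacing), 3L),
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' Labelled lesion occupancy mask
#'
#' A `lesion_mask` is an integer 3D array congruent with a [volume_image()]:
#' 0 marks background (non-lesion myocardium), and a positive label `k` marks
#' voxels belonging to lesion `k`. Only the necrotic core is labelled; the
#' border zone around a lesion is never part of the mask.
#'
#' @param labels integer 3D array of lesion labels (0 = background).
#' @param spacing,origin as in [volume_image()].
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  check_grid(labels, spacing, origin)
  if (any(labels < 0)) stop("lesion labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = rep_len(as.numeric(spacing), 3L),
                 origin = as.numeric(origin)),
            class = "lesion_mask")
}

#' Endocardial surface reference
#'
#' Defines the reference surface and contact point from which lesion depth is
#' measured: the endocardial plane sits at `z = plane_z` and depth increases
#' along `depth_axis` into the wall. The contact point is the (x, y) position
#' where the ablation catheter touched the endocardium.
#'
#' Only the canonical `+z` depth axis is supported; masks acquired with a
#' different slice ordering should be permuted on import.
#'
#' @param plane_z z-position (mm) of the endocardial plane.
#' @param contact_point length-2 numeric, catheter contact (x, y) in mm.
#' @param depth_axis unit vector of the depth direction; must be `c(0, 0, 1)`.
#' @return An object of class `surface_ref`.
#' @export
surface_ref <- function(plane_z = 0, contact_point = c(0, 0),
                        depth_axis = c(0, 0, 1)) {
  stopifnot(is.numeric(plane_z), length(plane_z) == 1L,
            is.numeric(contact_point), length(contact_point) == 2L)
  if (!isTRUE(all.equal(as.numeric(depth_axis), c(0, 0, 1))))
    stop("only the +z depth axis is supported; permute the volume instead")
  structure(list(plane_z = as.numeric(plane_z),
                 contact_point = as.numeric(contact_point),
                 depth_axis = c(0, 0, 1)),
            class = "surface_ref")
}

check_grid <- function(values, spacing, origin) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("grid values must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be positive")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 numeric")
  invisible(TRUE)
}

#' Physical centres of voxel layers along one axis
#' @param x a `volume_image` or `lesion_mask`.
#' @param axis axis index (1, 2, 3) or name ("x", "y", "z").
#' @return numeric vector of layer-centre positions in mm.
#' @keywords internal
axis_centers <- function(x, axis) {
  ax <- axis_index(axis)
  n <- dim(grid_values(x))[ax]
  x$origin[ax] + (seq_len(n) - 0.5) * x$spacing[ax]
}

axis_index <- function(axis) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 3L) stop("axis must be x, y or z")
  axis
}

grid_values <- function(x) {
  if (inherits(x, "lesion_mask")) x$labels else x$values
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<lesion_mask> %s voxels, spacing %s mm, %d lesion(s): %s\n",
              paste(dim(x$labels), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              length(labs),
              if (length(labs)) paste(labs, collapse = ", ") else "-"))
  invisible(x)
}
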