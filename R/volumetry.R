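#' Lesion volume from the four measured dimensions
#'
#' Closed-formula estimate of an ablation lesion volume from its maximum
#' depth `A`, maximum width `B`, depth of the maximum diameter `C` and
#' estuary diameter `D` (all mm):
#'
#' \deqn{LV = 0.75\pi (B/2)^2 (A - C) - 0.25\pi (D/2)^2 (A - 2C)}
#'
#' The formula assumes a regular ovoid lesion; for irregular lesions it is
#' known to underestimate the true volume substantially. `A - 2C` may be
#' negative, in which case the second term adds volume; the result is
#' returned as-is. A negative total (possible for degenerate inputs with
#' large `C`) is returned with a warning rather than clamped.
#'
#' @param A,B,C,D dimensions in mm (non-negative, finite); vectorized.
#' @return volume(s) in mm^3.
#' @export
formula_volume <- function(A, B, C, D) {
  n <- max(length(A), length(B), length(C), length(D))
  A <- rep_len(as.numeric(A), n); B <- rep_len(as.numeric(B), n)
  C <- rep_len(as.numeric(C), n); D <- rep_len(as.numeric(D), n)
  if (any(!is.finite(c(A, B, C, D))) || any(c(A, B, C, D) < 0))
    stop("dimensions must be finite and non-negative")
  v <- 0.75 * pi * (B / 2)^2 * (A - C) - 0.25 * pi * (D / 2)^2 * (A - 2 * C)
  if (any(v < 0))
    warning("formula volume is negative for ", sum(v < 0),
            " input(s); returned unclamped")
  v
}

#' Point-by-point (Cavalieri) lesion volume
#'
#' Direct volume estimate by slice summation: the lesion cross-section area
#' on every slice is multiplied by the slice thickness and summed, the
#' digital analogue of outlining the lesion circumference on each scan.
#' Two inputs are supported:
#'
#' * a [lesion_mask()] - areas are pixel counts times pixel area on each
#'   slice perpendicular to `axis`; with every slice at native thickness the
#'   result equals [voxel_volume()] exactly. `every = k` keeps every k-th
#'   slice and scales the thickness by k (Cavalieri subsampling).
#' * a list of per-slice closed polygons (n x 2 matrices of mm
#'   coordinates) - areas by the shoelace formula; self-intersecting
#'   polygons are rejected.
#'
#' @param x a `lesion_mask` or a list of polygon matrices.
#' @param slice_thickness slice thickness in mm; for masks it defaults to
#'   `every` times the native spacing along `axis`.
#' @param axis slicing axis for mask input.
#' @param every keep every `every`-th slice (mask input).
#' @param label lesion label (mask input); `NULL` pools all lesions.
#' @return volume in mm^3, with attribute `mode` ("mask" or "polygon").
#' @export
pointbypoint_volume <- function(x, slice_thickness = NULL, axis = "z",
                                every = 1L, label = NULL) {
  if (inherits(x, "lesion_mask")) {
    ax <- axis_index(axis)
    every <- as.integer(every)
    stopifnot(every >= 1L)
    if (is.null(slice_thickness)) slice_thickness <- every * x$spacing[ax]
    if (slice_thickness <= 0) stop("slice_thickness must be positive")
    sel <- if (is.null(label)) x$labels > 0L else x$labels == label
    counts <- apply(sel, ax, sum)
    idx <- seq(1L, length(counts), by = every)
    pix_area <- prod(x$spacing[-ax])
    ## grouped so that the native-thickness sum reproduces voxel_volume()
    ## to the last bit
    v <- sum(counts[idx]) * (pix_area * slice_thickness)
    return(structure(v, mode = "mask"))
  }
  if (!is.list(x) || !length(x)) stop("need at least one slice outline")
  if (is.null(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be supplied for polygon outlines")
  areas <- vapply(x, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each outline must be an n x 2 matrix with n >= 3")
    if (!is_simple_polygon(p)) stop("self-intersecting outline polygon")
    shoelace_area(p)
  }, numeric(1))
  structure(sum(areas) * slice_thickness, mode = "polygon")
}

shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

## simplicity check: no two non-adjacent edges intersect
is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges adjacent to edge i
    for (j in js)
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  (o1 != o2 && o3 != o4) && !(o1 == 0 || o2 == 0 || o3 == 0 || o4 == 0)
}

#' Voxel-count lesion volume
#'
#' The digital reference volume: number of lesion voxels times the voxel
#' volume `dx dy dz`.
#'
#' @param mask a [lesion_mask()].
#' @param label lesion label; `NULL` pools all lesions.
#' @return volume in mm^3.
#' @export
voxel_volume <- function(mask, label = NULL) {
  stopifnot(inherits(mask, "lesion_mask"))
  sel <- if (is.null(label)) mask$labels > 0L else mask$labels == label
  sum(sel) * prod(mask$spacing)
}
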