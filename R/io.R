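#' Read a 3D volume or lesion mask from disk
#'
#' Supports NIfTI-1 (`.nii` / `.nii.gz`), which carries voxel spacing in its
#' header, and multi-page TIFF, whose spacing must come from a YAML sidecar
#' written by [write_volume()] (`<file>.yaml`). A file without usable spacing
#' metadata is an error - spacing is never silently defaulted to 1 mm.
#'
#' @param path file path.
#' @param as `"auto"` (mask when the stored values are integer-typed or the
#'   sidecar says so), `"image"`, or `"mask"`.
#' @return A [volume_image()] or [lesion_mask()].
#' @export
read_volume <- function(path, as = c("auto", "image", "mask")) {
  as <- match.arg(as)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))  # drop NIfTI header attributes
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    spacing <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("NIfTI header lacks a positive voxel spacing: ", path)
    kind <- if (as == "auto") {
      if (is.integer(arr)) "mask" else "image"
    } else as
    return(if (kind == "mask") lesion_mask(arr, spacing)
           else volume_image(arr, spacing))
  }
  if (grepl("\\.tiff?$", path)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("TIFF volume requires a spacing sidecar (", sidecar,
           "); refusing to assume 1 mm voxels")
    meta <- yaml::read_yaml(sidecar)
    if (is.null(meta$spacing) || length(meta$spacing) != 3L ||
        any(meta$spacing <= 0))
      stop("sidecar lacks a valid 3-component spacing: ", sidecar)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    scale <- if (is.null(meta$scale)) 1 else meta$scale
    arr <- arr * scale
    kind <- if (as == "auto") {
      if (identical(meta$kind, "mask")) "mask" else "image"
    } else as
    if (kind == "mask") {
      arr <- round(arr)  # undo 32-bit TIFF quantization exactly for labels
      storage.mode(arr) <- "integer"
      return(lesion_mask(arr, meta$spacing))
    }
    return(volume_image(arr, meta$spacing))
  }
  stop("unsupported volume format: ", path)
}

#' Write a volume or lesion mask to disk
#'
#' NIfTI-1 output stores masks as `int32` and images as `double`, with the
#' voxel spacing in the header; the round trip is exact. TIFF output writes
#' one 32-bit page per z-slice, scaled into `[0, 1)` by a power of two
#' recorded in a YAML sidecar along with the spacing; integer labels
#' round-trip exactly (values are re-rounded on read), grayscale images to
#' about 1e-9 relative precision. The grid origin is not serialized.
#'
#' @param x a [volume_image()] or [lesion_mask()].
#' @param path destination ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "lesion_mask")
  if (!is_mask && !inherits(x, "volume_image"))
    stop("x must be a volume_image or lesion_mask")
  vals <- grid_values(x)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "int32" else "double")
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", path)) {
    vmax <- max(abs(vals), 1e-12)
    scale <- 2^ceiling(log2(vmax * (1 + 1e-9)))
    pages <- lapply(seq_len(dim(vals)[3]),
                    function(k) vals[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    yaml::write_yaml(list(kind = if (is_mask) "mask" else "image",
                          spacing = as.numeric(x$spacing),
                          scale = as.numeric(scale),
                          dim = dim(vals)),
                     paste0(path, ".yaml"))
    return(invisible(path))
  }
  stop("unsupported volume format: ", path)
}

#' Write a measurement or volume table as CSV with units in the header
#'
#' Column names carry their units (`_mm`, `_mm3`) so every exported table is
#' self-describing.
#'
#' @param df data.frame of records.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(df, path) {
  ren <- c(A = "A_depth_mm", B = "B_width_mm", C = "C_depth_of_width_mm",
           D = "D_estuary_mm",
           A_true = "A_true_mm", B_true = "B_true_mm", C_true = "C_true_mm",
           D_true = "D_true_mm", V_true = "V_true_mm3",
           V_formula = "V_formula_mm3",
           V_pointbypoint = "V_pointbypoint_mm3", V_voxel = "V_voxel_mm3",
           estimate = "estimate_mm_or_mm3")
  nm <- names(df)
  hit <- nm %in% names(ren)
  nm[hit] <- ren[nm[hit]]
  names(df) <- nm
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
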