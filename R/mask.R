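#' Binary segmentation mask volume
#'
#' A voxelised liver segmentation: a 3-D binary array ordered slice x row x
#' column, with voxel spacing in millimetres. This is the computational
#' counterpart of manually traced ROIs on transverse CT slices.
#'
#' @param voxels 3-D array (slice x row x column), logical or 0/1, with at
#'   least one foreground voxel.
#' @param spacing_mm Numeric length-3: slice thickness, row pitch, column
#'   pitch in mm, all > 0.
#' @param subject_id Identifier.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, spacing_mm, subject_id = "S01") {
  if (length(dim(voxels)) != 3L) {
    stop("voxels must be a 3-D array (slice x row x column)", call. = FALSE)
  }
  storage.mode(voxels) <- "integer"
  if (anyNA(voxels) || !all(voxels %in% c(0L, 1L))) {
    stop("voxels must be binary (0/1)", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be three positive values (slice, row, column)",
         call. = FALSE)
  }
  if (sum(voxels) == 0L) {
    stop("mask has no foreground voxels", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 subject_id = as.character(subject_id)[1L]),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask_volume> subject %s: %d x %d x %d voxels @ %s mm, %d foreground\n",
              x$subject_id, d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              sum(x$voxels)))
  invisible(x)
}

#' Extract a per-slice area series from a mask
#'
#' Per-slice area = foreground pixel count x row pitch x column pitch,
#' converted mm^2 -> cm^2. Leading and trailing all-background slices are
#' trimmed so the series covers exactly the liver-bearing slices; an
#' interior all-background slice raises a warning but is retained as a zero
#' area. Slice thickness is taken from the mask spacing (mm -> cm).
#'
#' @param mask A [mask_volume()].
#' @param observer_id Observer label for the resulting series.
#' @return A [slice_series()].
#' @export
mask_to_series <- function(mask, observer_id = "A") {
  stopifnot(inherits(mask, "mask_volume"))
  counts <- apply(mask$voxels, 1L, sum)
  nz <- which(counts > 0L)
  counts <- counts[nz[1]:nz[length(nz)]]
  if (any(counts == 0L)) {
    warning("interior all-background slice(s) retained as zero area",
            call. = FALSE)
  }
  areas <- counts * mask$spacing_mm[2] * mask$spacing_mm[3] / 100
  slice_series(areas, mask$spacing_mm[1] / 10,
               subject_id = mask$subject_id, observer_id = observer_id)
}

#' Rasterise an area series into a binary mask volume
#'
#' Each slice becomes a filled disc centred in the image plane whose radius
#' reproduces the slice area; pixel-centre-in-disc rasterisation keeps the
#' pixel-counted area within a perimeter-row of pixels of the requested
#' area. The in-plane grid is sized to the largest disc plus a margin.
#'
#' @param series A [slice_series()].
#' @param in_plane_pitch_mm Pixel pitch in mm (> 0); must be fine enough
#'   that the smallest slice area covers at least one pixel.
#' @return A [mask_volume()] (spacing: thickness, pitch, pitch).
#' @examples
#' m <- voxelize(slice_series(c(20, 100, 30), 0.25), in_plane_pitch_mm = 1)
#' mask_to_series(m)
#' @export
voxelize <- function(series, in_plane_pitch_mm = 1) {
  stopifnot(inherits(series, "slice_series"))
  pitch <- as.numeric(in_plane_pitch_mm)[1L]
  if (!is.finite(pitch) || pitch <= 0) {
    stop("in_plane_pitch_mm must be > 0", call. = FALSE)
  }
  areas_mm2 <- series$areas_cm2 * 100
  if (min(areas_mm2) < pitch^2) {
    stop(sprintf(paste0("pitch %.3g mm too coarse: smallest slice area ",
                        "%.3g mm^2 covers less than one pixel"),
                 pitch, min(areas_mm2)), call. = FALSE)
  }
  radii <- sqrt(areas_mm2 / pi)
  half <- ceiling(max(radii) / pitch) + 2L
  coords <- seq.int(-half, half) * pitch
  d2 <- outer(coords^2, coords^2, `+`)
  vox <- vapply(radii, function(r) (d2 <= r^2) * 1L,
                matrix(integer(1), length(coords), length(coords)))
  vox <- aperm(vox, c(3L, 1L, 2L))  # slice x row x column
  mask_volume(vox, c(series$thickness_cm * 10, pitch, pitch),
              subject_id = series$subject_id)
}

#' Read and write mask volumes as NIfTI
#'
#' Masks are stored in conventional NIfTI axis order (x = column, y = row,
#' z = slice) with the voxel spacing in the header pixdim; reading reverses
#' the permutation, so write/read round-trips exactly.
#'
#' @param mask A [mask_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_mask_nifti` returns `path` invisibly; `read_mask_nifti`
#'   returns a `mask_volume`.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  arr <- aperm(mask$voxels, c(3L, 2L, 1L))  # -> x, y, z
  attr(arr, "pixdim") <- mask$spacing_mm[c(3L, 2L, 1L)]
  attr(arr, "pixunits") <- "mm"
  img <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param subject_id Identifier for the returned mask (defaults to the file
#'   name without extension).
#' @export
read_mask_nifti <- function(path, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3-D NIfTI volume in ", path, call. = FALSE)
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop("missing or invalid voxel spacing in NIfTI header of ", path,
         "; supply an explicit thickness", call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  mask_volume(aperm(arr, c(3L, 2L, 1L)), sp[c(3L, 2L, 1L)],
              subject_id = subject_id)
}
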