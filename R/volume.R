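#' 3-D intensity volume with voxel spacing
#'
#' The unit every pipeline stage consumes and produces: a 3-D numeric array
#' plus its voxel spacing in millimetres (scalar for isotropic grids, length-3
#' for anisotropic input awaiting resampling). World position of voxel
#' `(i,j,k)` (1-based) is `(i-1, j-1, k-1) * spacing`; grids are axis-aligned.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm voxel spacing in mm; scalar or length-3 positive numeric.
#' @param meta optional named list of provenance metadata.
#' @return An object of class `aneu_volume`.
#' @export
aneu_volume <- function(data, spacing_mm = 0.3906, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing_mm <- as.numeric(spacing_mm)
  if (!length(spacing_mm) %in% c(1L, 3L) || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be a positive scalar or length-3 numeric")
  }
  structure(list(data = data, spacing_mm = spacing_mm, meta = meta),
            class = "aneu_volume")
}

#' @export
print.aneu_volume <- function(x, ...) {
  cat(sprintf("<aneu_volume> %s voxels @ %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm, digits = 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.aneu_volume <- function(x) dim(x$data)

#' @export
as.array.aneu_volume <- function(x, ...) x$data

spacing3 <- function(vol) {
  s <- vol$spacing_mm
  if (length(s) == 1L) rep(s, 3L) else s
}

is_isotropic <- function(vol, tol = 1e-6) {
  s <- spacing3(vol)
  diff(range(s)) <= tol * mean(s)
}

#' Read a NIfTI volume
#'
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return An [aneu_volume] with spacing taken from the NIfTI pixdim.
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (max(sp) - min(sp) < 1e-6 * mean(sp)) sp <- mean(sp)
  aneu_volume(arr, sp, meta = list(file = file))
}

#' Write a volume to NIfTI
#'
#' @param vol an [aneu_volume] (or a plain array, written with `spacing_mm`).
#' @param file output path (`.nii` or `.nii.gz`).
#' @param spacing_mm spacing used when `vol` is a bare array.
#' @return `file`, invisibly.
#' @export
write_volume <- function(vol, file, spacing_mm = 0.3906) {
  if (inherits(vol, "aneu_volume")) {
    arr <- vol$data
    sp <- spacing3(vol)
  } else {
    arr <- vol
    sp <- rep(spacing_mm, length.out = 3)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, file)
  invisible(file)
}
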