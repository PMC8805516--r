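#' Resample a volume to an isotropic grid
#'
#' Trilinear resampling onto an isotropic grid (default 0.3906 mm, the
#' working resolution of the whole pipeline). Output shape is the input
#' shape rescaled by the spacing ratios; world extent is preserved within
#' one output voxel. Grids are axis-aligned (no oblique affine support).
#'
#' @param vol an [aneu_volume] with positive spacings.
#' @param target_spacing_mm isotropic target spacing.
#' @return An isotropic [aneu_volume].
#' @export
resample_isotropic <- function(vol, target_spacing_mm = 0.3906) {
  stopifnot(inherits(vol, "aneu_volume"), target_spacing_mm > 0)
  sp <- spacing3(vol)
  if (any(sp <= 0)) stop("non-positive voxel spacing")
  d <- dim(vol$data)
  if (all(abs(sp - target_spacing_mm) < 1e-9))
    return(aneu_volume(vol$data, target_spacing_mm, vol$meta))
  out_dim <- pmax(1L, as.integer(round(d * sp / target_spacing_mm)))
  scale <- target_spacing_mm / sp
  out <- cpp_resample_linear(vol$data, out_dim, scale)
  aneu_volume(out, target_spacing_mm, vol$meta)
}

#' Train a Nyul-Udupa standard intensity scale
#'
#' Learns the standard scale of the Nyul-Udupa piecewise-linear histogram
#' standardization: each training volume's landmark percentiles are anchored
#' by an affine map sending its clip-bound percentiles onto the standard
#' range, and the standard landmark values are the across-volume means of the
#' anchored landmarks.
#'
#' @param volumes list of [aneu_volume] (>= 1).
#' @param landmark_percentiles ordered landmark percentiles in (0, 100);
#'   default deciles 10..90.
#' @param clip_percentiles low/high clip-bound percentiles (default 1 and 99).
#' @param standard_range numeric length-2, the standard intensity scale the
#'   clip bounds are anchored to (default `c(0, 100)`).
#' @return An object of class `nyul_scale`.
#' @export
nyul_train <- function(volumes,
                       landmark_percentiles = seq(10, 90, by = 10),
                       clip_percentiles = c(1, 99),
                       standard_range = c(0, 100)) {
  if (length(volumes) < 1) stop("need at least one training volume")
  stopifnot(all(diff(landmark_percentiles) > 0),
            all(landmark_percentiles > 0), all(landmark_percentiles < 100),
            clip_percentiles[1] < min(landmark_percentiles),
            clip_percentiles[2] > max(landmark_percentiles))
  anchored <- vapply(volumes, function(v) {
    x <- as.numeric(as.array(v))
    p <- quantile(x, c(clip_percentiles, landmark_percentiles) / 100,
                  names = FALSE, type = 7)
    lo <- p[1]; hi <- p[2]
    if (hi <= lo) stop("degenerate histogram: clip percentiles coincide")
    standard_range[1] + (p[-(1:2)] - lo) / (hi - lo) * diff(standard_range)
  }, numeric(length(landmark_percentiles)))
  anchored <- matrix(anchored, nrow = length(landmark_percentiles))
  structure(list(landmark_percentiles = landmark_percentiles,
                 standard_values = rowMeans(anchored),
                 clip_percentiles = clip_percentiles,
                 standard_range = standard_range),
            class = "nyul_scale")
}

#' @export
print.nyul_scale <- function(x, ...) {
  cat("<nyul_scale> landmarks at p{", paste(x$landmark_percentiles,
                                            collapse = ","), "}\n")
  cat("  standard values:", paste(round(x$standard_values, 2), collapse = " "),
      "\n")
  invisible(x)
}

#' Apply Nyul-Udupa standardization to a volume
#'
#' Piecewise-linear map sending the volume's own clip-bound and landmark
#' percentiles onto the trained standard scale. Intensities outside the clip
#' bounds are clamped to the standard range; the map is monotone
#' non-decreasing, and volumes already on the standard scale are fixed points
#' (application is idempotent up to interpolation tolerance).
#'
#' @param vol an [aneu_volume].
#' @param scale a trained [nyul_train()] `nyul_scale`.
#' @return Standardized [aneu_volume].
#' @export
nyul_apply <- function(vol, scale) {
  stopifnot(inherits(vol, "aneu_volume"), inherits(scale, "nyul_scale"))
  x <- as.numeric(vol$data)
  p <- quantile(x, c(scale$clip_percentiles, scale$landmark_percentiles) / 100,
                names = FALSE, type = 7)
  if (p[2] <= p[1]) stop("degenerate histogram: volume is (near-)constant")
  knots_x <- c(p[1], p[-(1:2)], p[2])
  knots_y <- c(scale$standard_range[1], scale$standard_values,
               scale$standard_range[2])
  keep <- c(TRUE, diff(knots_x) > 0)
  knots_x <- knots_x[keep]; knots_y <- knots_y[keep]
  if (length(knots_x) < 2) stop("degenerate histogram: volume is (near-)constant")
  y <- approx(knots_x, knots_y, xout = pmin(pmax(x, knots_x[1]),
                                            knots_x[length(knots_x)]),
              rule = 2, ties = "ordered")$y
  aneu_volume(array(y, dim(vol$data)), vol$spacing_mm, vol$meta)
}

#' Extract the arterial compartment by three-sigma thresholding
#'
#' Thresholds a normalized volume at mean + 3 sd of its intensities to remove
#' non-arterial tissue; on TOF-MRA-like data arteries are the bright upper
#' tail. By default the statistics are computed over strictly positive
#' voxels, which excludes zero-padding introduced by resampling; set
#' `foreground_only = FALSE` to use all voxels. A constant volume (sd = 0)
#' yields an empty mask with a warning.
#'
#' @param vol a normalized [aneu_volume].
#' @param foreground_only compute mean/sd over voxels with intensity > 0.
#' @return A list of class `artery_volume`: `volume`, logical `artery_mask`
#'   (`TRUE` iff intensity >= `threshold_used`), and `threshold_used`.
#' @export
extract_arteries <- function(vol, foreground_only = TRUE) {
  stopifnot(inherits(vol, "aneu_volume"))
  x <- vol$data
  pop <- if (foreground_only) x[x > 0] else as.numeric(x)
  if (length(pop) < 2) {
    warning("no foreground voxels; artery mask is empty")
    return(structure(list(volume = vol,
                          artery_mask = array(FALSE, dim(x)),
                          threshold_used = Inf),
                     class = "artery_volume"))
  }
  m <- mean(pop); s <- sd(pop)
  if (s == 0) {
    warning("constant volume: sd = 0, artery mask left empty")
    return(structure(list(volume = vol,
                          artery_mask = array(FALSE, dim(x)),
                          threshold_used = Inf),
                     class = "artery_volume"))
  }
  thr <- m + 3 * s
  structure(list(volume = vol, artery_mask = x >= thr, threshold_used = thr),
            class = "artery_volume")
}

#' @export
print.artery_volume <- function(x, ...) {
  cat(sprintf("<artery_volume> threshold %.3f, %d artery voxels (%.3f%%)\n",
              x$threshold_used, sum(x$artery_mask),
              100 * mean(x$artery_mask)))
  invisible(x)
}

#' Serialize / restore a standard intensity scale
#'
#' @param scale a `nyul_scale`.
#' @param file JSON path.
#' @return `file` (write) or the restored `nyul_scale` (read).
#' @export
write_nyul_scale <- function(scale, file) {
  jsonlite::write_json(unclass(scale), file, auto_unbox = FALSE, digits = NA)
  invisible(file)
}

#' @rdname write_nyul_scale
#' @export
read_nyul_scale <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(x, class = "nyul_scale")
}
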