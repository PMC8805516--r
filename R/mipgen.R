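rot_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  c <- cos(a); s <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
         y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
         z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3))
}

# proper rotation mapping viewing axis -> first array axis
view_base <- function(axis) {
  switch(axis,
         x = diag(3),
         y = rot_axis("z", -90),
         z = rot_axis("y", 90))
}

#' The 15 projection orientations
#'
#' Deterministic ordered list of the 15 viewing orientations used for the
#' concatenated MIP panel: the three canonical axis projections (along X, Y,
#' Z), followed by tilts of the canonical view by +/-30 and +/-45 degrees
#' about each of the X, Y and Z axes (12). A tilt about an axis is applied to
#' a canonical view *not* aligned with that axis (X-tilts tilt the Y-view,
#' Y- and Z-tilts tilt the X-view), so no rotation degenerates to an in-plane
#' spin of its own projection. The exact enumeration is isolated here so an
#' alternative set is a one-line change.
#'
#' @return List of 15 orientations, each with `name` and a proper rotation
#'   matrix `R` (orthonormal, det +1).
#' @export
orientation_set <- function() {
  out <- list(list(name = "axial_x", R = view_base("x")),
              list(name = "coronal_y", R = view_base("y")),
              list(name = "sagittal_z", R = view_base("z")))
  for (axis in c("x", "y", "z")) {
    base <- if (axis == "x") view_base("y") else view_base("x")
    for (ang in c(-45, -30, 30, 45)) {
      out[[length(out) + 1L]] <-
        list(name = sprintf("rot_%s_%+d", axis, ang),
             R = rot_axis(axis, ang) %*% base)
    }
  }
  out
}

#' Maximum-intensity projection of a patch under one orientation
#'
#' The cubic patch is resampled under the rotation (trilinear, zero-padded
#' outside the cube) and projected by per-ray maximum along the first array
#' axis.
#'
#' @param patch cubic numeric array of side S.
#' @param orientation one element of [orientation_set()].
#' @return S x S numeric tile.
#' @export
mip_project <- function(patch, orientation) {
  d <- dim(patch)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("mip_project requires a cubic patch")
  cpp_rotate_mip(patch, orientation$R)
}

#' Build the 15-view concatenated MIP panel
#'
#' Projects the patch under every orientation of [orientation_set()] and
#' stacks the 15 S x S tiles vertically into a (15 S) x S panel, the input
#' of the planar (2D) branch. No per-tile rescaling is applied, so relative
#' brightness across views is preserved.
#'
#' @param patch cubic numeric array of side S.
#' @param orientations orientation list (default [orientation_set()]).
#' @return (15 S) x S numeric matrix of class `mip_panel` with attribute
#'   `view_order`.
#' @export
build_panel <- function(patch, orientations = orientation_set()) {
  tiles <- lapply(orientations, function(o) mip_project(patch, o))
  panel <- do.call(rbind, tiles)
  structure(panel,
            view_order = vapply(orientations, `[[`, character(1), "name"),
            class = c("mip_panel", class(panel)))
}

#' Export a panel as PNG for inspection
#'
#' @param panel a [build_panel()] panel.
#' @param file output PNG path.
#' @return `file`, invisibly.
#' @export
panel_png <- function(panel, file) {
  rng <- range(panel)
  img <- if (diff(rng) > 0) (panel - rng[1]) / diff(rng) else panel * 0
  grDevices::png(file, width = ncol(img) * 4, height = nrow(img) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({graphics::par(op); grDevices::dev.off()}, add = TRUE)
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, useRaster = TRUE)
  invisible(file)
}
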