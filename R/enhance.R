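#' Multiscale selective-enhancement shape filtering
#'
#' Hessian-eigenvalue filter bank separating blob-like (aneurysm), line-like
#' (vessel) and plane-like structures. At each Gaussian scale sigma the
#' volume is smoothed, the Hessian eigenvalues are ordered by magnitude
#' `|l1| >= |l2| >= |l3|`, and the sigma^2-normalized responses are
#' \itemize{
#'   \item blob:  `s^2 * l3^2 / |l1|` where `l1, l2, l3 < 0`, else 0
#'   \item line:  `s^2 * |l2| * (|l2| - |l3|) / |l1|` where `l1, l2 < 0`, else 0
#'   \item plane: `s^2 * (|l1| - |l2|)` where `l1 < 0`, else 0
#' }
#' The final response of each kind is the per-voxel maximum over scales;
#' `argmax_scale` records the blob-maximizing scale. Division is guarded by
#' `eps = 1e-12`. The default scale set spans aneurysm radii of roughly
#' 3--15 mm equivalent diameters.
#'
#' @param vol an isotropic [aneu_volume] (resample first otherwise).
#' @param scales_mm Gaussian scales sigma in mm.
#' @return An object of class `shape_response`: arrays `blob`, `line`,
#'   `plane`, `argmax_scale` (mm), plus `scales_mm` and `spacing_mm`.
#' @export
shape_filter <- function(vol, scales_mm = c(0.6, 1.0, 1.6, 2.4, 3.6)) {
  stopifnot(inherits(vol, "aneu_volume"), length(scales_mm) >= 1)
  if (!is_isotropic(vol))
    stop("shape_filter requires an isotropic volume; run resample_isotropic()")
  sp <- spacing3(vol)[1]
  d <- dim(vol$data)
  blob <- array(0, d); line <- array(0, d); plane <- array(0, d)
  argmax <- array(scales_mm[1], d)
  for (s_mm in sort(scales_mm)) {
    r <- cpp_shape_responses(vol$data, s_mm / sp)
    upd <- r$blob > blob
    argmax[upd] <- s_mm
    blob <- pmax(blob, r$blob)
    line <- pmax(line, r$line)
    plane <- pmax(plane, r$plane)
  }
  structure(list(blob = blob, line = line, plane = plane,
                 argmax_scale = argmax, scales_mm = sort(scales_mm),
                 spacing_mm = sp),
            class = "shape_response")
}

#' @export
print.shape_response <- function(x, ...) {
  cat(sprintf("<shape_response> scales {%s} mm, blob max %.4g\n",
              paste(x$scales_mm, collapse = ", "), max(x$blob)))
  invisible(x)
}

#' Candidate points from the blob response
#'
#' 26-neighbourhood local maxima of the blob response inside the artery
#' mask, above a response floor, thinned by greedy non-maximum suppression
#' and returned sorted by descending response.
#'
#' @param response a [shape_filter()] `shape_response`.
#' @param artery_mask logical array of the same shape.
#' @param min_response response floor; default the 95th percentile of the
#'   in-mask blob response.
#' @param nms_radius_mm non-maximum suppression radius (mm).
#' @return data.frame with columns `i, j, k` (1-based voxel coordinates),
#'   `response`, `scale_mm`.
#' @export
extract_candidate_points <- function(response, artery_mask,
                                     min_response = NULL,
                                     nms_radius_mm = 3.0) {
  stopifnot(inherits(response, "shape_response"),
            identical(dim(response$blob), dim(artery_mask)))
  empty <- data.frame(i = integer(), j = integer(), k = integer(),
                      response = numeric(), scale_mm = numeric())
  if (!any(artery_mask)) return(empty)
  if (is.null(min_response)) {
    inmask <- response$blob[artery_mask]
    min_response <- as.numeric(quantile(inmask, 0.95, names = FALSE))
  }
  lm <- cpp_local_maxima(response$blob, artery_mask, min_response)
  if (nrow(lm$coords) == 0) return(empty)
  ord <- order(-lm$values, lm$coords[, 1], lm$coords[, 2], lm$coords[, 3])
  coords <- lm$coords[ord, , drop = FALSE]
  values <- lm$values[ord]
  r_vox <- nms_radius_mm / response$spacing_mm
  keep <- logical(length(values))
  kept <- matrix(0, 0, 3)
  for (t in seq_along(values)) {
    if (nrow(kept) > 0) {
      d2 <- (kept[, 1] - coords[t, 1])^2 + (kept[, 2] - coords[t, 2])^2 +
        (kept[, 3] - coords[t, 3])^2
      if (any(d2 < r_vox^2)) next
    }
    keep[t] <- TRUE
    kept <- rbind(kept, coords[t, ])
  }
  coords <- coords[keep, , drop = FALSE]
  data.frame(i = coords[, 1], j = coords[, 2], k = coords[, 3],
             response = values[keep],
             scale_mm = response$argmax_scale[coords])
}

patch_bounds <- function(center, side, dim) {
  lo <- as.integer(center) - side %/% 2L
  hi <- lo + side - 1L
  list(lo = lo, hi = hi,
       clo = pmax(lo, 1L), chi = pmin(hi, dim))
}

crop_patch <- function(data, center, side) {
  b <- patch_bounds(center, side, dim(data))
  patch <- array(0, rep(side, 3L))
  src <- lapply(1:3, function(a) b$clo[a]:b$chi[a])
  dst <- lapply(1:3, function(a) (b$clo[a] - b$lo[a] + 1L):(b$chi[a] - b$lo[a] + 1L))
  patch[dst[[1]], dst[[2]], dst[[3]]] <-
    data[src[[1]], src[[2]], src[[3]]]
  patch
}

#' Crop candidate patches and assign training labels
#'
#' Cubic patches of side `patch_side_vox` are cropped around each candidate
#' point (zero-padded at volume edges). A candidate is labelled `positive` if
#' some annotated aneurysm lies entirely inside the patch bounds, `partial`
#' if an annotation intersects the bounds but none is fully contained
#' (partials are discarded from model training), and `negative` otherwise.
#'
#' @param vol the normalized [aneu_volume] patches are cropped from.
#' @param points candidate points from [extract_candidate_points()].
#' @param annotations an `annotation_set` (may be empty).
#' @param patch_side_vox cubic patch side in voxels (default 32, i.e. 12.5 mm
#'   at 0.3906 mm spacing; use 48 to fully contain 15 mm aneurysms).
#' @return A list of candidates, each with `center_ijk`, `patch`,
#'   `peak_scale_mm`, `response`, `label`, and empty `features`/`probability`
#'   slots.
#' @export
crop_and_label <- function(vol, points, annotations, patch_side_vox = 32L) {
  stopifnot(inherits(vol, "aneu_volume"), patch_side_vox >= 4)
  d <- dim(vol$data)
  n_an <- length(annotations$regions)
  lapply(seq_len(nrow(points)), function(t) {
    center <- c(points$i[t], points$j[t], points$k[t])
    b <- patch_bounds(center, as.integer(patch_side_vox), d)
    label <- "negative"
    if (n_an > 0) {
      contained <- FALSE; intersects <- FALSE
      for (r in annotations$regions) {
        ins <- r$coords[, 1] >= b$lo[1] & r$coords[, 1] <= b$hi[1] &
               r$coords[, 2] >= b$lo[2] & r$coords[, 2] <= b$hi[2] &
               r$coords[, 3] >= b$lo[3] & r$coords[, 3] <= b$hi[3]
        if (all(ins)) contained <- TRUE
        if (any(ins)) intersects <- TRUE
      }
      label <- if (contained) "positive" else if (intersects) "partial"
               else "negative"
    }
    list(center_ijk = center,
         patch = crop_patch(vol$data, center, as.integer(patch_side_vox)),
         peak_scale_mm = points$scale_mm[t],
         response = points$response[t],
         label = label,
         features = NULL,
         probability = NA_real_)
  })
}

#' Hand-crafted candidate features for the pre-filter
#'
#' Fixed-order named features computed on the candidate patch: sphericity of
#' the bright (artery-mask) connected component at the patch center,
#' `pi^(1/3) * (6 V)^(2/3) / A` with V the component volume and A its surface
#' area (estimated as the integrated gradient magnitude of the smoothed
#' component indicator, which is orientation-unbiased where a raw
#' exposed-face count is not), component volume in mm^3, max/mean of the blob, line and
#' plane responses in the patch, response ratios at the center voxel,
#' distance from the center to the mask boundary, and patch intensity
#' mean/sd. An empty bright component yields sentinel zeros for the shape
#' features.
#'
#' @param candidate one element of [crop_and_label()] output.
#' @param response the volume's `shape_response`.
#' @param artery_mask logical artery mask of the full volume.
#' @return Named numeric feature vector (fixed order).
#' @export
candidate_features <- function(candidate, response, artery_mask) {
  side <- dim(candidate$patch)[1]
  sp <- response$spacing_mm
  center <- candidate$center_ijk
  msub <- crop_patch(artery_mask + 0, center, side) > 0.5
  bsub <- crop_patch(response$blob, center, side)
  lsub <- crop_patch(response$line, center, side)
  psub <- crop_patch(response$plane, center, side)
  cc <- side %/% 2L + 1L
  sph <- 0; vol_mm3 <- 0; dist_boundary <- 0
  if (msub[cc, cc, cc]) {
    lab <- cpp_label_components(msub)
    comp <- lab == lab[cc, cc, cc]
    V <- sum(comp)
    A <- surface_area_mm2(comp, sp)
    V_mm3 <- V * sp^3
    sph <- if (A > 0) pi^(1 / 3) * (6 * V_mm3)^(2 / 3) / A else 0
    vol_mm3 <- V_mm3
    bg <- which(!comp, arr.ind = TRUE)
    if (nrow(bg) > 0) {
      dist_boundary <- sqrt(min((bg[, 1] - cc)^2 + (bg[, 2] - cc)^2 +
                                (bg[, 3] - cc)^2))
    } else dist_boundary <- side / 2
  }
  eps <- 1e-12
  b0 <- response$blob[center[1], center[2], center[3]]
  l0 <- response$line[center[1], center[2], center[3]]
  p0 <- response$plane[center[1], center[2], center[3]]
  c(sphericity = sph,
    bright_volume_mm3 = vol_mm3,
    dist_to_boundary_vox = dist_boundary,
    blob_max = max(bsub), blob_mean = mean(bsub),
    line_max = max(lsub), line_mean = mean(lsub),
    plane_max = max(psub), plane_mean = mean(psub),
    line_blob_ratio = l0 / (b0 + eps),
    plane_blob_ratio = p0 / (b0 + eps),
    intensity_mean = mean(candidate$patch),
    intensity_sd = sd(as.numeric(candidate$patch)))
}

# surface area of a logical component, in mm^2: integrate the gradient
# magnitude of the Gaussian-smoothed indicator (sigma 1 voxel). For a flat
# interface the smoothed-step derivative integrates to exactly 1 per unit
# area, so the estimate is orientation-unbiased, unlike voxel-face counting.
surface_area_mm2 <- function(comp, spacing_mm) {
  f <- cpp_gaussian_smooth3d(comp + 0, 1.0)
  d <- dim(f)
  grad_axis <- function(axis) {
    g <- array(0, d)
    n <- d[axis]
    idx <- function(r) switch(axis,
                              list(r, seq_len(d[2]), seq_len(d[3])),
                              list(seq_len(d[1]), r, seq_len(d[3])),
                              list(seq_len(d[1]), seq_len(d[2]), r))
    hi <- idx(3:n); lo <- idx(seq_len(n - 2)); mid <- idx(2:(n - 1))
    g[mid[[1]], mid[[2]], mid[[3]]] <-
      (f[hi[[1]], hi[[2]], hi[[3]]] - f[lo[[1]], lo[[2]], lo[[3]]]) / 2
    g
  }
  gm <- sqrt(grad_axis(1)^2 + grad_axis(2)^2 + grad_axis(3)^2)
  sum(gm) * spacing_mm^2
}

#' Fit the candidate pre-filter
#'
#' Gradient-boosted decision trees (xgboost) on the hand-crafted candidate
#' features, positives vs negatives (partials excluded upstream). The
#' operating threshold is chosen on the supplied data to retain at least
#' `retention` of the positives, mimicking a high-sensitivity pre-filter.
#'
#' @param features numeric matrix (candidates x features).
#' @param labels character or factor; `"positive"` vs anything else.
#' @param retention minimum fraction of positives the threshold must keep.
#' @param nrounds,max_depth,eta xgboost parameters.
#' @return An object of class `aneu_prefilter` with the booster, feature
#'   names and operating `threshold`.
#' @export
fit_prefilter <- function(features, labels, retention = 0.99,
                          nrounds = 40, max_depth = 3, eta = 0.3) {
  y <- as.integer(labels == "positive")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("pre-filter training needs both positive and negative candidates")
  dtrain <- xgboost::xgb.DMatrix(as.matrix(features), label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  scores <- predict(booster, as.matrix(features))
  pos_scores <- scores[y == 1]
  threshold <- as.numeric(quantile(pos_scores, 1 - retention, names = FALSE,
                                   type = 1))
  structure(list(booster = booster, feature_names = colnames(features),
                 threshold = threshold, retention = retention),
            class = "aneu_prefilter")
}

#' Score candidates with the pre-filter
#'
#' @param prefilter an [fit_prefilter()] `aneu_prefilter`.
#' @param features numeric matrix of candidate features.
#' @return Numeric scores in `[0, 1]`.
#' @export
prefilter_scores <- function(prefilter, features) {
  stopifnot(inherits(prefilter, "aneu_prefilter"))
  predict(prefilter$booster, as.matrix(features))
}

#' Remove low-scoring candidates
#'
#' Drops candidates the pre-filter scores below its operating threshold;
#' order of the kept candidates is preserved. `prefilter = NULL` accepts
#' everything (identity).
#'
#' @param candidates list of candidates carrying `features`.
#' @param prefilter an `aneu_prefilter`, or `NULL` to accept all.
#' @return The kept candidates, original order preserved.
#' @export
prefilter_candidates <- function(candidates, prefilter) {
  if (length(candidates) == 0) return(candidates)
  if (is.null(prefilter)) return(candidates)
  if (!inherits(prefilter, "aneu_prefilter"))
    stop("prefilter must be a trained aneu_prefilter (or NULL)")
  feats <- do.call(rbind, lapply(candidates, `[[`, "features"))
  if (is.null(feats) || anyNA(feats))
    stop("candidates lack feature vectors; run candidate_features() first")
  scores <- prefilter_scores(prefilter, feats)
  candidates[scores >= prefilter$threshold]
}
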