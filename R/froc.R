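#' Match detections against ground-truth aneurysms
#'
#' A detection is a true positive iff its footprint shares at least one
#' voxel with some annotated aneurysm ("contains a part of the aneurysm");
#' otherwise it is a false positive. An aneurysm counts as detected iff at
#' least one true-positive detection intersects it; multiple true positives
#' on one aneurysm count it once for sensitivity.
#'
#' @param detections list of detections with `voxels` (linear indices).
#' @param annotations an `annotation_set` on the same voxel grid.
#' @param dim volume dimensions (defaults to `annotations$dim`); detections
#'   indexed on a different geometry are an error.
#' @return List with `detections` (data.frame: `score`, `tp`,
#'   `matched_ids`) and `detected` (named logical per aneurysm).
#' @export
match_detections <- function(detections, annotations, dim = annotations$dim) {
  if (!identical(as.integer(dim), as.integer(annotations$dim)))
    stop("detections and annotations are on different volume geometries")
  regions <- annotations$regions
  an_idx <- lapply(regions, function(r)
    r$coords[, 1] + dim[1] * (r$coords[, 2] - 1L) +
      prod(dim[1:2]) * (r$coords[, 3] - 1L))
  n_an <- length(regions)
  detected <- setNames(rep(FALSE, n_an),
                       vapply(regions, function(r) as.character(r$id),
                              character(1)))
  if (length(detections) == 0) {
    return(list(detections = data.frame(score = numeric(), tp = logical(),
                                        matched_ids = character()),
                detected = detected))
  }
  rows <- lapply(detections, function(det) {
    hit <- which(vapply(an_idx, function(ai) any(det$voxels %in% ai),
                        logical(1)))
    data.frame(score = det$score, tp = length(hit) > 0,
               matched_ids = paste(vapply(regions[hit], `[[`, 1, "id"),
                                   collapse = ","))
  })
  df <- do.call(rbind, rows)
  for (i in seq_len(nrow(df))) {
    if (df$tp[i]) {
      ids <- strsplit(df$matched_ids[i], ",")[[1]]
      detected[ids] <- TRUE
    }
  }
  list(detections = df, detected = detected)
}

#' FROC curve over a multi-case detection set
#'
#' For each threshold (descending over the observed detection scores) the
#' detections with score >= threshold are kept, matching is re-evaluated,
#' and the operating point records sensitivity (detected aneurysms over all
#' aneurysms, pooled over cases) and false positives per case (total false
#' positives over the number of cases).
#'
#' @param cases list, one element per case, each with `detections` (list of
#'   detections) and `annotations` (an `annotation_set`).
#' @param thresholds optional explicit thresholds; default the descending
#'   unique detection scores.
#' @return data.frame of class `froc_curve` with columns `threshold`,
#'   `fps_per_case`, `sensitivity`; attributes `n_cases`, `n_aneurysms`.
#' @export
froc_curve <- function(cases, thresholds = NULL) {
  n_cases <- length(cases)
  stopifnot(n_cases >= 1)
  n_an <- sum(vapply(cases, function(cs) length(cs$annotations$regions),
                     integer(1)))
  if (n_an == 0) stop("no aneurysms in the cohort: sensitivity is undefined")
  per_case <- lapply(cases, function(cs) {
    m <- match_detections(cs$detections, cs$annotations)
    list(df = m$detections, n_an = length(cs$annotations$regions))
  })
  all_scores <- unlist(lapply(per_case, function(pc) pc$df$score))
  if (is.null(thresholds)) {
    thresholds <- sort(unique(all_scores), decreasing = TRUE)
    if (length(thresholds) == 0) thresholds <- 1
  }
  pts <- lapply(thresholds, function(t) {
    tp_an <- 0L
    fps <- 0L
    for (pc in per_case) {
      act <- pc$df$score >= t
      fps <- fps + sum(act & !pc$df$tp)
      ids <- unique(unlist(strsplit(pc$df$matched_ids[act & pc$df$tp], ",")))
      tp_an <- tp_an + length(ids[nzchar(ids)])
    }
    data.frame(threshold = t, fps_per_case = fps / n_cases,
               sensitivity = tp_an / n_an)
  })
  out <- do.call(rbind, pts)
  attr(out, "n_cases") <- n_cases
  attr(out, "n_aneurysms") <- n_an
  class(out) <- c("froc_curve", class(out))
  out
}

#' Operating points of a FROC curve
#'
#' Reports the curve's maximum sensitivity with its false-positive rate, the
#' FPs/case needed to reach a fixed sensitivity (default 80%), and the
#' sensitivity attainable at a fixed FPs/case budget (default 3.0), with
#' linear interpolation between adjacent curve points. An unreachable
#' sensitivity target is reported explicitly (`NA` value,
#' `reachable = FALSE`).
#'
#' @param curve a [froc_curve()].
#' @param sens_target fixed sensitivity (default 0.80).
#' @param fps_target fixed FPs/case (default 3.0).
#' @return List with `max_sensitivity`, `fps_at_max_sensitivity`,
#'   `fps_at_sensitivity`, `sens_reachable`, `sensitivity_at_fps`, and the
#'   nearest raw curve points.
#' @export
operating_points <- function(curve, sens_target = 0.80, fps_target = 3.0) {
  stopifnot(nrow(curve) >= 1)
  ord <- order(curve$fps_per_case, curve$sensitivity)
  fps <- curve$fps_per_case[ord]
  sens <- curve$sensitivity[ord]
  # collapse duplicate sensitivities to their smallest fps (monotone hull)
  max_sens <- max(sens)
  fps_at_max <- min(fps[sens == max_sens])
  fps_at_s <- NA_real_
  reachable <- max_sens >= sens_target
  if (reachable) {
    i <- which(sens >= sens_target)[1]
    if (i == 1 || sens[i] == sens_target) {
      fps_at_s <- min(fps[sens >= sens_target])
    } else {
      s0 <- sens[i - 1]; s1 <- sens[i]
      f0 <- fps[i - 1]; f1 <- fps[i]
      fps_at_s <- if (s1 > s0) f0 + (sens_target - s0) / (s1 - s0) * (f1 - f0)
                  else min(f0, f1)
    }
  }
  if (fps_target >= max(fps)) {
    sens_at_f <- max_sens
  } else if (fps_target < min(fps)) {
    sens_at_f <- 0
  } else {
    j <- which(fps > fps_target)[1]
    if (fps[j - 1] == fps_target) {
      sens_at_f <- max(sens[fps <= fps_target])
    } else {
      f0 <- fps[j - 1]; f1 <- fps[j]
      s0 <- max(sens[fps <= fps_target]); s1 <- sens[j]
      sens_at_f <- s0 + (fps_target - f0) / (f1 - f0) * (s1 - s0)
    }
  }
  nearest <- function(target_fps) {
    i <- which.min(abs(fps - target_fps))
    c(fps_per_case = fps[i], sensitivity = sens[i])
  }
  list(max_sensitivity = max_sens,
       fps_at_max_sensitivity = fps_at_max,
       sens_target = sens_target,
       fps_at_sensitivity = fps_at_s,
       sens_reachable = reachable,
       fps_target = fps_target,
       sensitivity_at_fps = sens_at_f,
       nearest_point_sens = if (reachable) nearest(fps_at_s) else NULL,
       nearest_point_fps = nearest(fps_target))
}

#' Sensitivity stratified by aneurysm size and location
#'
#' Per-bin sensitivity with the conventional size bins (< 3.0, 3.0-5.9,
#' 6.0-8.9, >= 9.0 mm) and per-location detected/missed counts. Empty bins
#' are reported with `n = 0` and `NA` sensitivity.
#'
#' @param cases list per case with `annotations` and `detected` (logical per
#'   aneurysm, e.g. from [match_detections()]).
#' @param size_breaks inner bin edges in mm.
#' @return List with data.frames `by_size` and `by_location`.
#' @export
stratified_report <- function(cases, size_breaks = c(3, 6, 9)) {
  rows <- list()
  for (cs in cases) {
    regs <- cs$annotations$regions
    if (length(regs) == 0) next
    det <- cs$detected
    for (r in regs) {
      rows[[length(rows) + 1L]] <- data.frame(
        diameter_mm = r$equivalent_diameter_mm,
        location = if (is.null(r$location)) NA_character_ else r$location,
        detected = isTRUE(det[[as.character(r$id)]]))
    }
  }
  breaks <- c(-Inf, size_breaks, Inf)
  labels <- c(sprintf("<%.1f", size_breaks[1]),
              vapply(seq_len(length(size_breaks) - 1), function(i)
                sprintf("%.1f-%.1f", size_breaks[i], size_breaks[i + 1] - 0.1),
                character(1)),
              sprintf(">=%.1f", size_breaks[length(size_breaks)]))
  if (length(rows) == 0) {
    by_size <- data.frame(size_bin = labels, n = 0L, detected = 0L,
                          sensitivity = NA_real_)
    return(list(by_size = by_size,
                by_location = data.frame(location = character(), n = integer(),
                                         detected = integer(),
                                         sensitivity = numeric())))
  }
  df <- do.call(rbind, rows)
  df$size_bin <- cut(df$diameter_mm, breaks = breaks, labels = labels,
                     right = FALSE)
  by_size <- do.call(rbind, lapply(labels, function(b) {
    sub <- df[df$size_bin == b, ]
    data.frame(size_bin = b, n = nrow(sub), detected = sum(sub$detected),
               sensitivity = if (nrow(sub) > 0) mean(sub$detected) else NA_real_)
  }))
  locs <- df[!is.na(df$location), ]
  by_location <- if (nrow(locs) > 0) {
    do.call(rbind, lapply(sort(unique(locs$location)), function(l) {
      sub <- locs[locs$location == l, ]
      data.frame(location = l, n = nrow(sub), detected = sum(sub$detected),
                 sensitivity = mean(sub$detected))
    }))
  } else {
    data.frame(location = character(), n = integer(), detected = integer(),
               sensitivity = numeric())
  }
  list(by_size = by_size, by_location = by_location)
}

#' Plot a FROC curve
#'
#' @param x a `froc_curve`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.froc_curve <- function(x, ...) {
  ord <- order(x$fps_per_case)
  plot(x$fps_per_case[ord], x$sensitivity[ord], type = "b", pch = 16,
       xlab = "FPs/case", ylab = "Sensitivity", ylim = c(0, 1), ...)
  abline(h = 0.8, lty = 2, col = "grey50")
  invisible(x)
}
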