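mk_annotations <- function(centers, radius, d = c(40, 40, 40), sp = 0.3906) {
  regions <- lapply(seq_along(radius), function(a) {
    coords <- ball_voxels(centers[a, ], radius[a], d)
    list(id = a, coords = coords, centroid_ijk = centers[a, ],
         equivalent_diameter_mm = (6 * nrow(coords) / pi)^(1 / 3) * sp,
         location = c("trunk", "bifurcation", "distal")[1 + a %% 3])
  })
  annotation_set(regions, d, sp)
}

mk_detection <- function(vox, score, d = c(40, 40, 40)) {
  idx <- vox[, 1] + d[1] * (vox[, 2] - 1) + prod(d[1:2]) * (vox[, 3] - 1)
  list(voxels = idx, rep_point = as.integer(round(colMeans(vox))),
       vote_count = 6L, score = score)
}

test_that("a single shared voxel makes a detection a true positive", {
  an <- mk_annotations(matrix(c(15, 15, 15), 1), 4)
  border <- an$regions[[1]]$coords[1, , drop = FALSE]
  tp <- mk_detection(border, 0.9)
  fp <- mk_detection(matrix(c(35, 35, 35), 1), 0.8)
  m <- match_detections(list(tp, fp), an)
  expect_identical(m$detections$tp, c(TRUE, FALSE))
  expect_true(m$detected[["1"]])
  # no detections: sensitivity bookkeeping stays defined
  m0 <- match_detections(list(), an)
  expect_false(any(m0$detected))
  expect_error(match_detections(list(tp), an, dim = c(10, 10, 10)),
               "geometries")
})

test_that("matching is invariant to annotation id relabelling", {
  an <- mk_annotations(rbind(c(12, 12, 12), c(30, 30, 30)), c(4, 3))
  det <- mk_detection(an$regions[[2]]$coords[1:3, ], 0.7)
  m1 <- match_detections(list(det), an)
  an_swapped <- an
  an_swapped$regions <- an_swapped$regions[c(2, 1)]
  an_swapped$regions[[1]]$id <- 1; an_swapped$regions[[2]]$id <- 2
  m2 <- match_detections(list(det), an_swapped)
  expect_equal(sum(m1$detected), sum(m2$detected))
  expect_equal(m1$detections$tp, m2$detections$tp)
})

test_that("FROC curves match an exhaustive threshold-loop recomputation", {
  set.seed(41)
  d <- c(40, 40, 40)
  cases <- lapply(1:5, function(cs) {
    an <- mk_annotations(rbind(c(12, 12, 12), c(30, 28, 20)), c(4, 3), d)
    dets <- lapply(1:4, function(t) {
      if (t <= 2) {
        mk_detection(an$regions[[t]]$coords[1:4, ], runif(1), d)
      } else {
        mk_detection(ball_voxels(sample(30:38, 3, replace = TRUE), 2, d),
                     runif(1), d)
      }
    })
    list(detections = dets[sample(4)], annotations = an)
  })
  curve <- froc_curve(cases)
  # independent recomputation: explicit loop over thresholds and cases
  scores <- sort(unique(unlist(lapply(cases, function(cs)
    vapply(cs$detections, `[[`, numeric(1), "score")))), decreasing = TRUE)
  for (t in scores) {
    tp_an <- 0; fp <- 0
    for (cs in cases) {
      for (r in cs$annotations$regions) {
        hit <- FALSE
        ridx <- r$coords[, 1] + 40 * (r$coords[, 2] - 1) +
          1600 * (r$coords[, 3] - 1)
        for (det in cs$detections)
          if (det$score >= t && any(det$voxels %in% ridx)) hit <- TRUE
        tp_an <- tp_an + hit
      }
      for (det in cs$detections) {
        if (det$score < t) next
        is_tp <- FALSE
        for (r in cs$annotations$regions) {
          ridx <- r$coords[, 1] + 40 * (r$coords[, 2] - 1) +
            1600 * (r$coords[, 3] - 1)
          if (any(det$voxels %in% ridx)) is_tp <- TRUE
        }
        fp <- fp + !is_tp
      }
    }
    row <- curve[abs(curve$threshold - t) < 1e-12, ]
    expect_equal(row$sensitivity, tp_an / 10)
    expect_equal(row$fps_per_case, fp / 5)
  }
  # curve shape: sensitivity never decreases as FPs/case increases
  ord <- order(curve$fps_per_case)
  expect_true(all(diff(curve$sensitivity[ord]) >= 0))
})

test_that("degenerate curves behave as documented", {
  d <- c(40, 40, 40)
  an <- mk_annotations(matrix(c(15, 15, 15), 1), 4, d)
  # oracle detector: one TP per aneurysm, no FPs
  oracle <- list(list(detections = list(
    mk_detection(an$regions[[1]]$coords[1:5, ], 0.99, d)), annotations = an))
  crv <- froc_curve(oracle)
  expect_equal(nrow(crv), 1)
  expect_equal(crv$fps_per_case, 0)
  expect_equal(crv$sensitivity, 1)
  # all detections false positive: sensitivity 0 at every threshold
  allfp <- list(list(detections = list(
    mk_detection(matrix(c(35, 35, 35), 1), 0.7, d),
    mk_detection(matrix(c(2, 2, 2), 1), 0.4, d)), annotations = an))
  crv2 <- froc_curve(allfp)
  expect_true(all(crv2$sensitivity == 0))
  # zero aneurysms: error
  none <- list(list(detections = list(), annotations = annotation_set(list(), d, 0.3906)))
  expect_error(froc_curve(none), "undefined")
})

test_that("operating points interpolate the constructed curve correctly", {
  curve <- data.frame(threshold = c(0.9, 0.6, 0.3),
                      fps_per_case = c(0, 2, 5),
                      sensitivity = c(0.5, 0.8, 0.9))
  class(curve) <- c("froc_curve", "data.frame")
  op <- operating_points(curve, sens_target = 0.8, fps_target = 3.0)
  expect_equal(op$fps_at_sensitivity, 2)
  expect_equal(op$sensitivity_at_fps, 0.8 + (3 - 2) / (5 - 2) * 0.1)
  expect_equal(op$max_sensitivity, 0.9)
  expect_equal(op$fps_at_max_sensitivity, 5)
  # perfect detector: zero FPs at the 80% target
  perfect <- data.frame(threshold = 0.5, fps_per_case = 0, sensitivity = 1)
  class(perfect) <- c("froc_curve", "data.frame")
  expect_equal(operating_points(perfect)$fps_at_sensitivity, 0)
  # unreachable sensitivity is flagged, not fabricated
  low <- data.frame(threshold = 0.5, fps_per_case = 1, sensitivity = 0.6)
  class(low) <- c("froc_curve", "data.frame")
  op_low <- operating_points(low, sens_target = 0.8)
  expect_false(op_low$sens_reachable)
  expect_true(is.na(op_low$fps_at_sensitivity))
})

test_that("stratified sensitivities agree with a direct group-by", {
  set.seed(42)
  d <- c(40, 40, 40)
  cases <- lapply(1:4, function(cs) {
    centers <- rbind(c(10, 10, 10), c(28, 28, 28))
    radius <- runif(2, 3, 9)
    an <- mk_annotations(centers, radius, d)
    detected <- setNames(runif(2) < 0.7, c("1", "2"))
    list(annotations = an, detected = detected)
  })
  rep <- stratified_report(cases)
  # direct group-by oracle
  diam <- unlist(lapply(cases, function(cs)
    vapply(cs$annotations$regions, `[[`, numeric(1),
           "equivalent_diameter_mm")))
  det <- unlist(lapply(cases, function(cs) cs$detected))
  bins <- cut(diam, c(-Inf, 3, 6, 9, Inf), right = FALSE,
              labels = rep$by_size$size_bin)
  for (b in levels(bins)) {
    sub <- det[bins == b]
    row <- rep$by_size[rep$by_size$size_bin == b, ]
    expect_equal(row$n, length(sub))
    if (length(sub) > 0) expect_equal(row$sensitivity, mean(sub))
    else expect_true(is.na(row$sensitivity))
  }
  # pooled sensitivity equals the size-bin-weighted mean
  pooled <- sum(rep$by_size$detected) / sum(rep$by_size$n)
  expect_equal(pooled, mean(det))
  # missing locations degrade gracefully
  cases_noloc <- lapply(cases, function(cs) {
    cs$annotations$regions <- lapply(cs$annotations$regions, function(r) {
      r$location <- NULL; r
    })
    cs
  })
  rep2 <- stratified_report(cases_noloc)
  expect_equal(nrow(rep2$by_location), 0)
  expect_equal(rep2$by_size$n, rep$by_size$n)
})
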