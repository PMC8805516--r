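# closed-form blob response of a Gaussian blob of scale s0 and amplitude A
# under sigma^2-normalized Hessian filtering at scale s (all in voxels):
# the smoothed blob is Gaussian with variance s0^2 + s^2, its Hessian at the
# center has three equal eigenvalues -A * s0^3 / (s0^2 + s^2)^(5/2), and the
# blob measure l3^2/|l1| reduces to |lambda|.
analytic_blob <- function(s, s0, A) s^2 * A * s0^3 / (s0^2 + s^2)^(5 / 2)

test_that("blob response on a Gaussian blob matches the closed form", {
  s0 <- 2; A <- 100; sp <- 0.3906
  vol <- gaussian_blob_volume(n = 41, sigma = s0, amplitude = A, spacing = sp)
  scales_vox <- c(1.0, 1.4, 1.63, 2.0, 2.56)
  resp <- shape_filter(vol, scales_mm = scales_vox * sp)
  cc <- 21
  measured <- resp$blob[cc, cc, cc]
  expected <- max(analytic_blob(scales_vox, s0, A))
  expect_lt(abs(measured - expected) / expected, 0.05)
  # blob dominates line and plane at the blob center
  expect_gt(measured, resp$line[cc, cc, cc])
  expect_gt(measured, resp$plane[cc, cc, cc])
  # best scale agrees with the analytic optimum over the same grid
  best <- scales_vox[which.max(analytic_blob(scales_vox, s0, A))]
  expect_equal(resp$argmax_scale[cc, cc, cc] / sp, best, tolerance = 1e-6)
})

test_that("a long Gaussian cylinder drives line response, not blob", {
  sp <- 0.3906
  n <- 33; len <- 81; s0 <- 2; A <- 100
  g <- expand.grid(i = 1:n, j = 1:n)
  slice <- matrix(A * exp(-((g$i - 17)^2 + (g$j - 17)^2) / (2 * s0^2)), n, n)
  cyl <- array(rep(slice, len), c(n, n, len))
  resp <- shape_filter(aneu_volume(cyl, sp), scales_mm = c(1.4, 2.0) * sp)
  expect_lt(resp$blob[17, 17, 41], 1e-6)
  expect_gt(resp$line[17, 17, 41], 1)
  # constant volume: all responses exactly zero
  r0 <- shape_filter(aneu_volume(array(3, c(16, 16, 16)), sp), c(0.8))
  expect_true(all(r0$blob == 0) && all(r0$line == 0) && all(r0$plane == 0))
  # anisotropic input is rejected
  va <- aneu_volume(array(0, c(8, 8, 8)), c(0.5, 0.5, 1))
  expect_error(shape_filter(va, 1), "isotropic")
})

test_that("blob filtering commutes with exact 90-degree rotations", {
  sp <- 0.3906
  vol <- gaussian_blob_volume(n = 33, center = c(12, 17, 22), sigma = 2,
                              amplitude = 50, spacing = sp)
  resp <- shape_filter(vol, scales_mm = c(1.4, 2.0) * sp)
  # rotate 90 degrees about the k axis: (i, j, k) -> (j, n+1-i, k)
  rot <- aperm(vol$data, c(2, 1, 3))[, 33:1, ]
  resp_rot <- shape_filter(aneu_volume(rot, sp), scales_mm = c(1.4, 2.0) * sp)
  mapped <- resp_rot$blob[17, 33 + 1 - 12, 22]
  expect_equal(mapped, resp$blob[12, 17, 22], tolerance = 1e-8)
})

test_that("scale selection tracks blob size within one scale step", {
  sp <- 0.3906
  scales_vox <- c(1.0, 1.5, 2.2, 3.3)
  for (s0 in c(1.5, 2, 3)) {
    vol <- gaussian_blob_volume(n = 41, sigma = s0, amplitude = 100,
                                spacing = sp)
    resp <- shape_filter(vol, scales_mm = scales_vox * sp)
    picked <- resp$argmax_scale[21, 21, 21] / sp
    # optimum of the continuous response is sigma = sqrt(2/3) * s0
    target <- sqrt(2 / 3) * s0
    steps <- which.min(abs(scales_vox - picked)) -
      which.min(abs(scales_vox - target))
    expect_lte(abs(steps), 1)
  }
})

test_that("candidate points sit on blob maxima and respect suppression", {
  sp <- 0.3906
  # zero response field -> no candidates
  z <- structure(list(blob = array(0, c(16, 16, 16)),
                      line = array(0, c(16, 16, 16)),
                      plane = array(0, c(16, 16, 16)),
                      argmax_scale = array(1, c(16, 16, 16)),
                      scales_mm = 1, spacing_mm = sp),
                 class = "shape_response")
  expect_equal(nrow(extract_candidate_points(z, array(TRUE, c(16, 16, 16)),
                                             min_response = 0)), 0)
  # one blob on a tube -> exactly one candidate within 2 voxels of center
  vol <- gaussian_blob_volume(n = 41, center = c(21, 21, 21), sigma = 2,
                              amplitude = 100, spacing = sp)
  vol$data <- vol$data + 1e-3  # keep mask interesting
  resp <- shape_filter(vol, scales_mm = c(1.4, 2.0) * sp)
  mask <- array(TRUE, dim(vol$data))
  pts <- extract_candidate_points(resp, mask, min_response = 1,
                                  nms_radius_mm = 3)
  expect_equal(nrow(pts), 1)
  expect_lte(sqrt(sum((unlist(pts[1, 1:3]) - 21)^2)), 2)
  # two blobs farther apart than the suppression radius -> two candidates
  two <- gaussian_blob_volume(n = 49, center = c(14, 14, 14), sigma = 2,
                              amplitude = 100, spacing = sp)
  blob2 <- gaussian_blob_volume(n = 49, center = c(38, 38, 38), sigma = 2,
                                amplitude = 90, spacing = sp)
  two$data <- two$data + blob2$data
  resp2 <- shape_filter(two, scales_mm = c(1.4, 2.0) * sp)
  pts2 <- extract_candidate_points(resp2, array(TRUE, dim(two$data)),
                                   min_response = 1, nms_radius_mm = 3)
  expect_equal(nrow(pts2), 2)
  # candidates are sorted by descending response
  expect_true(all(diff(pts2$response) <= 0))
})

test_that("containment labels agree with a brute-force check", {
  set.seed(9)
  d <- c(40, 40, 40)
  vol <- aneu_volume(array(rnorm(prod(d)), d), 0.3906)
  for (rep in 1:20) {
    centers <- matrix(sample(8:33, 6, replace = TRUE), 2, 3)
    radius <- runif(2, 2, 5)
    regions <- lapply(1:2, function(a) {
      list(id = a, coords = ball_voxels(centers[a, ], radius[a], d),
           centroid_ijk = centers[a, ], equivalent_diameter_mm = 2 * radius[a] * 0.3906,
           location = "trunk")
    })
    an <- annotation_set(regions, d, 0.3906)
    pts <- data.frame(i = sample(5:36, 4), j = sample(5:36, 4),
                      k = sample(5:36, 4), response = runif(4), scale_mm = 1)
    side <- 16L
    cands <- crop_and_label(vol, pts, an, side)
    for (t in seq_len(nrow(pts))) {
      lo <- c(pts$i[t], pts$j[t], pts$k[t]) - side %/% 2L
      hi <- lo + side - 1L
      inside_all <- inside_any <- FALSE
      for (r in regions) {
        ins <- rep(TRUE, nrow(r$coords))
        for (a in 1:3)
          ins <- ins & r$coords[, a] >= lo[a] & r$coords[, a] <= hi[a]
        if (all(ins)) inside_all <- TRUE
        if (any(ins)) inside_any <- TRUE
      }
      want <- if (inside_all) "positive" else if (inside_any) "partial"
              else "negative"
      expect_identical(cands[[t]]$label, want)
    }
  }
})

test_that("patches are cropped around centers with zero padding at edges", {
  d <- c(20, 20, 20)
  x <- array(seq_len(prod(d)), d)
  vol <- aneu_volume(x, 0.3906)
  pts <- data.frame(i = c(10L, 2L), j = c(10L, 2L), k = c(10L, 19L),
                    response = c(1, 1), scale_mm = 1)
  an <- annotation_set(list(), d, 0.3906)
  cands <- crop_and_label(vol, pts, an, 8L)
  expect_equal(dim(cands[[1]]$patch), c(8, 8, 8))
  expect_equal(cands[[1]]$patch[5, 5, 5], x[10, 10, 10])
  # edge patch keeps in-volume values and zero-pads the rest
  expect_equal(cands[[2]]$patch[5, 5, 5], x[2, 2, 19])
  expect_true(any(cands[[2]]$patch == 0))
})

test_that("sphericity ranks spheres above tubes and handles empties", {
  sp <- 0.3906
  d <- c(33, 33, 33)
  sphere_mask <- rasterized_sphere(33, 10)
  tube_mask <- array(FALSE, d)
  tube_mask[13:21, 13:21, ] <- TRUE
  dummy_resp <- structure(list(blob = array(0, d), line = array(0, d),
                               plane = array(0, d),
                               argmax_scale = array(1, d),
                               scales_mm = 1, spacing_mm = sp),
                          class = "shape_response")
  cand <- list(center_ijk = c(17, 17, 17), patch = array(0, c(32, 32, 32)))
  f_sphere <- candidate_features(cand, dummy_resp, sphere_mask)
  f_tube <- candidate_features(cand, dummy_resp, tube_mask)
  expect_gte(f_sphere[["sphericity"]], 0.95)
  expect_lt(f_tube[["sphericity"]], f_sphere[["sphericity"]])
  # empty bright component: sentinel zeros for shape features
  f_empty <- candidate_features(cand, dummy_resp, array(FALSE, d))
  expect_equal(f_empty[["sphericity"]], 0)
  expect_equal(f_empty[["bright_volume_mm3"]], 0)
  expect_named(f_empty, names(f_sphere))
})

test_that("the pre-filter retains the configured share of positives", {
  set.seed(10)
  n <- 400
  # overlapping classes so the booster cannot separate perfectly
  feats <- cbind(x1 = c(rnorm(n / 2, 1.0), rnorm(n / 2, 0)),
                 x2 = c(rnorm(n / 2, 0.5), rnorm(n / 2, 0)))
  labels <- rep(c("positive", "negative"), each = n / 2)
  pf <- fit_prefilter(feats, labels, retention = 0.99)
  scores <- prefilter_scores(pf, feats)
  kept_pos <- mean(scores[labels == "positive"] >= pf$threshold)
  expect_gte(kept_pos, 0.99)
  # candidate-list filtering preserves order and drops low scorers
  cands <- lapply(seq_len(n), function(i)
    list(center_ijk = c(1, 1, 1), features = feats[i, ], label = labels[i]))
  kept <- prefilter_candidates(cands, pf)
  expect_lte(length(kept), n)
  idx <- vapply(kept, function(cd) which(labels == cd$label &
    feats[, 1] == cd$features[["x1"]])[1], numeric(1))
  expect_true(all(diff(idx) > 0) || length(kept) < 2)
  # NULL pre-filter accepts everything; empty input stays empty
  expect_identical(prefilter_candidates(cands, NULL), cands)
  expect_length(prefilter_candidates(list(), pf), 0)
  expect_error(prefilter_candidates(cands, "not a filter"), "trained")
})
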