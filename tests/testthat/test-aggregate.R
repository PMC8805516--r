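mk_cand <- function(center, p) list(center_ijk = as.integer(center),
                                    probability = p)

test_that("the probability threshold is strict", {
  cands <- list(mk_cand(c(5, 5, 5), 0.5), mk_cand(c(6, 6, 6), 0.51),
                mk_cand(c(7, 7, 7), 0.49))
  kept <- positive_candidates(cands, tau = 0.5)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$probability, 0.51)
  # tau = 0 keeps everything with p > 0; empty input stays empty
  expect_length(positive_candidates(cands, tau = 0), 3)
  expect_length(positive_candidates(list(), tau = 0.5), 0)
})

test_that("the vote minimum implements the more-than-five rule", {
  d <- c(30, 30, 30)
  mask <- array(FALSE, d)
  mask[10:20, 10:20, 10:20] <- TRUE
  six <- lapply(1:6, function(i) mk_cand(c(14 + i %% 3, 15, 15), 0.6 + i / 100))
  expect_length(vote_regions(six, mask, patch_side_vox = 8, min_votes = 6), 1)
  expect_length(vote_regions(six[1:5], mask, patch_side_vox = 8,
                             min_votes = 6), 0)
  # two well-separated clusters of six -> two regions
  mask2 <- array(FALSE, c(60, 60, 60))
  mask2[8:16, 8:16, 8:16] <- TRUE
  mask2[44:52, 44:52, 44:52] <- TRUE
  both <- c(lapply(1:6, function(i) mk_cand(c(11 + i %% 2, 12, 12), 0.7)),
            lapply(1:6, function(i) mk_cand(c(47 + i %% 2, 48, 48), 0.8)))
  regions <- vote_regions(both, mask2, patch_side_vox = 8, min_votes = 6)
  expect_length(regions, 2)
  expect_setequal(vapply(regions, `[[`, numeric(1), "score"), c(0.7, 0.8))
})

test_that("voting agrees with the brute-force oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(16:32, 1)
    d <- rep(n, 3)
    mask <- array(runif(prod(d)) < 0.25, d)
    ncand <- sample(3:20, 1)
    cands <- lapply(seq_len(ncand), function(i)
      mk_cand(sample(2:(n - 1), 3, replace = TRUE), runif(1, 0.5, 1)))
    side <- sample(c(6L, 8L), 1)
    mv <- sample(2:6, 1)
    got <- vote_regions(cands, mask, patch_side_vox = side, min_votes = mv)
    want <- oracle_vote_regions(cands, mask, side, mv)
    expect_same_regions(got, want)
  }
})

test_that("separation merges close regions and keeps the best score", {
  reg <- function(p, s) list(voxels = 1L, rep_point = as.integer(p),
                             vote_count = 6L, score = s)
  # 20 voxels apart: distinct
  two <- separate_detections(list(reg(c(5, 5, 5), 0.9), reg(c(25, 5, 5), 0.8)),
                             min_separation_vox = 16)
  expect_length(two, 2)
  # 10 voxels apart: merged, max score wins
  one <- separate_detections(list(reg(c(5, 5, 5), 0.7), reg(c(15, 5, 5), 0.9)),
                             min_separation_vox = 16)
  expect_length(one, 1)
  expect_equal(one[[1]]$score, 0.9)
  expect_equal(one[[1]]$rep_point, c(15L, 5L, 5L))
  # exactly 16 voxels apart counts as different points
  expect_length(separate_detections(list(reg(c(5, 5, 5), 0.7),
                                         reg(c(21, 5, 5), 0.9)),
                                    min_separation_vox = 16), 2)
  # single region passes through
  expect_length(separate_detections(list(reg(c(5, 5, 5), 0.5))), 1)
})

test_that("separation agrees with the transitive-closure oracle", {
  set.seed(32)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    regions <- lapply(seq_len(n), function(i)
      list(voxels = i, rep_point = sample.int(40, 3, replace = TRUE),
           vote_count = sample(6:9, 1), score = runif(1)))
    got <- separate_detections(regions, min_separation_vox = 16)
    want <- oracle_separate(regions, 16)
    expect_same_regions(got, want)
  }
})

test_that("detection output nests as tau rises and is order-invariant", {
  set.seed(33)
  d <- c(36, 36, 36)
  mask <- array(runif(prod(d)) < 0.3, d)
  cands <- lapply(1:25, function(i)
    mk_cand(sample(4:33, 3, replace = TRUE), runif(1)))
  taus <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  # positive-candidate counts are strictly monotone in tau, and each
  # higher-tau detection footprint nests inside the lower-tau footprint
  # union (regions themselves may split when a bridging candidate drops out)
  ncand <- vapply(taus, function(tau)
    length(positive_candidates(cands, tau = tau)), integer(1))
  expect_true(all(diff(ncand) <= 0))
  dets <- lapply(taus, function(tau)
    detect_case(cands, mask, patch_side_vox = 8, tau = tau, min_votes = 3))
  for (t in seq_along(taus)[-1]) {
    hi <- unlist(lapply(dets[[t]], `[[`, "voxels"))
    lo <- unlist(lapply(dets[[t - 1]], `[[`, "voxels"))
    expect_true(all(hi %in% lo) || length(hi) == 0)
  }
  # shuffling candidate order changes nothing
  a <- detect_case(cands, mask, patch_side_vox = 8, tau = 0.3, min_votes = 3)
  b <- detect_case(cands[sample(25)], mask, patch_side_vox = 8, tau = 0.3,
                   min_votes = 3)
  expect_same_regions(a, b)
})

test_that("the separation threshold reproduces the printed millimetre figure", {
  expect_equal(16 * 0.3906, 6.2496)
  expect_equal(round(16 * 0.3906, 2), 6.25)
})
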