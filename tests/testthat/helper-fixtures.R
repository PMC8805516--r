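# Shared fixtures and independent brute-force oracles. Oracles are written
# as plainly as possible (array shifting, exhaustive loops) and never call
# the code paths they check.

# -- array fixtures -----------------------------------------------------

gaussian_blob_volume <- function(n = 41, center = NULL, sigma = 2,
                                 amplitude = 100, spacing = 0.3906) {
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  aneu_volume(array(amplitude * exp(-d2 / (2 * sigma^2)), c(n, n, n)), spacing)
}

rasterized_sphere <- function(n = 17, radius = 6) {
  cc <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  array((g$i - cc)^2 + (g$j - cc)^2 + (g$k - cc)^2 <= radius^2, c(n, n, n))
}

ball_voxels <- function(center, radius, dim) {
  lo <- pmax(1, floor(center - radius)); hi <- pmin(dim, ceiling(center + radius))
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
  g[d2 <= radius^2, , drop = FALSE]
}

# -- brute-force 26-connected labelling (min-label propagation) ---------

shift3 <- function(a, off) {
  d <- dim(a)
  out <- array(0L, d)
  src <- lapply(1:3, function(ax) {
    idx <- seq_len(d[ax]) - off[ax]
    idx[idx >= 1 & idx <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    idx <- seq_len(d[ax])
    idx[idx - off[ax] >= 1 & idx - off[ax] <= d[ax]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

oracle_label_components <- function(mask) {
  lab <- array(0L, dim(mask))
  lab[mask] <- which(mask)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  repeat {
    m <- lab
    for (t in seq_len(nrow(offsets))) {
      sh <- shift3(lab, offsets[t, ])
      cand <- mask & sh > 0 & sh < m
      m[cand] <- sh[cand]
    }
    if (identical(m, lab)) break
    lab <- m
  }
  u <- unique(lab[lab > 0])
  out <- array(0L, dim(mask))
  for (t in seq_along(u)) out[lab == u[t]] <- t
  out
}

# -- brute-force voting + separation oracles ----------------------------

oracle_cube <- function(center, side, dim) {
  lo <- center - side %/% 2L
  hi <- lo + side - 1L
  lapply(1:3, function(a) max(lo[a], 1L):min(hi[a], dim[a]))
}

oracle_vote_regions <- function(cands, artery_mask, side, min_votes) {
  d <- dim(artery_mask)
  fp <- array(FALSE, d)
  for (cand in cands) {
    cu <- oracle_cube(cand$center_ijk, side, d)
    fp[cu[[1]], cu[[2]], cu[[3]]] <- fp[cu[[1]], cu[[2]], cu[[3]]] |
      artery_mask[cu[[1]], cu[[2]], cu[[3]]]
  }
  if (!any(fp)) return(list())
  lab <- oracle_label_components(fp)
  out <- list()
  for (id in seq_len(max(lab))) {
    votes <- 0L; score <- -Inf
    for (cand in cands) {
      cu <- oracle_cube(cand$center_ijk, side, d)
      if (any(lab[cu[[1]], cu[[2]], cu[[3]]] == id)) {
        votes <- votes + 1L
        score <- max(score, cand$probability)
      }
    }
    if (votes >= min_votes) {
      vox <- which(lab == id)
      out[[length(out) + 1L]] <- list(
        voxels = vox,
        rep_point = as.integer(round(colMeans(arrayInd(vox, d)))),
        vote_count = votes, score = score)
    }
  }
  out
}

oracle_separate <- function(regions, min_sep) {
  n <- length(regions)
  if (n <= 1) return(regions)
  pts <- do.call(rbind, lapply(regions, `[[`, "rep_point"))
  adj <- as.matrix(stats::dist(pts)) < min_sep
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && grp[j] > grp[i]) { grp[j] <- grp[i]; changed <- TRUE }
      if (adj[i, j] && grp[i] > grp[j]) { grp[i] <- grp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  lapply(unique(grp), function(g) {
    members <- regions[grp == g]
    sc <- vapply(members, `[[`, numeric(1), "score")
    list(voxels = sort(unique(unlist(lapply(members, `[[`, "voxels")))),
         rep_point = members[[which.max(sc)]]$rep_point,
         vote_count = sum(vapply(members, `[[`, integer(1), "vote_count")),
         score = max(sc))
  })
}

# order-insensitive comparison of detection-region lists
expect_same_regions <- function(a, b) {
  key <- function(rs) {
    if (length(rs) == 0) return(character())
    sort(vapply(rs, function(r)
      paste(paste(r$rep_point, collapse = ","), r$vote_count,
            format(r$score, digits = 12),
            paste(range(r$voxels), collapse = "-"), length(r$voxels)),
      character(1)))
  }
  expect_identical(key(a), key(b))
}

# -- tiny phantom cohort, memoized across test files --------------------

.fixture_env <- new.env(parent = emptyenv())

tiny_phantom <- function(seed = 42) {
  key <- paste0("phantom", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- phantom_config(volume_shape = c(64, 64, 64), n_vessels = 3,
                          n_aneurysms = 2,
                          aneurysm_diameter_range_mm = c(3, 5.5), seed = seed)
    .fixture_env[[key]] <- list(
      config = cfg,
      phantom = implant_aneurysms(generate_vessel_volume(cfg), cfg))
  }
  .fixture_env[[key]]
}

# study-scale experiment configuration shared by the end-to-end tests
phantom_study_config <- function(seed, n_volumes = 50L) {
  experiment_config(
    phantom = phantom_config(volume_shape = c(72, 72, 72), n_vessels = 3,
                             vessel_radius_range_mm = c(0.4, 1.2),
                             n_aneurysms = 2,
                             aneurysm_diameter_range_mm = c(3, 5.5),
                             vessel_intensity = 100, background_mean = 20,
                             noise_sigma = 10),
    n_volumes = n_volumes,
    fractions = c(train = 0.64, val = 0.16, test = 0.20),
    scales_mm = c(0.8, 1.2, 1.8),
    min_response_q = 0.45, candidate_mode = "dense", stride_vox = 2L,
    patch_side = 16L,
    prefilter_retention = NA,
    net = net_config(patch_side = 16L, branch_depth = 2L, base_channels = 8L,
                     se_reduction = 4L, epochs = 5L, batch_size = 32L,
                     learning_rate = 1e-3, seed = 1L),
    archs = c("2d", "3d", "md"),
    neg_per_case = 12L, pos_per_case = 8L,
    seed = seed)
}
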