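#' Case-level train/validation/test split
#'
#' Shuffles cases with the given seed and assigns them to partitions using
#' largest-remainder rounding, so all candidates of one case stay together.
#' The three sets are disjoint and exhaustive.
#'
#' @param case_ids character vector of case identifiers.
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param seed split seed.
#' @return List with `train`, `val`, `test` character vectors.
#' @export
split_cases <- function(case_ids, fractions = c(train = 0.64, val = 0.16,
                                                test = 0.20), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0))
  n <- length(case_ids)
  if (n < sum(fractions > 0)) stop("fewer cases than partitions")
  raw <- n * fractions
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    give <- order(-rem)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  set.seed(seed)
  shuffled <- sample(case_ids)
  splits <- rep(c("train", "val", "test"), counts)
  list(train = sort(shuffled[splits == "train"]),
       val = sort(shuffled[splits == "val"]),
       test = sort(shuffled[splits == "test"]))
}

#' Dense candidate points on a stride grid
#'
#' Alternative to the local-maxima extractor for the vote-based aggregation
#' stage, which needs several candidate voxels per lesion: every in-mask
#' voxel whose blob response exceeds the floor, subsampled on a regular
#' stride grid. Sorted by descending response.
#'
#' @param response a `shape_response`.
#' @param artery_mask logical array of the same shape.
#' @param min_response response floor; default the 95th percentile of the
#'   in-mask blob response.
#' @param stride_vox grid stride in voxels.
#' @return data.frame as in [extract_candidate_points()].
#' @export
dense_candidate_points <- function(response, artery_mask, min_response = NULL,
                                   stride_vox = 2L) {
  stopifnot(inherits(response, "shape_response"),
            identical(dim(response$blob), dim(artery_mask)))
  empty <- data.frame(i = integer(), j = integer(), k = integer(),
                      response = numeric(), scale_mm = numeric())
  if (!any(artery_mask)) return(empty)
  if (is.null(min_response)) {
    min_response <- as.numeric(quantile(response$blob[artery_mask], 0.95,
                                        names = FALSE))
  }
  d <- dim(artery_mask)
  grid <- array(FALSE, d)
  gi <- seq(1L, d[1], by = stride_vox)
  gj <- seq(1L, d[2], by = stride_vox)
  gk <- seq(1L, d[3], by = stride_vox)
  grid[gi, gj, gk] <- TRUE
  sel <- which(artery_mask & grid & response$blob > min_response)
  if (length(sel) == 0) return(empty)
  coords <- arrayInd(sel, d)
  vals <- response$blob[sel]
  ord <- order(-vals)
  data.frame(i = coords[ord, 1], j = coords[ord, 2], k = coords[ord, 3],
             response = vals[ord], scale_mm = response$argmax_scale[sel][ord])
}

#' Experiment configuration
#'
#' Bundles every stage's parameters for [run_experiment()].
#'
#' @param phantom a [phantom_config()] (its per-case seed is managed by the
#'   cohort generator).
#' @param n_volumes cohort size.
#' @param fractions case-level train/val/test fractions.
#' @param scales_mm Hessian filter scales.
#' @param min_response_q in-mask blob-response quantile used as candidate
#'   floor.
#' @param candidate_mode `"dense"` (stride grid; default, feeds the vote
#'   rule) or `"maxima"` (NMS-thinned local maxima).
#' @param stride_vox,nms_radius_mm candidate extraction parameters.
#' @param patch_side candidate patch side in voxels.
#' @param prefilter_retention positive retention of the pre-filter operating
#'   point; `NA` disables the pre-filter.
#' @param prefilter_at_inference apply the pre-filter to test candidates too.
#' @param net a [net_config()] shared by the three architectures.
#' @param archs architectures to train.
#' @param neg_per_case cap on negative training candidates sampled per case.
#' @param pos_per_case cap on positive training candidates per case
#'   (`Inf` keeps all).
#' @param tau,min_votes,min_separation_vox aggregation parameters.
#' @param seed global experiment seed; every stage's randomness derives from
#'   it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              n_volumes = 20L,
                              fractions = c(train = 0.64, val = 0.16,
                                            test = 0.20),
                              scales_mm = c(0.6, 1.0, 1.6, 2.4, 3.6),
                              min_response_q = 0.95,
                              candidate_mode = c("dense", "maxima"),
                              stride_vox = 2L,
                              nms_radius_mm = 3.0,
                              patch_side = 32L,
                              prefilter_retention = 0.99,
                              prefilter_at_inference = TRUE,
                              net = net_config(),
                              archs = c("2d", "3d", "md"),
                              neg_per_case = 15L,
                              pos_per_case = Inf,
                              tau = 0.5,
                              min_votes = 6L,
                              min_separation_vox = 16,
                              seed = 1L) {
  candidate_mode <- match.arg(candidate_mode)
  stopifnot(inherits(phantom, "phantom_config"), n_volumes >= 3,
            inherits(net, "net_config"),
            all(archs %in% c("2d", "3d", "md")))
  if (net$patch_side != patch_side)
    stop("net$patch_side must equal patch_side")
  structure(as.list(environment()), class = "experiment_config")
}

process_case <- function(case, config) {
  voln <- resample_isotropic(case$volume, config$phantom$spacing_mm)
  voln <- nyul_apply(voln, case$scale)
  art <- extract_arteries(voln)
  resp <- shape_filter(voln, config$scales_mm)
  minr <- as.numeric(quantile(resp$blob[art$artery_mask], config$min_response_q,
                              names = FALSE))
  pts <- if (config$candidate_mode == "dense") {
    dense_candidate_points(resp, art$artery_mask, min_response = minr,
                           stride_vox = config$stride_vox)
  } else {
    extract_candidate_points(resp, art$artery_mask, min_response = minr,
                             nms_radius_mm = config$nms_radius_mm)
  }
  cands <- crop_and_label(voln, pts, case$annotations, config$patch_side)
  if (!is.na(config$prefilter_retention)) {
    for (i in seq_along(cands)) {
      cands[[i]]$features <- candidate_features(cands[[i]], resp,
                                                art$artery_mask)
    }
  }
  list(case_id = case$case_id, candidates = cands,
       artery_mask = art$artery_mask, annotations = case$annotations)
}

candidate_tensors <- function(cands) {
  S <- dim(cands[[1]]$patch)[1]
  patches <- array(0, c(S, S, S, length(cands)))
  panels <- array(0, c(15L * S, S, length(cands)))
  ors <- orientation_set()
  for (i in seq_along(cands)) {
    patches[, , , i] <- cands[[i]]$patch
    panels[, , i] <- build_panel(cands[[i]]$patch, ors)
  }
  list(patches = patches, panels = panels)
}

#' Run a full end-to-end experiment on a phantom cohort
#'
#' Generates the cohort, splits cases, trains the preprocessing scale and
#' the pre-filter on training cases only, extracts and classifies
#' candidates, trains each requested architecture on the same split, and
#' evaluates detections on the held-out test cases with FROC analysis.
#' Candidates from test cases never enter training (asserted at run time).
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param verbose print stage progress.
#' @return A list of class `aneu_experiment`: `split`, per-arch `models`,
#'   `froc`, `operating_points`, `stratified`, `detections`, plus a
#'   reproducibility `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating cohort of %d phantoms", config$n_volumes)
  cohort <- generate_cohort(config$n_volumes, config$phantom,
                            seed = config$seed)
  ids <- vapply(cohort$cases, `[[`, character(1), "case_id")
  split <- split_cases(ids, config$fractions, seed = config$seed + 1L)
  train_cases <- cohort$cases[ids %in% split$train]
  scale <- nyul_train(lapply(train_cases, `[[`, "volume"))
  say("preprocessing + candidate extraction")
  processed <- lapply(cohort$cases, function(cs) {
    cs$scale <- scale
    process_case(cs, config)
  })
  names(processed) <- ids
  # pre-filter trained on training cases only (positives vs negatives)
  prefilter <- NULL
  if (!is.na(config$prefilter_retention)) {
    tr_cands <- unlist(lapply(processed[split$train], `[[`, "candidates"),
                       recursive = FALSE)
    labs <- vapply(tr_cands, `[[`, character(1), "label")
    keep <- labs != "partial"
    if (any(labs[keep] == "positive") && any(labs[keep] == "negative")) {
      feats <- do.call(rbind, lapply(tr_cands[keep], `[[`, "features"))
      prefilter <- fit_prefilter(feats, labs[keep],
                                 retention = config$prefilter_retention)
    }
  }
  if (!is.null(prefilter)) {
    for (id in ids) {
      if (id %in% split$test && !config$prefilter_at_inference) next
      processed[[id]]$candidates <-
        prefilter_candidates(processed[[id]]$candidates, prefilter)
    }
  }
  # training arrays: train+val cases, partial labels excluded, negatives
  # capped per case
  say("building training tensors")
  set.seed(config$seed + 2L)
  sel_cands <- list(); sel_labels <- character(); sel_cases <- character()
  for (id in c(split$train, split$val)) {
    cands <- processed[[id]]$candidates
    labs <- vapply(cands, `[[`, character(1), "label")
    pos <- which(labs == "positive")
    neg <- which(labs == "negative")
    if (length(pos) > config$pos_per_case)
      pos <- sort(sample(pos, config$pos_per_case))
    if (length(neg) > config$neg_per_case)
      neg <- sort(sample(neg, config$neg_per_case))
    sel <- c(pos, neg)
    sel_cands <- c(sel_cands, cands[sel])
    sel_labels <- c(sel_labels, labs[sel])
    sel_cases <- c(sel_cases, rep(id, length(sel)))
  }
  stopifnot(!any(sel_cases %in% split$test))  # leakage guard
  if (!any(sel_labels == "positive") || !any(sel_labels == "negative"))
    stop("training set lacks a class; enlarge the cohort or loosen the floor")
  tens <- candidate_tensors(sel_cands)
  test_tens <- lapply(processed[split$test], function(pc) {
    if (length(pc$candidates) == 0) return(NULL)
    candidate_tensors(pc$candidates)
  })
  models <- list(); frocs <- list(); ops <- list(); strats <- list()
  detections <- list()
  for (arch in config$archs) {
    say("training %s", arch)
    cfg <- config$net
    cfg$seed <- config$seed + 10L + match(arch, c("2d", "3d", "md"))
    model <- new_net(arch, cfg)
    model <- train_net(model,
                       panels = if (arch %in% c("2d", "md")) tens$panels,
                       patches = if (arch %in% c("3d", "md")) tens$patches,
                       labels = sel_labels, case_ids = sel_cases,
                       val_cases = split$val)
    models[[arch]] <- model
    say("  best val loss %.4f (constant baseline %.4f)",
        min(model$history$val_loss), model$baseline_val_loss)
    case_results <- list()
    for (id in split$test) {
      pc <- processed[[id]]
      dets <- list()
      if (length(pc$candidates) > 0) {
        tt <- test_tens[[id]]
        probs <- predict(model,
                         panels = if (arch %in% c("2d", "md")) tt$panels,
                         patches = if (arch %in% c("3d", "md")) tt$patches)
        for (i in seq_along(pc$candidates))
          pc$candidates[[i]]$probability <- probs[i]
        dets <- detect_case(pc$candidates, pc$artery_mask, config$patch_side,
                            tau = config$tau, min_votes = config$min_votes,
                            min_separation_vox = config$min_separation_vox)
      }
      case_results[[id]] <- list(detections = dets,
                                 annotations = pc$annotations)
    }
    crv <- froc_curve(case_results)
    frocs[[arch]] <- crv
    ops[[arch]] <- operating_points(crv)
    strat_cases <- lapply(case_results, function(cr) {
      m <- match_detections(cr$detections, cr$annotations)
      list(annotations = cr$annotations, detected = m$detected)
    })
    strats[[arch]] <- stratified_report(strat_cases)
    detections[[arch]] <- case_results
  }
  manifest <- list(seed = config$seed, n_volumes = config$n_volumes,
                   split = split, archs = config$archs,
                   patch_side = config$patch_side,
                   scales_mm = config$scales_mm,
                   case_seeds = vapply(cohort$cases, `[[`, numeric(1), "seed"))
  result <- structure(list(split = split, models = models, froc = frocs,
                           operating_points = ops, stratified = strats,
                           detections = detections, manifest = manifest,
                           prefilter = prefilter, scale = scale),
                      class = "aneu_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.aneu_experiment <- function(x, ...) {
  cat("<aneu_experiment>\n")
  for (arch in names(x$froc)) {
    op <- x$operating_points[[arch]]
    cat(sprintf("  %s: max sensitivity %.3f @ %.2f FPs/case%s\n",
                arch, op$max_sensitivity, op$fps_at_max_sensitivity,
                if (op$sens_reachable)
                  sprintf("; %.2f FPs/case @ %.0f%% sens",
                          op$fps_at_sensitivity, 100 * op$sens_target)
                else ""))
  }
  invisible(x)
}

write_experiment <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  for (arch in names(result$froc)) {
    write.csv(result$froc[[arch]],
              file.path(out_dir, sprintf("froc_%s.csv", arch)),
              row.names = FALSE)
    write.csv(result$stratified[[arch]]$by_size,
              file.path(out_dir, sprintf("stratified_size_%s.csv", arch)),
              row.names = FALSE)
    dets <- result$detections[[arch]]
    det_json <- lapply(names(dets), function(id) {
      lapply(dets[[id]]$detections, function(dd) list(
        case_id = id, representative_point_ijk = dd$rep_point,
        score = dd$score, vote_count = dd$vote_count))
    })
    jsonlite::write_json(det_json,
                         file.path(out_dir, sprintf("detections_%s.json", arch)),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
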