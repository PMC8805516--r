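#' Select positive candidates by probability threshold
#'
#' Keeps candidates whose model probability strictly exceeds `tau` (a
#' probability of exactly `tau` is excluded).
#'
#' @param candidates list of candidates.
#' @param probs probabilities aligned with `candidates`; if `NULL`, each
#'   candidate's `probability` slot is used.
#' @param tau decision threshold (default 0.5).
#' @return The positive candidates, with `probability` slots filled.
#' @export
positive_candidates <- function(candidates, probs = NULL, tau = 0.5) {
  if (length(candidates) == 0) return(candidates)
  if (is.null(probs))
    probs <- vapply(candidates, `[[`, numeric(1), "probability")
  stopifnot(length(probs) == length(candidates),
            all(probs >= 0 & probs <= 1))
  for (i in seq_along(candidates)) candidates[[i]]$probability <- probs[i]
  candidates[probs > tau]
}

candidate_cube <- function(center, side, dim) {
  b <- patch_bounds(center, as.integer(side), dim)
  lapply(1:3, function(a) b$clo[a]:b$chi[a])
}

#' Aggregate positive candidates into voted detection regions
#'
#' Formalizes the "part of the artery" voting rule: the union of the
#' positive candidates' patch footprints is intersected with the artery mask
#' and split into 26-connected components. Each component's vote count is
#' the number of positive candidates whose footprint touches it; components
#' with at least `min_votes` votes (the "more than five candidate voxels"
#' rule, i.e. >= 6) are emitted. A region's score is the maximum member
#' probability; its representative point is the footprint centroid rounded
#' to the nearest voxel.
#'
#' @param candidates positive candidates (see [positive_candidates()]) with
#'   `center_ijk` and `probability`.
#' @param artery_mask logical artery mask.
#' @param patch_side_vox candidate patch side (footprint cube side).
#' @param min_votes minimum vote count for a region to be emitted.
#' @return List of detection regions: `voxels` (linear indices into the
#'   volume), `rep_point`, `vote_count`, `score`.
#' @export
vote_regions <- function(candidates, artery_mask, patch_side_vox,
                         min_votes = 6L) {
  if (length(candidates) == 0) return(list())
  d <- dim(artery_mask)
  fp <- array(FALSE, d)
  for (cand in candidates) {
    cube <- candidate_cube(cand$center_ijk, patch_side_vox, d)
    fp[cube[[1]], cube[[2]], cube[[3]]] <-
      fp[cube[[1]], cube[[2]], cube[[3]]] | artery_mask[cube[[1]], cube[[2]], cube[[3]]]
  }
  if (!any(fp)) return(list())
  lab <- cpp_label_components(fp)
  nlab <- max(lab)
  votes <- integer(nlab)
  score <- numeric(nlab)
  for (cand in candidates) {
    cube <- candidate_cube(cand$center_ijk, patch_side_vox, d)
    ids <- unique(as.integer(lab[cube[[1]], cube[[2]], cube[[3]]]))
    ids <- ids[ids > 0]
    votes[ids] <- votes[ids] + 1L
    score[ids] <- pmax(score[ids], cand$probability)
  }
  keep <- which(votes >= min_votes)
  lapply(keep, function(id) {
    vox <- which(lab == id)
    coords <- arrayInd(vox, d)
    list(voxels = vox,
         rep_point = as.integer(round(colMeans(coords))),
         vote_count = votes[id],
         score = score[id])
  })
}

#' Merge detections closer than the separation threshold
#'
#' Regions whose representative points are at least `min_separation_vox`
#' apart (Euclidean distance in voxels; 16 voxels is about 6.25 mm at
#' 0.3906 mm spacing) remain distinct detections; closer regions are merged
#' into one detection that keeps the union footprint and the highest score.
#' Merging is by connected components of the proximity graph, so the result
#' does not depend on input order.
#'
#' @param regions list of detection regions from [vote_regions()].
#' @param min_separation_vox separation threshold in voxels (default 16).
#' @return List of final detections.
#' @export
separate_detections <- function(regions, min_separation_vox = 16) {
  n <- length(regions)
  if (n <= 1) return(regions)
  pts <- do.call(rbind, lapply(regions, `[[`, "rep_point"))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < min_separation_vox) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    members <- regions[roots == r]
    scores <- vapply(members, `[[`, numeric(1), "score")
    best <- which.max(scores)
    list(voxels = sort(unique(unlist(lapply(members, `[[`, "voxels")))),
         rep_point = members[[best]]$rep_point,
         vote_count = sum(vapply(members, `[[`, integer(1), "vote_count")),
         score = max(scores))
  })
}

#' Full per-case detection from candidate probabilities
#'
#' Convenience wrapper chaining [positive_candidates()], [vote_regions()]
#' and [separate_detections()].
#'
#' @param candidates candidate list with probabilities.
#' @param artery_mask logical artery mask.
#' @param patch_side_vox footprint cube side.
#' @param tau probability threshold (strict).
#' @param min_votes vote minimum.
#' @param min_separation_vox separation threshold in voxels.
#' @return List of final detections.
#' @export
detect_case <- function(candidates, artery_mask, patch_side_vox,
                        tau = 0.5, min_votes = 6L, min_separation_vox = 16) {
  pos <- positive_candidates(candidates, tau = tau)
  regions <- vote_regions(pos, artery_mask, patch_side_vox,
                          min_votes = min_votes)
  separate_detections(regions, min_separation_vox = min_separation_vox)
}
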