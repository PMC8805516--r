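#' Phantom generator configuration
#'
#' Parameters of the synthetic TOF-MRA-like phantom: bright tubular vessels
#' with curvature and bifurcations over a noisy darker background, plus
#' spherical aneurysm bulges attached to vessel walls. Diameters above 15 mm
#' are outside the modelled population and are rejected.
#'
#' @param volume_shape integer length-3, voxels per axis.
#' @param spacing_mm isotropic voxel spacing in mm (default 0.3906, the
#'   resampled grid used throughout the pipeline).
#' @param n_vessels number of vessels; when >= 2 the second vessel always
#'   branches off the first so a bifurcation is present.
#' @param vessel_radius_range_mm min/max vessel radius in mm.
#' @param n_aneurysms number of implanted aneurysms.
#' @param aneurysm_diameter_range_mm min/max equivalent diameter in mm; must
#'   lie within (0, 15].
#' @param vessel_intensity,background_mean,noise_sigma signal units of the
#'   tube peak intensity, additive background level and Gaussian noise sd.
#' @param seed integer seed; `(config, seed)` fully determines every output.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(64L, 64L, 64L),
                           spacing_mm = 0.3906,
                           n_vessels = 3L,
                           vessel_radius_range_mm = c(0.4, 1.2),
                           n_aneurysms = 2L,
                           aneurysm_diameter_range_mm = c(3.0, 15.0),
                           vessel_intensity = 100,
                           background_mean = 20,
                           noise_sigma = 10,
                           seed = 1L) {
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 8),
            spacing_mm > 0, n_vessels >= 0, n_aneurysms >= 0,
            length(vessel_radius_range_mm) == 2,
            length(aneurysm_diameter_range_mm) == 2)
  if (vessel_radius_range_mm[1] > vessel_radius_range_mm[2] ||
      aneurysm_diameter_range_mm[1] > aneurysm_diameter_range_mm[2])
    stop("range minimum exceeds maximum")
  if (aneurysm_diameter_range_mm[1] <= 0 || aneurysm_diameter_range_mm[2] > 15)
    stop("aneurysm_diameter_range_mm must lie within (0, 15] mm")
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_mm = spacing_mm,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range_mm = vessel_radius_range_mm,
                 n_aneurysms = as.integer(n_aneurysms),
                 aneurysm_diameter_range_mm = aneurysm_diameter_range_mm,
                 vessel_intensity = vessel_intensity,
                 background_mean = background_mean,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth random C1 centerline through jittered control points; returns a
# dense sample (about 2 points per voxel) of 1-based continuous coordinates.
random_centerline <- function(shape, start = NULL) {
  n_ctrl <- 4L
  if (is.null(start)) {
    axis <- sample.int(3L, 1L)
    p0 <- runif(3, 0.15, 0.85) * shape
    p1 <- runif(3, 0.15, 0.85) * shape
    p0[axis] <- 2 + runif(1) * 2
    p1[axis] <- shape[axis] - 1 - runif(1) * 2
  } else {
    p0 <- start
    p1 <- runif(3, 0.1, 0.9) * shape
  }
  ctrl <- vapply(1:3, function(a) {
    base <- seq(p0[a], p1[a], length.out = n_ctrl)
    base + c(0, runif(n_ctrl - 2, -0.12, 0.12) * shape[a], 0)
  }, numeric(n_ctrl))
  tt <- seq(0, 1, length.out = n_ctrl)
  approx_len <- sum(sqrt(rowSums(diff(ctrl)^2)))
  ns <- max(8L, ceiling(approx_len * 2))
  ts <- seq(0, 1, length.out = ns)
  pts <- vapply(1:3, function(a)
    stats::spline(tt, ctrl[, a], xout = ts, method = "natural")$y,
    numeric(ns))
  pmin(pmax(pts, 1), matrix(shape, ns, 3, byrow = TRUE))
}

#' Generate a synthetic vessel volume
#'
#' Builds `n_vessels` smooth random tubes (spline centerlines, Gaussian
#' radial intensity profile) over Gaussian background noise. With two or more
#' vessels the second branches from a random point of the first, so at least
#' one bifurcation is present. Identical `config` (including its seed) gives
#' bit-identical output.
#'
#' @param config a [phantom_config].
#' @return A list with `volume` (noisy [aneu_volume]), `vessel_mask` (logical
#'   array of tube interiors), `signal` (noiseless signal component) and
#'   `centerlines` (per-vessel sampled centerline, radius, branch origin).
#' @export
generate_vessel_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$volume_shape
  sp <- config$spacing_mm
  r_max_vox <- config$vessel_radius_range_mm[2] / sp
  if (6 * r_max_vox > min(shape))
    stop("volume too small for requested vessel radii: min extent ",
         min(shape), " voxels vs max radius ", round(r_max_vox, 1), " voxels")
  set.seed(config$seed)
  signal <- array(0, shape)
  mask <- array(FALSE, shape)
  centerlines <- list()
  n <- config$n_vessels
  if (n > 0) {
    for (v in seq_len(n)) {
      if (v == 2L || (v > 2L && runif(1) < 0.5)) {
        parent <- centerlines[[if (v == 2L) 1L else sample.int(v - 1L, 1L)]]
        s0 <- sample(seq(3L, nrow(parent$pts) - 2L), 1L)
        pts <- random_centerline(shape, start = parent$pts[s0, ])
        branch_origin <- parent$pts[s0, ]
      } else {
        pts <- random_centerline(shape)
        branch_origin <- NULL
      }
      r_mm <- runif(1, config$vessel_radius_range_mm[1],
                    config$vessel_radius_range_mm[2])
      r_vox <- r_mm / sp
      # per-vessel signal factor: TOF signal varies with flow between vessels
      ifac <- runif(1, 0.75, 1.05)
      rr <- ceiling(2.5 * r_vox)
      # near-plug flow profile: flat core, soft rim
      sig_t <- 2 * r_vox^2
      for (s in seq_len(nrow(pts))) {
        p <- pts[s, ]
        lo <- pmax(1, floor(p - rr))
        hi <- pmin(shape, ceiling(p + rr))
        if (any(lo > hi)) next
        ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
        d2 <- outer(outer((ix - p[1])^2, (iy - p[2])^2, "+"), (iz - p[3])^2, "+")
        signal[ix, iy, iz] <- pmax(signal[ix, iy, iz],
                                   ifac * config$vessel_intensity *
                                     exp(-d2 / sig_t))
        mask[ix, iy, iz] <- mask[ix, iy, iz] | (d2 <= r_vox^2)
      }
      centerlines[[v]] <- list(pts = pts, r_vox = r_vox, r_mm = r_mm,
                               intensity_factor = ifac,
                               branch_origin = branch_origin)
    }
  }
  noisy <- signal + config$background_mean +
    array(rnorm(prod(shape), 0, config$noise_sigma), shape)
  list(volume = aneu_volume(noisy, sp, meta = list(kind = "phantom",
                                                   seed = config$seed)),
       vessel_mask = mask,
       signal = signal,
       centerlines = centerlines)
}

random_perpendicular <- function(tangent) {
  tangent <- tangent / sqrt(sum(tangent^2))
  repeat {
    v <- rnorm(3)
    v <- v - sum(v * tangent) * tangent
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) return(v / nv)
  }
}

ball_coords <- function(center, radius_vox, shape) {
  lo <- pmax(1, floor(center - radius_vox))
  hi <- pmin(shape, ceiling(center + radius_vox))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
  d2 <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 + (g[, 3] - center[3])^2
  g[d2 <= radius_vox^2, , drop = FALSE]
}

#' Implant aneurysms on vessel walls
#'
#' Attaches bright spherical bulges at randomly chosen vessel-wall points,
#' centered one vessel radius outward from the wall so each protrudes
#' hemispherically. Equivalent diameters are drawn uniformly from the
#' configured range; per-aneurysm ground-truth masks are returned.
#'
#' @param phantom output of [generate_vessel_volume()] (or a list with
#'   `volume`, `vessel_mask`, `signal`, optionally `centerlines`).
#' @param config the [phantom_config] used to generate it.
#' @return A list with updated `volume`, `signal`, `vessel_mask`, and
#'   `annotations` (an `annotation_set`).
#' @export
implant_aneurysms <- function(phantom, config) {
  stopifnot(inherits(config, "phantom_config"))
  n_an <- config$n_aneurysms
  shape <- config$volume_shape
  sp <- config$spacing_mm
  annots <- list()
  if (n_an == 0L) {
    return(c(phantom, list(annotations = annotation_set(annots, shape, sp))))
  }
  if (!any(phantom$vessel_mask))
    stop("cannot implant aneurysms: vessel mask is empty")
  set.seed(config$seed + 1L)
  signal <- phantom$signal
  noisy <- phantom$volume$data
  cls <- phantom$centerlines
  taken <- matrix(numeric(0), 0, 3)
  for (a in seq_len(n_an)) {
    d_mm <- runif(1, config$aneurysm_diameter_range_mm[1],
                  config$aneurysm_diameter_range_mm[2])
    ra_vox <- d_mm / 2 / sp
    placed <- FALSE
    for (try in 1:300) {
      v <- sample.int(length(cls), 1L)
      cl <- cls[[v]]
      ns <- nrow(cl$pts)
      s <- sample(seq(2L, ns - 1L), 1L)
      tangent <- cl$pts[s + 1L, ] - cl$pts[s - 1L, ]
      dir <- random_perpendicular(tangent)
      offset <- if (ra_vox >= cl$r_vox) 2 * cl$r_vox else cl$r_vox + 0.5 * ra_vox
      center <- cl$pts[s, ] + dir * offset
      if (any(center - ra_vox < 1.5) || any(center + ra_vox > shape - 0.5)) next
      coords <- ball_coords(center, ra_vox, shape)
      if (nrow(coords) == 0) next
      if (nrow(taken) > 0) {
        key_new <- coords[, 1] + shape[1] * (coords[, 2] - 1) +
          prod(shape[1:2]) * (coords[, 3] - 1)
        key_old <- taken[, 1] + shape[1] * (taken[, 2] - 1) +
          prod(shape[1:2]) * (taken[, 3] - 1)
        if (any(key_new %in% key_old)) next
      }
      loc <- "trunk"
      if (!is.null(cl$branch_origin) &&
          sqrt(sum((cl$pts[s, ] - cl$branch_origin)^2)) * sp < 3) loc <- "bifurcation"
      origin_near <- vapply(cls, function(other) {
        !is.null(other$branch_origin) &&
          sqrt(sum((cl$pts[s, ] - other$branch_origin)^2)) * sp < 3
      }, logical(1))
      if (any(origin_near)) loc <- "bifurcation"
      if (loc == "trunk" && s / ns > 0.75) loc <- "distal"
      idx <- coords[, 1] + shape[1] * (coords[, 2] - 1) +
        prod(shape[1:2]) * (coords[, 3] - 1)
      ifac <- if (is.null(cl$intensity_factor)) 1 else cl$intensity_factor
      old <- signal[idx]
      signal[idx] <- pmax(old, ifac * config$vessel_intensity)
      noisy[idx] <- noisy[idx] + (signal[idx] - old)
      annots[[a]] <- list(id = a,
                          coords = coords,
                          centroid_ijk = colMeans(coords),
                          sampled_diameter_mm = d_mm,
                          equivalent_diameter_mm =
                            (6 * nrow(coords) / pi)^(1 / 3) * sp,
                          location = loc)
      taken <- rbind(taken, coords)
      placed <- TRUE
      break
    }
    if (!placed) stop("failed to place aneurysm ", a,
                      " (volume too crowded or too small)")
  }
  vol <- aneu_volume(noisy, sp, meta = phantom$volume$meta)
  list(volume = vol, vessel_mask = phantom$vessel_mask, signal = signal,
       centerlines = cls,
       annotations = annotation_set(annots, shape, sp))
}

#' Per-aneurysm ground truth container
#'
#' @param regions list of per-aneurysm records (`id`, voxel `coords` matrix,
#'   `centroid_ijk`, `equivalent_diameter_mm`, `location`).
#' @param dim volume dimensions the coordinates refer to.
#' @param spacing_mm voxel spacing.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(regions, dim, spacing_mm) {
  structure(list(regions = regions, dim = as.integer(dim),
                 spacing_mm = spacing_mm),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d aneurysm(s)\n", length(x$regions)))
  for (r in x$regions)
    cat(sprintf("  #%d: %d voxels, %.2f mm, %s\n", r$id, nrow(r$coords),
                r$equivalent_diameter_mm, r$location))
  invisible(x)
}

#' Labelled mask array of an annotation set
#'
#' @param annotations an `annotation_set`.
#' @return Integer array; voxel value is the aneurysm id (0 = background).
#' @export
annotation_label_array <- function(annotations) {
  arr <- array(0L, annotations$dim)
  for (r in annotations$regions) arr[r$coords] <- r$id
  arr
}

#' Annotation table
#'
#' @param annotations an `annotation_set`.
#' @return data.frame with one row per aneurysm.
#' @export
annotation_table <- function(annotations) {
  if (length(annotations$regions) == 0)
    return(data.frame(id = integer(), ci = numeric(), cj = numeric(),
                      ck = numeric(), diameter_mm = numeric(),
                      location = character()))
  do.call(rbind, lapply(annotations$regions, function(r)
    data.frame(id = r$id, ci = r$centroid_ijk[1], cj = r$centroid_ijk[2],
               ck = r$centroid_ijk[3],
               diameter_mm = r$equivalent_diameter_mm,
               location = r$location)))
}

#' Generate a seeded phantom cohort
#'
#' Draws one sub-seed per case from the master seed, generates each phantom
#' with its aneurysms, and (optionally) writes NIfTI volumes, label masks and
#' a JSON manifest. Fully reproducible from `(config, seed)`.
#'
#' @param n_volumes number of cases (>= 1).
#' @param config a [phantom_config]; its `seed` field is replaced per case.
#' @param seed master seed.
#' @param out_dir optional output directory for NIfTI + manifest files.
#' @return A list of class `aneu_cohort`: `cases` (each with `case_id`,
#'   `volume`, `vessel_mask`, `annotations`, `seed`) and `manifest`.
#' @export
generate_cohort <- function(n_volumes, config, seed, out_dir = NULL) {
  stopifnot(n_volumes >= 1, inherits(config, "phantom_config"))
  set.seed(seed)
  case_seeds <- sample.int(2^20, n_volumes)
  cases <- vector("list", n_volumes)
  an_rows <- list()
  for (i in seq_len(n_volumes)) {
    cfg <- config
    cfg$seed <- case_seeds[i]
    ph <- implant_aneurysms(generate_vessel_volume(cfg), cfg)
    case_id <- sprintf("case%03d", i)
    cases[[i]] <- list(case_id = case_id, seed = case_seeds[i],
                       volume = ph$volume, vessel_mask = ph$vessel_mask,
                       signal = ph$signal, centerlines = ph$centerlines,
                       annotations = ph$annotations)
    tab <- annotation_table(ph$annotations)
    if (nrow(tab) > 0) an_rows[[i]] <- cbind(case_id = case_id, tab)
  }
  an_table <- if (length(an_rows)) do.call(rbind, an_rows) else
    data.frame(case_id = character(), id = integer())
  manifest <- list(
    n_volumes = n_volumes,
    master_seed = seed,
    spacing_mm = config$spacing_mm,
    cases = lapply(cases, function(cs) list(
      case_id = cs$case_id, seed = cs$seed,
      aneurysms = lapply(cs$annotations$regions, function(r) list(
        id = r$id, centroid_ijk = unname(round(r$centroid_ijk, 3)),
        diameter_mm = round(r$equivalent_diameter_mm, 4),
        location = r$location)))))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
    for (cs in cases) {
      write_volume(cs$volume, file.path(out_dir, paste0(cs$case_id, ".nii.gz")))
      write_volume(annotation_label_array(cs$annotations),
                   file.path(out_dir, paste0(cs$case_id, "_labels.nii.gz")),
                   spacing_mm = config$spacing_mm)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cases = cases, manifest = manifest, annotation_table = an_table),
            class = "aneu_cohort")
}
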