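#' Roaming-sphere (searchlight) decoding of a beta volume
#'
#' For every in-mask voxel, extracts the multivoxel pattern of the in-mask
#' sphere neighborhood around it, runs the same leave-one-run-out engine as
#' ROI decoding, and assigns the fold-averaged accuracy to the centroid
#' voxel. Spheres that contain fewer than two voxels are still decoded but
#' recorded in `small_spheres`.
#'
#' @param volume An `mvpa_volume` from [simulate_brain_volume()] or
#'   [read_volume()].
#' @param scheme A [make_scheme()] scheme (name or object); must be a
#'   cross-validation scheme.
#' @param settings A [classifier_settings()].
#' @param radius_mm Sphere radius in millimeters (default 10).
#' @return An object of class `mvpa_accuracy_map`: list with `values`
#'   (3-D array, `NA` outside the mask), `mask`, `radius_mm`, `scheme`,
#'   `chance` and `small_spheres` (matrix of flagged centers, possibly
#'   empty).
#' @export
run_searchlight <- function(volume, scheme, settings = classifier_settings(),
                            radius_mm = 10) {
  stopifnot(inherits(volume, "mvpa_volume"))
  if (is.character(scheme)) scheme <- make_scheme(scheme)
  if (scheme$mode != "cross_validation") {
    stop("searchlight supports cross-validation schemes", call. = FALSE)
  }
  dim3 <- dim(volume$mask)
  if (!any(volume$mask)) stop("mask is empty", call. = FALSE)
  n_slices <- dim(volume$betas)[4]
  betas <- matrix(volume$betas, prod(dim3), n_slices)
  design <- volume$conditions
  cls <- scheme_classes(scheme, design)
  keep <- !is.na(cls)
  y <- factor(cls[keep], levels = scheme$classes)
  run <- design$run[keep]
  offsets <- sphere_offsets(radius_mm, volume$voxel_size_mm)
  centers <- which(volume$mask, arr.ind = TRUE)
  values <- array(NA_real_, dim3)
  small <- NULL
  for (i in seq_len(nrow(centers))) {
    vox <- sphere_voxels(centers[i, ], offsets, dim3, volume$mask)
    if (length(vox) < 2) small <- rbind(small, centers[i, ])
    x <- t(betas[vox, keep, drop = FALSE])
    eng <- loro_engine(x, y, run, scheme, settings)
    values[centers[i, 1], centers[i, 2], centers[i, 3]] <- eng$accuracy
  }
  structure(
    list(
      values = values, mask = volume$mask, radius_mm = radius_mm,
      scheme = scheme$name, chance = scheme$chance,
      small_spheres = small
    ),
    class = "mvpa_accuracy_map"
  )
}

#' Group-level permutation test of searchlight maps
#'
#' Voxel-wise one-sample t test of per-subject accuracies against the
#' chance level, with familywise error controlled by a sign-flipping
#' max-statistic permutation: for each permutation the per-subject
#' deviations from chance are randomly sign-flipped, the voxel-wise t map
#' recomputed, and its maximum recorded; the familywise-corrected p of a
#' voxel is the proportion of permutation maxima at or above its observed
#' t (with the +1 correction), so any-voxel false positives are controlled
#' at `alpha` under exchangeability. Voxels with zero between-subject
#' variance have no defined t: they are flagged and excluded from the
#' maximum statistic.
#'
#' @param maps List of `mvpa_accuracy_map` objects (>= 2 subjects) sharing
#'   grid, mask and chance level.
#' @param chance Chance level; default taken from the first map.
#' @param n_permutations Number of random sign flips (default 1000).
#' @param seed Integer seed for the sign flips.
#' @param alpha Familywise error level.
#' @return An object of class `mvpa_group_map`: `t_values` (3-D array),
#'   `p_fwe` (3-D array of corrected p values), `threshold` (critical t at
#'   `alpha`), `significant` (logical array), `n_permutations`, `chance`,
#'   and `undefined` (logical array of zero-variance voxels).
#' @export
group_searchlight_test <- function(maps, chance = NULL,
                                   n_permutations = 1000L, seed = 1L,
                                   alpha = 0.05) {
  stopifnot(length(maps) >= 2)
  mask <- maps[[1]]$mask
  dim3 <- dim(mask)
  same <- vapply(maps, function(m) identical(dim(m$mask), dim3), logical(1))
  if (!all(same)) stop("maps must share the same grid", call. = FALSE)
  if (is.null(chance)) chance <- maps[[1]]$chance
  n <- length(maps)
  idx <- which(mask)
  d <- vapply(maps, function(m) m$values[idx] - chance, numeric(length(idx)))
  ssq <- rowSums(d^2)
  undefined_v <- apply(d, 1, function(z) stats::sd(z) == 0)
  t_from_mean <- function(m) {
    v <- (ssq - n * m^2) / (n - 1)
    m / sqrt(v / n)
  }
  t_obs <- t_from_mean(rowMeans(d))
  t_obs[undefined_v] <- NA_real_
  set.seed(seed)
  signs <- matrix(
    sample(c(-1, 1), n * n_permutations, replace = TRUE),
    n, n_permutations
  )
  m_perm <- (d %*% signs) / n
  v_perm <- (ssq - n * m_perm^2) / (n - 1)
  t_perm <- m_perm / sqrt(v_perm / n)
  t_perm[undefined_v, ] <- NA_real_
  max_t <- apply(t_perm, 2, function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0) -Inf else max(z)
  })
  p_fwe_v <- vapply(t_obs, function(t) {
    if (is.na(t)) return(NA_real_)
    (1 + sum(max_t >= t)) / (n_permutations + 1)
  }, numeric(1))
  k <- floor(alpha * (n_permutations + 1))
  threshold <- if (k >= 1) {
    sort(max_t, decreasing = TRUE)[k]
  } else {
    Inf
  }
  to_array <- function(v) {
    a <- array(NA_real_, dim3)
    a[idx] <- v
    a
  }
  sig <- array(FALSE, dim3)
  sig[idx] <- !is.na(p_fwe_v) & p_fwe_v <= alpha
  undef <- array(FALSE, dim3)
  undef[idx] <- undefined_v
  structure(
    list(
      t_values = to_array(t_obs), p_fwe = to_array(p_fwe_v),
      threshold = threshold, significant = sig,
      n_permutations = as.integer(n_permutations), chance = chance,
      alpha = alpha, undefined = undef
    ),
    class = "mvpa_group_map"
  )
}

# 26-connected neighbor offsets
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Local maxima of a 3-D map within a mask: strictly greater than all
# 26-connected in-mask neighbors; plateau ties resolved toward the
# smallest linear index.
local_maxima <- function(map, mask) {
  dim3 <- dim(map)
  offs <- neighbor_offsets_26()
  centers <- which(mask, arr.ind = TRUE)
  lin <- which(mask)
  is_max <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    pts <- sweep(offs, 2, centers[i, ], "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= dim3[1] &
      pts[, 2] >= 1 & pts[, 2] <= dim3[2] &
      pts[, 3] >= 1 & pts[, 3] <= dim3[3]
    pts <- pts[ok, , drop = FALSE]
    nlin <- pts[, 1] + dim3[1] * (pts[, 2] - 1L) +
      dim3[1] * dim3[2] * (pts[, 3] - 1L)
    nlin <- nlin[mask[nlin]]
    if (length(nlin) == 0) {
      is_max[i] <- TRUE
      next
    }
    v <- map[lin[i]]
    nv <- map[nlin]
    if (all(nv < v)) {
      is_max[i] <- TRUE
    } else if (all(nv <= v)) {
      # plateau: keep only the smallest linear index among the tied voxels
      is_max[i] <- all(nlin[nv == v] > lin[i])
    }
  }
  centers[is_max, , drop = FALSE]
}

#' Define a spherical ROI from a t map via a threshold ladder
#'
#' Thresholds the t map at the first ladder level (default p < 0.001, then
#' 0.005, then 0.01) that yields at least one suprathreshold voxel, finds
#' the suprathreshold local maximum nearest (Euclidean, in millimeters) to
#' the landmark coordinate, and returns the sphere of the given radius
#' centered there, restricted to the mask.
#'
#' @param t_map 3-D array of t values.
#' @param landmark Length-3 voxel index triple (1-based).
#' @param df Degrees of freedom used to convert the ladder's p levels into
#'   critical t values (one-sided).
#' @param radius_mm ROI sphere radius (default 10 mm).
#' @param threshold_ladder Increasing vector of voxel-wise p levels.
#' @param mask Optional 3-D logical array (default: all in-mask).
#' @param voxel_size_mm Voxel size for millimeter distances.
#' @return An object of class `roi_mask`: `found` flag, `center`,
#'   `radius_mm`, `voxels` (logical array), `threshold_used` (the p level)
#'   and `t_critical`. When no ladder level yields a suprathreshold voxel,
#'   `found` is `FALSE` and `voxels` is `NULL` (never a silent empty mask).
#' @export
define_roi_from_tmap <- function(t_map, landmark, df, radius_mm = 10,
                                 threshold_ladder = c(0.001, 0.005, 0.01),
                                 mask = NULL, voxel_size_mm = 3) {
  stopifnot(length(dim(t_map)) == 3, length(landmark) == 3)
  if (is.unsorted(threshold_ladder, strictly = TRUE)) {
    stop("threshold_ladder must be strictly increasing", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(t_map))
  vs <- rep_len(voxel_size_mm, 3L)
  landmark <- as.integer(landmark)
  for (p_level in threshold_ladder) {
    t_crit <- stats::qt(1 - p_level, df)
    supra <- mask & !is.na(t_map) & t_map > t_crit
    if (!any(supra)) next
    peaks <- local_maxima(t_map, supra)
    if (nrow(peaks) == 0) next
    d_mm <- sqrt(colSums((t(peaks) - landmark)^2 * vs^2))
    lin <- peaks[, 1] + dim(t_map)[1] * (peaks[, 2] - 1L) +
      dim(t_map)[1] * dim(t_map)[2] * (peaks[, 3] - 1L)
    best <- order(d_mm, lin)[1]
    center <- peaks[best, ]
    offs <- sphere_offsets(radius_mm, voxel_size_mm)
    vox_lin <- sphere_voxels(center, offs, dim(t_map), mask)
    voxels <- array(FALSE, dim(t_map))
    voxels[vox_lin] <- TRUE
    return(structure(
      list(
        found = TRUE, center = unname(center), radius_mm = radius_mm,
        voxels = voxels, threshold_used = p_level, t_critical = t_crit
      ),
      class = "roi_mask"
    ))
  }
  structure(
    list(
      found = FALSE, center = NULL, radius_mm = radius_mm, voxels = NULL,
      threshold_used = NA_real_, t_critical = NA_real_
    ),
    class = "roi_mask"
  )
}

#' Write a 3-D map as NIfTI
#'
#' @param map An `mvpa_accuracy_map`, `mvpa_group_map` (its t values) or a
#'   plain 3-D array.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size recorded in the header.
#' @return The path, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = 3) {
  arr <- if (inherits(map, "mvpa_accuracy_map")) {
    map$values
  } else if (inherits(map, "mvpa_group_map")) {
    map$t_values
  } else {
    map
  }
  RNifti::writeNifti(
    RNifti::asNifti(arr, pixdim = rep_len(voxel_size_mm, 3L)), path
  )
  invisible(path)
}
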