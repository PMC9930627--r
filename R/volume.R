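#' Integer voxel offsets of a sphere
#'
#' Membership is by center-to-center distance in millimeters:
#' `||offset * voxel_size_mm|| <= radius_mm`. With a 10 mm radius on a 3 mm
#' isotropic grid this admits all offsets up to 3.33 voxel units. The offset
#' set is symmetric under reflection of any axis.
#'
#' @param radius_mm Sphere radius in millimeters (> 0).
#' @param voxel_size_mm Voxel edge length(s) in millimeters; scalar or
#'   length-3.
#' @return An integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm = 3) {
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  vs <- rep_len(voxel_size_mm, 3L)
  r_vox <- floor(radius_mm / vs)
  grid <- as.matrix(expand.grid(
    dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2], dz = -r_vox[3]:r_vox[3]
  ))
  mm2 <- (grid[, 1] * vs[1])^2 + (grid[, 2] * vs[2])^2 + (grid[, 3] * vs[3])^2
  grid[mm2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# In-mask linear indices of the sphere centered at `center` (1-based voxel
# index triple).
sphere_voxels <- function(center, offsets, dim3, mask) {
  pts <- sweep(offsets, 2, as.integer(center), "+")
  ok <- pts[, 1] >= 1 & pts[, 1] <= dim3[1] &
    pts[, 2] >= 1 & pts[, 2] <= dim3[2] &
    pts[, 3] >= 1 & pts[, 3] <= dim3[3]
  pts <- pts[ok, , drop = FALSE]
  lin <- pts[, 1] + dim3[1] * (pts[, 2] - 1L) + dim3[1] * dim3[2] * (pts[, 3] - 1L)
  lin[mask[lin]]
}

#' Simulate a 4-D beta volume with planted informative spheres
#'
#' Generates one subject's condition-by-run beta volume on a regular grid.
#' Voxels inside the planted spheres (and inside the mask) carry condition
#' signal under the given latent geometry, embedded through a random
#' loading matrix exactly as in [simulate_roi_patterns()]; all other
#' in-mask voxels contain only noise; out-of-mask voxels are zero.
#'
#' @param dim Length-3 integer grid dimensions.
#' @param voxel_size_mm Physical voxel edge length (scalar or length-3).
#' @param mask 3-D logical array (default: all `TRUE`).
#' @param spheres A data frame with columns `x`, `y`, `z` (1-based voxel
#'   indices of the center) and `radius_mm`; `NULL` for a null volume.
#' @param geometry A [geometry_params()] or latent mean matrix.
#' @param info_scale Signal multiplier inside the planted spheres.
#' @param n_runs Number of runs.
#' @param noise_sd_run,noise_sd_voxel Noise SDs as in [roi_spec()].
#' @param seed Integer seed.
#' @return A list of class `mvpa_volume` with elements `betas` (4-D array,
#'   4th dimension ordered run-major with condition fastest), `mask`,
#'   `voxel_size_mm`, `truth_centers` (matrix of planted centers, 1-based),
#'   `conditions` (tibble mapping 4th-dimension slices to person, valence,
#'   run) and `n_runs`.
#' @export
simulate_brain_volume <- function(dim = c(12L, 12L, 12L), voxel_size_mm = 3,
                                  mask = NULL, spheres = NULL,
                                  geometry = geometry_params(),
                                  info_scale = 1, n_runs = 8L,
                                  noise_sd_run = 0.5, noise_sd_voxel = 1,
                                  seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (inherits(geometry, "geometry_params")) geometry <- build_geometry(geometry)
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(identical(dim(mask), dim))
  set.seed(seed)
  n_vox <- prod(dim)
  n_slices <- 8L * n_runs
  conds <- condition_table()
  slice_map <- tidyr::expand_grid(run = seq_len(n_runs), idx = 1:8)
  slice_map <- tibble::tibble(
    slice = seq_len(n_slices),
    person = conds$person[slice_map$idx],
    valence = conds$valence[slice_map$idx],
    run = slice_map$run
  )
  betas <- matrix(0, n_vox, n_slices)
  in_mask <- which(as.vector(mask))
  # noise: run offsets shared across the 8 conditions of a run
  for (r in seq_len(n_runs)) {
    off <- stats::rnorm(length(in_mask), sd = noise_sd_run)
    cols <- (r - 1L) * 8L + 1:8
    betas[in_mask, cols] <- off +
      matrix(stats::rnorm(length(in_mask) * 8L, sd = noise_sd_voxel),
        length(in_mask), 8L
      )
  }
  truth <- NULL
  if (!is.null(spheres) && nrow(spheres) > 0) {
    for (i in seq_len(nrow(spheres))) {
      center <- as.integer(c(spheres$x[i], spheres$y[i], spheres$z[i]))
      if (any(center < 1L) || any(center > dim)) {
        stop("planted sphere center outside the grid", call. = FALSE)
      }
      offs <- sphere_offsets(spheres$radius_mm[i], voxel_size_mm)
      vox <- sphere_voxels(center, offs, dim, mask)
      if (length(vox) == 0) {
        stop("planted sphere contains no in-mask voxels", call. = FALSE)
      }
      loading <- embedding_matrix(length(vox), ncol(geometry))
      signal <- info_scale * (geometry %*% t(loading)) # 8 x k
      for (r in seq_len(n_runs)) {
        cols <- (r - 1L) * 8L + 1:8
        betas[vox, cols] <- betas[vox, cols] + t(signal)
      }
      truth <- rbind(truth, center)
    }
    dimnames(truth) <- NULL
  }
  structure(
    list(
      betas = array(betas, c(dim, n_slices)), mask = mask,
      voxel_size_mm = voxel_size_mm, truth_centers = truth,
      conditions = slice_map, n_runs = as.integer(n_runs)
    ),
    class = "mvpa_volume"
  )
}

#' Write / read a simulated volume as NIfTI
#'
#' The 4-D betas and the 3-D mask are written as NIfTI files; the slice
#' ordering and truth centers go into a JSON sidecar manifest.
#'
#' @param volume An `mvpa_volume`.
#' @param dir Output directory (created if needed).
#' @return `write_volume()` returns the directory invisibly; `read_volume()`
#'   returns an `mvpa_volume`.
#' @export
write_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "mvpa_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- rep_len(volume$voxel_size_mm, 3L)
  RNifti::writeNifti(
    RNifti::asNifti(volume$betas, pixdim = vs),
    file.path(dir, "betas.nii.gz")
  )
  RNifti::writeNifti(
    RNifti::asNifti(array(as.numeric(volume$mask), dim(volume$mask)),
      pixdim = vs
    ),
    file.path(dir, "mask.nii.gz")
  )
  manifest <- list(
    voxel_size_mm = vs, n_runs = volume$n_runs,
    conditions = volume$conditions,
    truth_centers = volume$truth_centers
  )
  jsonlite::write_json(manifest, file.path(dir, "volume.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_volume
#' @export
read_volume <- function(dir) {
  betas <- as.array(RNifti::readNifti(file.path(dir, "betas.nii.gz")))
  mask_num <- as.array(RNifti::readNifti(file.path(dir, "mask.nii.gz")))
  manifest <- jsonlite::read_json(file.path(dir, "volume.json"),
    simplifyVector = TRUE
  )
  conds <- tibble::as_tibble(manifest$conditions)
  conds$person <- factor(conds$person, levels = persons())
  conds$valence <- factor(conds$valence, levels = valences())
  truth <- manifest$truth_centers
  if (!is.null(truth)) truth <- matrix(as.integer(truth), ncol = 3)
  structure(
    list(
      betas = betas, mask = array(mask_num > 0.5, dim(mask_num)),
      voxel_size_mm = manifest$voxel_size_mm,
      truth_centers = truth, conditions = conds,
      n_runs = as.integer(manifest$n_runs)
    ),
    class = "mvpa_volume"
  )
}
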