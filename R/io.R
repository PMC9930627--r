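#' Write / read a cohort as per-cell CSV files plus a JSON manifest
#'
#' Each subject-by-ROI cell is written as one CSV (columns `person`,
#' `valence`, `run`, `voxel_*`); the cohort spec (geometry, ROI
#' definitions, seed) and the file list go into `manifest.json`, making
#' the directory self-describing and exactly re-loadable.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   cohort tibble with the spec re-attached when present in the manifest.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- dplyr::group_split(
    dplyr::group_by(cohort, .data$subject, .data$roi, .data$network)
  )
  files <- purrr::map(cells, function(cell) {
    fn <- sprintf("%s_%s.csv", cell$subject[1], cell$roi[1])
    out <- cell[order(cell$run, cell$person, cell$valence), ]
    readr::write_csv(
      out[, c("person", "valence", "run", grep("^voxel_", names(out), value = TRUE))],
      file.path(dir, fn)
    )
    tibble::tibble(
      subject = cell$subject[1], roi = cell$roi[1],
      network = as.character(cell$network[1]), file = fn
    )
  })
  files <- dplyr::bind_rows(files)
  spec <- attr(cohort, "spec")
  manifest <- list(
    package = "socialmvpa",
    version = as.character(utils::packageVersion("socialmvpa")),
    files = files
  )
  if (!is.null(spec)) {
    manifest$spec <- list(
      n_subjects = spec$n_subjects, n_runs = spec$n_runs,
      subject_jitter_sd = spec$subject_jitter_sd,
      geometry = unclass(spec$geometry),
      rois = purrr::map(spec$rois, unclass)
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
    simplifyVector = TRUE
  )
  files <- tibble::as_tibble(manifest$files)
  cells <- purrr::map(seq_len(nrow(files)), function(i) {
    d <- readr::read_csv(file.path(dir, files$file[i]),
      show_col_types = FALSE, progress = FALSE
    )
    d$person <- factor(d$person, levels = persons())
    d$valence <- factor(d$valence, levels = valences())
    dplyr::bind_cols(
      tibble::tibble(
        subject = files$subject[i], roi = files$roi[i],
        network = files$network[i]
      )[rep(1L, nrow(d)), ],
      d
    )
  })
  out <- dplyr::bind_rows(cells)
  if (!is.null(manifest$spec)) {
    sp <- manifest$spec
    geom <- do.call(geometry_params, as.list(sp$geometry))
    rois <- purrr::map(seq_len(nrow(sp$rois)), function(i) {
      r <- sp$rois[i, ]
      roi_spec(r$name, r$network,
        n_voxels = r$n_voxels, info_scale = r$info_scale,
        noise_sd_run = r$noise_sd_run, noise_sd_voxel = r$noise_sd_voxel
      )
    })
    attr(out, "spec") <- cohort_spec(
      n_subjects = sp$n_subjects, n_runs = sp$n_runs, rois = rois,
      geometry = geom, subject_jitter_sd = sp$subject_jitter_sd
    )
  }
  class(out) <- c("mvpa_cohort", class(out))
  out
}
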