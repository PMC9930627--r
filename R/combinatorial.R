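#' Decode the voxel-wise concatenation of two ROIs
#'
#' Joint-ROI decoding: the two pattern sets are aligned on (person, valence,
#' run) and concatenated along the voxel dimension, then decoded with the
#' same engine as a single ROI.
#'
#' @param patterns_a,patterns_b Pattern tibbles for the same subject
#'   (identical condition/run structure).
#' @param scheme A [make_scheme()] scheme.
#' @param settings A [classifier_settings()].
#' @return An `mvpa_accuracy` for the combined pattern.
#' @export
joint_accuracy <- function(patterns_a, patterns_b, scheme,
                           settings = classifier_settings()) {
  check_pattern_design(patterns_a)
  check_pattern_design(patterns_b)
  key <- c("person", "valence", "run")
  a <- dplyr::arrange(patterns_a, .data$run, .data$person, .data$valence)
  b <- dplyr::arrange(patterns_b, .data$run, .data$person, .data$valence)
  if (!identical(
    as.data.frame(a[, key]),
    as.data.frame(b[, key])
  )) {
    stop("the two ROIs have mismatched condition/run structure", call. = FALSE)
  }
  vox_b <- grep("^voxel_", names(b), value = TRUE)
  xb <- as.matrix(b[, vox_b])
  colnames(xb) <- paste0("voxel_", ncol_voxels(a) + seq_len(ncol(xb)))
  joint <- dplyr::bind_cols(
    a[, c(key, grep("^voxel_", names(a), value = TRUE))],
    tibble::as_tibble(xb)
  )
  decode_patterns(joint, scheme, settings)
}

ncol_voxels <- function(patterns) {
  length(grep("^voxel_", names(patterns)))
}

# Binding ROIs of unequal voxel counts into one tibble pads the narrower
# ROI with all-NA voxel columns; strip those before decoding.
drop_na_voxels <- function(patterns) {
  vox <- grep("^voxel_", names(patterns), value = TRUE)
  all_na <- vox[vapply(patterns[vox], function(v) all(is.na(v)), logical(1))]
  if (length(all_na) > 0) {
    patterns <- patterns[, setdiff(names(patterns), all_na)]
  }
  patterns
}

# Seeded subsampling of voxel columns down to n (without replacement).
subsample_voxels <- function(patterns, n, seed) {
  vox <- grep("^voxel_", names(patterns), value = TRUE)
  set.seed(seed)
  keep <- sort(sample(seq_along(vox), n))
  kept <- as.matrix(patterns[, vox[keep]])
  colnames(kept) <- paste0("voxel_", seq_len(n))
  dplyr::bind_cols(
    patterns[, c("person", "valence", "run")],
    tibble::as_tibble(kept)
  )
}

#' Pairwise combinatorial-ROI delta matrix for one subject
#'
#' For every ordered ROI pair (r, c), decodes the concatenation of ROI r
#' ("original") with ROI c ("added") and subtracts ROI r's single-ROI
#' baseline: `delta[r, c] = accuracy(joint r + c) - baseline[r]`. Rows are
#' the original ROI, columns the added ROI; the diagonal is `NA`. Joint
#' patterns all share the same feature count because ROI voxel counts must
#' match (or be equalized by seeded subsampling).
#'
#' @param subject_patterns Cohort tibble restricted to one subject
#'   (columns `roi`, `network`, `person`, `valence`, `run`, `voxel_*`).
#' @param scheme A [make_scheme()] scheme (name or object).
#' @param settings A [classifier_settings()].
#' @param equalize If ROI voxel counts differ, subsample every ROI down to
#'   the smallest count (seeded) instead of refusing.
#' @param seed Seed for the equalization subsampling.
#' @return An object of class `joint_delta` with elements `delta` (ROI x
#'   ROI matrix), `baseline` (named vector), `networks` (named vector),
#'   `scheme` and `subject`.
#' @export
combinatorial_matrix <- function(subject_patterns, scheme,
                                 settings = classifier_settings(),
                                 equalize = FALSE, seed = 1L) {
  if (is.character(scheme)) scheme <- make_scheme(scheme)
  if (length(unique(subject_patterns$subject)) > 1) {
    stop("combinatorial_matrix() expects a single subject", call. = FALSE)
  }
  cells <- dplyr::group_split(
    dplyr::group_by(subject_patterns, .data$roi, .data$network)
  )
  cells <- lapply(cells, drop_na_voxels)
  rois <- vapply(cells, function(d) d$roi[1], character(1))
  networks <- vapply(cells, function(d) as.character(d$network[1]), character(1))
  names(networks) <- rois
  if (length(rois) < 2) stop("need >= 2 ROIs", call. = FALSE)
  counts <- vapply(cells, ncol_voxels, integer(1))
  if (length(unique(counts)) > 1) {
    if (!equalize) {
      stop(
        "ROI voxel counts differ (", paste(counts, collapse = ", "),
        "); set equalize = TRUE to subsample",
        call. = FALSE
      )
    }
    n_min <- min(counts)
    cells <- lapply(seq_along(cells), function(i) {
      subsample_voxels(cells[[i]], n_min, seed + i)
    })
  }
  baseline <- vapply(cells, function(cell) {
    decode_patterns(cell, scheme, settings)$accuracy
  }, numeric(1))
  names(baseline) <- rois
  n <- length(rois)
  delta <- matrix(NA_real_, n, n, dimnames = list(original = rois, added = rois))
  for (r in seq_len(n)) {
    for (co in seq_len(n)) {
      if (r == co) next
      joint <- joint_accuracy(cells[[r]], cells[[co]], scheme, settings)
      delta[r, co] <- joint$accuracy - baseline[r]
    }
  }
  structure(
    list(
      delta = delta, baseline = baseline, networks = networks,
      scheme = scheme$name, subject = subject_patterns$subject[1]
    ),
    class = "joint_delta"
  )
}

#' Combinatorial-ROI decoding across a cohort
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @inheritParams combinatorial_matrix
#' @return A list of `joint_delta` objects, one per subject.
#' @export
combinatorial_cohort <- function(cohort, scheme = "self_vs_other",
                                 settings = classifier_settings(),
                                 equalize = FALSE, seed = 1L) {
  subjects <- unique(cohort$subject)
  lapply(subjects, function(s) {
    combinatorial_matrix(
      dplyr::filter(cohort, .data$subject == s),
      scheme, settings,
      equalize = equalize, seed = seed
    )
  })
}

#' Giver/taker summary of combinatorial decoding
#'
#' An ROI's *contribution* ("giver" score) is the mean of its column of the
#' delta matrix — the accuracy it adds when appended to other ROIs. Its
#' *benefit* ("taker" score) is the mean of its row — the accuracy it gains
#' from the addition of other ROIs. Both are averaged over subjects, and
#' the default-network versus semantic-network contrast is a signed-rank
#' test on subject-level network means.
#'
#' @param deltas A list of `joint_delta` objects (one per subject), as
#'   returned by [combinatorial_cohort()].
#' @param alpha Significance level for the network contrast.
#' @return A list of class `giver_taker` with `by_roi` (tibble of mean
#'   contribution/benefit per ROI), `by_subject` (subject-level network
#'   means) and `network_contrast` (signed-rank results for contribution
#'   and benefit, DN minus SN), or `NULL` contrast if a network has no ROI.
#' @export
giver_taker_summary <- function(deltas, alpha = 0.05) {
  stopifnot(length(deltas) >= 1, all(vapply(deltas, inherits, logical(1), "joint_delta")))
  per_subject <- purrr::map(deltas, function(d) {
    tibble::tibble(
      subject = d$subject,
      roi = rownames(d$delta),
      network = unname(d$networks[rownames(d$delta)]),
      contribution = colMeans(d$delta, na.rm = TRUE),
      benefit = rowMeans(d$delta, na.rm = TRUE),
      baseline = unname(d$baseline)
    )
  })
  per_subject <- dplyr::bind_rows(per_subject)
  by_roi <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$roi, .data$network),
    contribution = mean(.data$contribution),
    benefit = mean(.data$benefit),
    baseline = mean(.data$baseline),
    .groups = "drop"
  )
  by_subject <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$subject, .data$network),
    contribution = mean(.data$contribution),
    benefit = mean(.data$benefit),
    .groups = "drop"
  )
  contrast <- NULL
  if (all(c("DN", "SN") %in% by_subject$network) && length(deltas) >= 2) {
    wide <- tidyr::pivot_wider(by_subject,
      names_from = "network",
      values_from = c("contribution", "benefit")
    )
    contrast <- list(
      contribution = signed_rank_test(
        wide$contribution_DN - wide$contribution_SN,
        tail = "two", alpha = alpha
      ),
      benefit = signed_rank_test(
        wide$benefit_DN - wide$benefit_SN,
        tail = "two", alpha = alpha
      )
    )
  } else {
    warning("a network has no ROI (or only one subject); contrast omitted")
  }
  structure(
    list(
      by_roi = by_roi, by_subject = by_subject,
      network_contrast = contrast
    ),
    class = "giver_taker"
  )
}
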