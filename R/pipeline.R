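#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Default end-to-end analysis configuration
#'
#' @param n_subjects,n_runs Cohort size.
#' @param n_voxels Voxels per ROI.
#' @param schemes Decoding schemes to run.
#' @param combinatorial_scheme Scheme for the combinatorial-ROI stage
#'   (`NULL` skips the stage).
#' @param models Model RDMs for the comparison stage.
#' @param alpha Nominal significance level used throughout.
#' @return A named list understood by [run_full_analysis()].
#' @export
default_config <- function(n_subjects = 24L, n_runs = 8L, n_voxels = 80L,
                           schemes = scheme_names(),
                           combinatorial_scheme = "self_vs_other",
                           models = c("binary", "graded", "behavioral"),
                           alpha = 0.05) {
  list(
    n_subjects = n_subjects, n_runs = n_runs, n_voxels = n_voxels,
    schemes = schemes, combinatorial_scheme = combinatorial_scheme,
    models = models, alpha = alpha
  )
}

#' Run the full simulate-decode-combine-RSA-inference pipeline
#'
#' Simulates the cohort and behavioral ratings, runs all configured
#' decoding schemes with group tests against chance, the pairwise
#' combinatorial-ROI analysis with the giver/taker summary, the RSA suite
#' (cross-valence consistency, model comparison with noise ceiling,
#' second-order region clustering, within/between-network ANOVA) and the
#' univariate contrasts, and writes every table to `out_dir` as CSV plus a
#' JSON manifest. Byte-identical outputs are produced for identical
#' config + seed.
#'
#' @param config A list from [default_config()].
#' @param out_dir Output directory (created; `NULL` skips writing).
#' @param seed Master integer seed for every source of randomness.
#' @return Invisibly, a list with all result objects (`cohort` spec,
#'   `accuracy`, `group_tests`, `combinatorial`, `giver_taker`, `rsa`,
#'   `univariate`).
#' @export
run_full_analysis <- function(config = default_config(), out_dir = NULL,
                              seed = 1L) {
  alpha <- config$alpha
  spec <- cohort_spec(
    n_subjects = config$n_subjects, n_runs = config$n_runs,
    rois = default_rois(n_voxels = config$n_voxels),
    geometry = geometry_params(seed = seed)
  )
  cohort <- simulate_cohort(spec)
  ratings <- simulate_behavioral_ratings(spec, seed = seed + 1L)

  accuracy <- decode_cohort(cohort, schemes = config$schemes, keep_fits = FALSE)
  rois <- unique(accuracy$roi)
  group_tests <- dplyr::group_split(
    dplyr::group_by(accuracy, .data$roi, .data$network, .data$scheme)
  )
  group_tests <- purrr::map(group_tests, function(d) {
    res <- one_sample_t_vs_chance(d$accuracy,
      chance = d$chance[1],
      tail = "one", alpha = alpha, m = length(rois)
    )
    dplyr::bind_cols(
      tibble::tibble(
        roi = d$roi[1], network = d$network[1], scheme = d$scheme[1],
        mean_accuracy = mean(d$accuracy), chance = d$chance[1]
      ),
      tidy.mvpa_test(res)[, c("statistic", "df", "p", "significant_bonferroni")]
    )
  })
  group_tests <- dplyr::bind_rows(group_tests)

  combinatorial <- NULL
  giver_taker <- NULL
  if (!is.null(config$combinatorial_scheme)) {
    deltas <- combinatorial_cohort(cohort, config$combinatorial_scheme)
    combinatorial <- dplyr::bind_rows(purrr::map(deltas, tidy.joint_delta))
    giver_taker <- giver_taker_summary(deltas, alpha = alpha)
  }

  rsa <- list(
    cross_valence = cross_valence_consistency(cohort, alpha = alpha),
    model_comparison = model_comparison(cohort,
      models = config$models,
      ratings = ratings, alpha = alpha
    ),
    region_similarity = second_order_region_similarity(cohort),
    network_effect = within_between_network_effect(cohort)
  )
  univariate <- univariate_contrast(cohort, alpha = alpha)

  result <- list(
    spec = spec, accuracy = accuracy, group_tests = group_tests,
    combinatorial = combinatorial, giver_taker = giver_taker,
    rsa = rsa, univariate = univariate, ratings = ratings, seed = seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    w(accuracy, "accuracy.csv")
    w(group_tests, "group_tests.csv")
    if (!is.null(combinatorial)) {
      w(combinatorial, "combinatorial_deltas.csv")
      w(giver_taker$by_roi, "giver_taker_by_roi.csv")
      w(giver_taker$by_subject, "giver_taker_by_subject.csv")
    }
    w(rsa$cross_valence$by_roi, "cross_valence_by_roi.csv")
    w(rsa$model_comparison$by_roi, "model_comparison_by_roi.csv")
    if (!is.null(rsa$model_comparison$contrasts)) {
      w(rsa$model_comparison$contrasts, "model_contrasts.csv")
    }
    w(tidy.noise_ceiling(rsa$model_comparison$noise_ceiling), "noise_ceiling.csv")
    sim <- rsa$region_similarity$similarity
    w(
      dplyr::bind_cols(
        tibble::tibble(roi = rownames(sim)),
        tibble::as_tibble(sim)
      ),
      "region_similarity.csv"
    )
    writeLines(
      as_newick(rsa$region_similarity$tree),
      file.path(out_dir, "region_dendrogram.nwk")
    )
    w(rsa$region_similarity$tree$merges, "region_dendrogram_merges.csv")
    w(
      dplyr::bind_rows(rsa$network_effect$anova, .id = "method"),
      "network_anova.csv"
    )
    w(univariate$tests, "univariate_tests.csv")
    w(ratings, "ratings.csv")
    manifest <- list(
      package = "socialmvpa",
      version = as.character(utils::packageVersion("socialmvpa")),
      seed = seed, config = config
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(result)
}
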