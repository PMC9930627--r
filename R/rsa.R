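#' Lower-triangle vector of a square matrix
#'
#' Off-diagonal lower-triangular entries in column-major order; an m x m
#' matrix yields m(m-1)/2 values. Second-order RSA statistics use only
#' these entries to avoid inflating correlations with the diagonal.
#'
#' @param m A square matrix.
#' @return Numeric vector of length `m(m-1)/2`.
#' @export
lower_tri <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[lower.tri(m)]
}

#' Condition similarity matrix (neural RDM)
#'
#' Pearson correlation between the run-averaged beta vectors of every pair
#' of conditions. At the `eight_condition` level the matrix is 8 x 8
#' (person x valence); at the `four_person` level the two valence variants
#' of each person are averaged first, giving a 4 x 4 matrix. The
#' dissimilarity view is `1 - r` (see [rdm_distance()]).
#'
#' @param patterns Pattern tibble for one subject/ROI.
#' @param level `"eight_condition"` or `"four_person"`.
#' @param valence Optionally restrict to `"Positive"` or `"Negative"`
#'   conditions before averaging (used by the cross-valence analysis
#'   together with `level = "four_person"`).
#' @return A symmetric correlation matrix of class `similarity_matrix` with
#'   unit diagonal; attribute `level` records the level.
#' @export
condition_rdm <- function(patterns,
                          level = c("eight_condition", "four_person"),
                          valence = NULL) {
  level <- match.arg(level)
  if (!is.null(valence)) {
    patterns <- patterns[patterns$valence %in% valence, , drop = FALSE]
    if (nrow(patterns) == 0) stop("no conditions left after valence filter",
        call. = FALSE
      )
  }
  vox <- grep("^voxel_", names(patterns), value = TRUE)
  if (length(vox) < 2) stop("need >= 2 voxels", call. = FALSE)
  group_cols <- if (level == "eight_condition") {
    c("person", "valence")
  } else {
    "person"
  }
  avg <- dplyr::summarise(
    dplyr::group_by(patterns, dplyr::across(dplyr::all_of(group_cols))),
    dplyr::across(dplyr::all_of(vox), mean),
    .groups = "drop"
  )
  labels <- if (level == "eight_condition") {
    paste(avg$person, avg$valence, sep = ".")
  } else {
    as.character(avg$person)
  }
  x <- t(as.matrix(avg[, vox]))
  colnames(x) <- labels
  degenerate <- apply(x, 2, stats::sd) == 0
  if (any(degenerate)) {
    warning(
      "zero-variance pattern(s): ",
      paste(labels[degenerate], collapse = ", "),
      "; correlations undefined for their pairs"
    )
  }
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  structure(r, level = level, class = c("similarity_matrix", "matrix", "array"))
}

#' @rdname condition_rdm
#' @param similarity A similarity (correlation) matrix.
#' @export
rdm_distance <- function(similarity) {
  d <- 1 - unclass(similarity)
  diag(d) <- 0
  d
}

#' Kendall's tau-a rank correlation
#'
#' (concordant - discordant) / (n(n-1)/2), with no tie correction: tied
#' pairs count as neither concordant nor discordant but remain in the
#' denominator. This is the standard index for comparing representational
#' dissimilarity matrices against categorical model matrices with tied
#' entries.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The tau-a coefficient.
#' @export
kendall_tau_a <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need vectors of length >= 3", call. = FALSE)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  s <- dx * dy
  sum(s[lower.tri(s)]) / (n * (n - 1) / 2)
}

#' Rank correlation between two vectors
#'
#' Kendall's tau-a (no tie correction) or Spearman's rho (Pearson on
#' midranks). A constant input makes the coefficient undefined: `NA` is
#' returned with a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"kendall_tau_a"` or `"spearman_rho"`.
#' @return The coefficient, or `NA` if an input is constant.
#' @export
rank_correlation <- function(x, y,
                             method = c("kendall_tau_a", "spearman_rho")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; rank correlation undefined")
    return(NA_real_)
  }
  switch(method,
    kendall_tau_a = kendall_tau_a(x, y),
    spearman_rho = stats::cor(x, y, method = "spearman")
  )
}

#' Cross-valence consistency of person-level RDMs
#'
#' Per subject and ROI, builds the 4 x 4 person similarity matrix
#' separately from the positive and from the negative conditions,
#' rank-correlates their lower triangles, and tests the coefficients
#' against zero per ROI with a one-tailed signed-rank test (Bonferroni
#' over ROIs).
#'
#' @param cohort A cohort tibble.
#' @param method Rank-correlation method (see [rank_correlation()]).
#' @param alpha Nominal significance level.
#' @return A list with `per_subject` (subject x ROI coefficients) and
#'   `by_roi` (per-ROI mean coefficient, signed-rank statistic, p,
#'   Bonferroni flag).
#' @export
cross_valence_consistency <- function(cohort, method = "kendall_tau_a",
                                      alpha = 0.05) {
  cells <- dplyr::group_split(
    dplyr::group_by(cohort, .data$subject, .data$roi, .data$network)
  )
  per_subject <- purrr::map(cells, function(cell) {
    pos <- condition_rdm(cell, "four_person", valence = "Positive")
    neg <- condition_rdm(cell, "four_person", valence = "Negative")
    tibble::tibble(
      subject = cell$subject[1], roi = cell$roi[1], network = cell$network[1],
      coefficient = rank_correlation(lower_tri(pos), lower_tri(neg), method)
    )
  })
  per_subject <- dplyr::bind_rows(per_subject)
  rois <- unique(per_subject$roi)
  by_roi <- purrr::map(rois, function(r) {
    co <- per_subject$coefficient[per_subject$roi == r]
    res <- signed_rank_test(co, tail = "one", alpha = alpha, m = length(rois))
    tibble::tibble(
      roi = r,
      network = per_subject$network[per_subject$roi == r][1],
      mean_coefficient = mean(co, na.rm = TRUE),
      statistic = res$statistic, p = res$p,
      significant_bonferroni = res$significant_bonferroni
    )
  })
  list(per_subject = per_subject, by_roi = dplyr::bind_rows(by_roi))
}

#' Noise ceiling for RDM model correlations
#'
#' Upper bound: mean over subjects of the rank correlation between each
#' subject's matrix and the group-average matrix (subject included). Lower
#' bound: the same with the subject excluded from the average
#' (leave-one-subject-out).
#'
#' @param matrices List of same-sized similarity (or dissimilarity)
#'   matrices, one per subject.
#' @param method Rank-correlation method.
#' @return A list of class `noise_ceiling` with elements `lower` and
#'   `upper`.
#' @export
noise_ceiling <- function(matrices, method = "kendall_tau_a") {
  n <- length(matrices)
  if (n < 3) stop("need >= 3 subjects", call. = FALSE)
  lts <- vapply(matrices, lower_tri, numeric(length(lower_tri(matrices[[1]]))))
  grand <- rowMeans(lts)
  upper <- mean(vapply(seq_len(n), function(i) {
    rank_correlation(lts[, i], grand, method)
  }, numeric(1)))
  lower <- mean(vapply(seq_len(n), function(i) {
    rank_correlation(lts[, i], rowMeans(lts[, -i, drop = FALSE]), method)
  }, numeric(1)))
  structure(list(lower = lower, upper = upper), class = "noise_ceiling")
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Average linkage (UPGMA) by default. Input must be square, symmetric and
#' nonnegative with a zero diagonal. Ties in merge order follow the
#' deterministic behavior of the underlying agglomeration (first pair in
#' index order).
#'
#' @param distance Square symmetric distance matrix with labels.
#' @param linkage Linkage method passed to the agglomeration
#'   (`"average"`, `"complete"`, `"single"`, ...).
#' @return An object of class `mvpa_dendrogram`: list with the `hclust`
#'   fit, a `merges` tibble (step, heights, member labels) and `labels`.
#' @export
hierarchical_clustering <- function(distance, linkage = "average") {
  stopifnot(is.matrix(distance), nrow(distance) == ncol(distance))
  if (max(abs(distance - t(distance))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(distance) != 0) || any(distance < -1e-12)) {
    stop("need a nonnegative distance matrix with zero diagonal", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(distance), method = linkage)
  labels <- hc$labels
  merges <- tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
  structure(
    list(hclust = hc, merges = merges, labels = labels, linkage = linkage),
    class = "mvpa_dendrogram"
  )
}

#' @rdname hierarchical_clustering
#' @param tree An `mvpa_dendrogram`.
#' @param k Number of clusters to cut into.
#' @return `cut_clusters()`: named membership vector; `as_newick()`: a
#'   Newick string with branch lengths from the merge heights.
#' @export
cut_clusters <- function(tree, k = 2) {
  stats::cutree(tree$hclust, k = k)
}

#' @rdname hierarchical_clustering
#' @export
as_newick <- function(tree) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy)
}

#' Model dissimilarity matrices over the four persons
#'
#' * `binary`: 0 within the self pair and within the other pair, 1 between
#'   the domains.
#' * `graded`: equidistant spectrum — dissimilarity is the absolute
#'   difference of the ordinal positions 0..3, so PresentSelf-Queen is
#'   three times PresentSelf-PastSelf.
#' * `behavioral`: `(100 - rating) / 100` from a subject's pairwise
#'   similarity ratings.
#'
#' @param kind `"binary"`, `"graded"` or `"behavioral"`.
#' @param ratings For `"behavioral"`: a rating tibble for one subject (see
#'   [simulate_behavioral_ratings()]) or a 4 x 4 rating matrix.
#' @return A 4 x 4 dissimilarity matrix of class `model_rdm` with attribute
#'   `kind`; a zero-variance behavioral matrix carries attribute
#'   `degenerate = TRUE` (with a warning).
#' @export
model_rdm <- function(kind = c("binary", "graded", "behavioral"),
                      ratings = NULL) {
  kind <- match.arg(kind)
  p <- persons()
  pos <- 0:3
  degenerate <- FALSE
  m <- switch(kind,
    binary = {
      self <- p %in% c("PresentSelf", "PastSelf")
      outer(self, self, "!=") * 1
    },
    graded = abs(outer(pos, pos, "-")),
    behavioral = {
      if (is.null(ratings)) {
        stop("behavioral model requires ratings", call. = FALSE)
      }
      rm <- if (is.matrix(ratings)) ratings else rating_matrix(ratings)
      d <- (100 - rm[p, p]) / 100
      diag(d) <- 0
      if (stats::sd(d[lower.tri(d)]) == 0) {
        degenerate <- TRUE
        warning("behavioral ratings have zero variance; model RDM is flat")
      }
      d
    }
  )
  dimnames(m) <- list(p, p)
  structure(m,
    kind = kind, degenerate = degenerate,
    class = c("model_rdm", "matrix", "array")
  )
}

#' Compare model RDMs against neural similarity matrices
#'
#' Per subject and ROI, rank-correlates the lower triangle of the neural
#' person-level dissimilarity (1 - r) with each model RDM. Per ROI and
#' model, coefficients are tested against zero with a one-tailed
#' signed-rank test, Bonferroni-corrected over ROIs. Models are also
#' contrasted pairwise (two-tailed signed-rank on per-subject coefficient
#' differences, averaged over ROIs), and the leave-one-subject-out noise
#' ceiling — averaged across regions — is attached.
#'
#' @param cohort A cohort tibble.
#' @param models Character vector of model kinds, or a named list of
#'   `model_rdm` matrices shared by all subjects.
#' @param ratings Rating tibble over subjects (required when
#'   `"behavioral"` is among the models); each subject is compared against
#'   their own behavioral RDM.
#' @param method Rank-correlation method.
#' @param alpha Nominal significance level.
#' @return A list of class `model_comparison`: `per_subject` coefficients,
#'   `by_roi` test table, `contrasts` (pairwise model tests) and
#'   `noise_ceiling`.
#' @export
model_comparison <- function(cohort, models = c("binary", "graded"),
                             ratings = NULL, method = "kendall_tau_a",
                             alpha = 0.05) {
  if (is.character(models)) {
    names(models) <- models
  } else {
    stopifnot(!is.null(names(models)))
  }
  cells <- dplyr::group_split(
    dplyr::group_by(cohort, .data$subject, .data$roi, .data$network)
  )
  neural <- purrr::map(cells, function(cell) {
    list(
      subject = cell$subject[1], roi = cell$roi[1],
      network = as.character(cell$network[1]),
      rdm = rdm_distance(condition_rdm(cell, "four_person"))
    )
  })
  model_for <- function(kind_or_matrix, subject) {
    if (is.matrix(kind_or_matrix)) {
      return(kind_or_matrix)
    }
    if (kind_or_matrix == "behavioral") {
      if (is.null(ratings)) stop("behavioral model requires ratings",
          call. = FALSE
        )
      model_rdm("behavioral", ratings[ratings$subject == subject, ])
    } else {
      model_rdm(kind_or_matrix)
    }
  }
  per_subject <- purrr::map(neural, function(cell) {
    purrr::map(names(models), function(mn) {
      mm <- model_for(models[[mn]], cell$subject)
      if (isTRUE(attr(mm, "degenerate"))) {
        warning("degenerate model '", mn, "' excluded for ", cell$subject)
        return(NULL)
      }
      tibble::tibble(
        subject = cell$subject, roi = cell$roi, network = cell$network,
        model = mn,
        coefficient = rank_correlation(
          lower_tri(cell$rdm), lower_tri(unclass(mm)), method
        )
      )
    })
  })
  per_subject <- dplyr::bind_rows(purrr::flatten(per_subject))
  rois <- unique(per_subject$roi)
  by_roi <- dplyr::group_split(
    dplyr::group_by(per_subject, .data$roi, .data$network, .data$model)
  )
  by_roi <- purrr::map(by_roi, function(d) {
    res <- signed_rank_test(d$coefficient,
      tail = "one", alpha = alpha,
      m = length(rois)
    )
    tibble::tibble(
      roi = d$roi[1], network = d$network[1], model = d$model[1],
      mean_coefficient = mean(d$coefficient, na.rm = TRUE),
      statistic = res$statistic, p = res$p,
      significant_bonferroni = res$significant_bonferroni
    )
  })
  by_roi <- dplyr::bind_rows(by_roi)
  # pairwise model contrasts on per-subject coefficients averaged over ROIs
  subj_means <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$subject, .data$model),
    coefficient = mean(.data$coefficient, na.rm = TRUE), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(subj_means,
    names_from = "model",
    values_from = "coefficient"
  )
  mods <- intersect(names(models), names(wide))
  contrasts <- NULL
  if (length(mods) >= 2) {
    combos <- utils::combn(mods, 2)
    contrasts <- purrr::map(seq_len(ncol(combos)), function(i) {
      a <- combos[1, i]
      b <- combos[2, i]
      res <- signed_rank_test(wide[[a]] - wide[[b]], tail = "two",
        alpha = alpha
      )
      tibble::tibble(
        model_a = a, model_b = b,
        mean_difference = mean(wide[[a]] - wide[[b]], na.rm = TRUE),
        statistic = res$statistic, p = res$p
      )
    })
    contrasts <- dplyr::bind_rows(contrasts)
  }
  ceilings <- purrr::map(rois, function(r) {
    mats <- purrr::map(
      purrr::keep(neural, function(cell) cell$roi == r),
      "rdm"
    )
    noise_ceiling(mats, method)
  })
  nc <- structure(
    list(
      lower = mean(vapply(ceilings, `[[`, numeric(1), "lower")),
      upper = mean(vapply(ceilings, `[[`, numeric(1), "upper"))
    ),
    class = "noise_ceiling"
  )
  structure(
    list(
      per_subject = per_subject, by_roi = by_roi, contrasts = contrasts,
      noise_ceiling = nc
    ),
    class = "model_comparison"
  )
}

#' Second-order similarity between regions
#'
#' Group-averages each region's eight-condition similarity matrix over
#' subjects (entrywise), rank-correlates every pair of regions' lower
#' triangles, and clusters the resulting distance (1 - coefficient).
#'
#' @param cohort A cohort tibble.
#' @param method Rank-correlation method.
#' @param linkage Linkage for the dendrogram.
#' @return A list with `similarity` (region x region coefficients),
#'   `distance`, `tree` (an `mvpa_dendrogram`) and `networks` (named
#'   vector).
#' @export
second_order_region_similarity <- function(cohort, method = "kendall_tau_a",
                                           linkage = "average") {
  cells <- dplyr::group_split(dplyr::group_by(cohort, .data$roi, .data$network))
  if (length(cells) < 2) stop("need >= 2 regions", call. = FALSE)
  region_mats <- purrr::map(cells, function(cell) {
    subj <- dplyr::group_split(dplyr::group_by(cell, .data$subject))
    mats <- purrr::map(subj, condition_rdm)
    Reduce(`+`, lapply(mats, unclass)) / length(mats)
  })
  rois <- vapply(cells, function(d) d$roi[1], character(1))
  networks <- vapply(cells, function(d) as.character(d$network[1]), character(1))
  names(networks) <- rois
  n <- length(rois)
  sim <- matrix(1, n, n, dimnames = list(rois, rois))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- rank_correlation(
        lower_tri(region_mats[[i]]), lower_tri(region_mats[[j]]), method
      )
      sim[i, j] <- sim[j, i] <- co
    }
  }
  dist <- 1 - sim
  diag(dist) <- 0
  list(
    similarity = sim, distance = dist,
    tree = hierarchical_clustering(dist, linkage), networks = networks
  )
}

#' Within- versus between-network representational similarity
#'
#' Per subject and valence context, computes each region's person-level
#' similarity matrix from that valence's conditions, rank-correlates every
#' region pair, and averages the coefficients over within-network pairs
#' and between-network pairs. The resulting 2 (membership) x 2 (valence)
#' within-subject table is analyzed with [rm_anova_2x2()].
#'
#' @param cohort A cohort tibble with DN and SN regions.
#' @param methods Rank-correlation methods to run (results are reported
#'   for each).
#' @return A list with `cell_means` (subject x membership x valence x
#'   method) and `anova` (one `mvpa_anova` tibble per method, with the
#'   membership factor as `A` and valence as `B`).
#' @export
within_between_network_effect <- function(cohort,
                                          methods = c(
                                            "kendall_tau_a",
                                            "spearman_rho"
                                          )) {
  subjects <- unique(cohort$subject)
  if (length(subjects) < 2) stop("need >= 2 subjects", call. = FALSE)
  vals <- valences()
  rows <- list()
  for (s in subjects) {
    sc <- cohort[cohort$subject == s, , drop = FALSE]
    cells <- dplyr::group_split(dplyr::group_by(sc, .data$roi, .data$network))
    rois <- vapply(cells, function(d) d$roi[1], character(1))
    networks <- vapply(cells, function(d) as.character(d$network[1]), character(1))
    for (v in vals) {
      mats <- purrr::map(cells, condition_rdm,
        level = "four_person",
        valence = v
      )
      lts <- vapply(mats, lower_tri, numeric(6))
      idx <- utils::combn(length(rois), 2)
      same <- networks[idx[1, ]] == networks[idx[2, ]]
      if (!any(same) || all(same)) {
        stop("need both within- and between-network region pairs",
          call. = FALSE
        )
      }
      for (meth in methods) {
        co <- vapply(seq_len(ncol(idx)), function(k) {
          rank_correlation(lts[, idx[1, k]], lts[, idx[2, k]], meth)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = s, valence = v, method = meth,
          membership = c("within", "between"),
          similarity = c(mean(co[same]), mean(co[!same]))
        )
      }
    }
  }
  cell_means <- dplyr::bind_rows(rows)
  anova <- purrr::map(stats::setNames(methods, methods), function(meth) {
    d <- cell_means[cell_means$method == meth, ]
    rm_anova_2x2(d,
      subject = "subject", factor_a = "membership",
      factor_b = "valence", value = "similarity"
    )
  })
  list(cell_means = cell_means, anova = anova)
}

#' Concordance between pattern similarity and pairwise decodability
#'
#' Rank-correlates pairwise condition similarity with pairwise binary
#' decoding accuracy: pairs whose patterns are more similar are expected
#' to be harder to tell apart, giving a negative coefficient. Run
#' separately within each valence context.
#'
#' @param patterns Pattern tibble for one subject/ROI.
#' @param settings A [classifier_settings()] for the pairwise decoding.
#' @param method Rank-correlation method (default Spearman).
#' @return A tibble with one row per valence: `valence`, `coefficient`,
#'   `n_pairs`. A constant accuracy vector gives `NA` with a warning.
#' @export
similarity_accuracy_concordance <- function(patterns,
                                            settings = classifier_settings(),
                                            method = "spearman_rho") {
  acc <- pairwise_condition_accuracy(patterns, settings)
  out <- purrr::map(valences(), function(v) {
    sim <- condition_rdm(patterns, "four_person", valence = v)
    av <- acc[acc$valence == v, ]
    sims <- mapply(function(a, b) sim[a, b],
      as.character(av$person_a), as.character(av$person_b)
    )
    tibble::tibble(
      valence = v,
      coefficient = rank_correlation(sims, av$accuracy, method),
      n_pairs = nrow(av)
    )
  })
  dplyr::bind_rows(out)
}
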