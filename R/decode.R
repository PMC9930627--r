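#' Train a linear SVM and predict test labels
#'
#' Thin deterministic wrapper around a linear max-margin classifier
#' (libsvm via e1071) with fixed cost and optional train-fold z-scoring.
#'
#' @param train_x,test_x Numeric matrices with equal column counts.
#' @param train_y Class labels for the training rows (factor or character).
#' @param settings A [classifier_settings()].
#' @return Factor of predicted labels, one per test row, with the levels of
#'   `train_y`.
#' @export
train_and_predict <- function(train_x, train_y,
                              test_x, settings = classifier_settings()) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (ncol(train_x) != ncol(test_x)) {
    stop("train and test feature dimensions differ", call. = FALSE)
  }
  if (!is.factor(train_y)) train_y <- factor(train_y)
  if (any(table(train_y) == 0)) {
    stop("every class needs at least one training example", call. = FALSE)
  }
  if (settings$scaling == "train_fold_zscore") {
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sdv, "/")
  }
  fit <- e1071::svm(train_x, train_y,
    kernel = "linear", cost = settings$cost,
    scale = FALSE, type = "C-classification"
  )
  unname(stats::predict(fit, test_x))
}

# Apply a scheme's class map to a design tibble; returns character classes
# with NA for excluded conditions.
scheme_classes <- function(scheme, design) {
  key <- paste(design$person, design$valence)
  map_key <- paste(scheme$map$person, scheme$map$valence)
  scheme$map$class[match(key, map_key)]
}

scheme_sides <- function(scheme, design) {
  key <- paste(design$person, design$valence)
  map_key <- paste(scheme$map$person, scheme$map$valence)
  scheme$map$side[match(key, map_key)]
}

new_accuracy_result <- function(scheme, per_fold, confusion) {
  structure(
    list(
      scheme = scheme$name, mode = scheme$mode,
      accuracy = mean(per_fold$accuracy), per_fold = per_fold,
      chance = scheme$chance, n_folds = nrow(per_fold),
      confusion = confusion
    ),
    class = "mvpa_accuracy"
  )
}

#' @export
print.mvpa_accuracy <- function(x, ...) {
  cat(sprintf(
    "<mvpa_accuracy> scheme %s (%s): accuracy %.3f (chance %.3f, %d folds)\n",
    x$scheme, x$mode, x$accuracy, x$chance, x$n_folds
  ))
  invisible(x)
}

#' Leave-one-run-out cross-validated decoding of one ROI
#'
#' One fold per run: the classifier learns from all other runs and is
#' tested on the held-out run, so no example ever appears in both the
#' training and test set of a fold. Accuracy is example-weighted within a
#' fold and averaged across folds.
#'
#' @param patterns Pattern tibble for one subject/ROI (columns `person`,
#'   `valence`, `run`, `voxel_*`), e.g. one cell of [simulate_cohort()].
#' @param scheme A cross-validation [make_scheme()] scheme.
#' @param settings A [classifier_settings()].
#' @return An object of class `mvpa_accuracy` with fields `accuracy`,
#'   `per_fold`, `chance`, `n_folds` and a true-by-predicted `confusion`
#'   count matrix. See [tidy.mvpa_accuracy()].
#' @export
cross_validate <- function(patterns, scheme,
                           settings = classifier_settings()) {
  stopifnot(inherits(scheme, "decoding_scheme"))
  if (scheme$mode != "cross_validation") {
    stop("scheme '", scheme$name, "' is not a cross-validation scheme",
      call. = FALSE
    )
  }
  check_pattern_design(patterns)
  pm <- pattern_matrix(patterns)
  cls <- scheme_classes(scheme, pm$design)
  keep <- !is.na(cls)
  x <- pm$x[keep, , drop = FALSE]
  y <- factor(cls[keep], levels = scheme$classes)
  run <- pm$design$run[keep]
  eng <- loro_engine(x, y, run, scheme, settings)
  new_accuracy_result(scheme, eng$per_fold, eng$confusion)
}

# Leave-one-run-out fold loop shared by ROI cross-validation and the
# searchlight (identical folds and classifier either way).
loro_engine <- function(x, y, run, scheme, settings) {
  runs <- sort(unique(run))
  if (length(runs) < 2) stop("need >= 2 runs for cross-validation", call. = FALSE)
  confusion <- matrix(0L, scheme$n_classes, scheme$n_classes,
    dimnames = list(true = scheme$classes, predicted = scheme$classes)
  )
  per_fold <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    test <- run == runs[i]
    pred <- train_and_predict(
      x[!test, , drop = FALSE], y[!test],
      x[test, , drop = FALSE], settings
    )
    confusion <- confusion + unclass(table(y[test], pred))
    per_fold[[i]] <- tibble::tibble(
      fold = i, run = runs[i],
      accuracy = mean(pred == y[test]), n_test = sum(test)
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  list(
    per_fold = per_fold, confusion = confusion,
    accuracy = mean(per_fold$accuracy)
  )
}

#' Bidirectional cross-classification of one ROI
#'
#' Trains on one condition partition and tests on the disjoint other
#' partition, in both directions, and averages the two direction
#' accuracies. The train and test condition sets never overlap, and all
#' runs contribute to both sides (generalization is across conditions, not
#' runs).
#'
#' @inheritParams cross_validate
#' @param scheme A cross-classification [make_scheme()] scheme.
#' @return An `mvpa_accuracy`; `per_fold` holds one row per direction.
#' @export
cross_classify <- function(patterns, scheme,
                           settings = classifier_settings()) {
  stopifnot(inherits(scheme, "decoding_scheme"))
  if (scheme$mode != "cross_classification") {
    stop("scheme '", scheme$name, "' is not a cross-classification scheme",
      call. = FALSE
    )
  }
  check_pattern_design(patterns)
  pm <- pattern_matrix(patterns)
  cls <- scheme_classes(scheme, pm$design)
  side <- scheme_sides(scheme, pm$design)
  keep <- !is.na(cls) & !is.na(side)
  x <- pm$x[keep, , drop = FALSE]
  y <- factor(cls[keep], levels = scheme$classes)
  side <- side[keep]
  confusion <- matrix(0L, scheme$n_classes, scheme$n_classes,
    dimnames = list(true = scheme$classes, predicted = scheme$classes)
  )
  dirs <- list(c("A", "B"), c("B", "A"))
  per_fold <- vector("list", 2L)
  for (i in 1:2) {
    tr <- side == dirs[[i]][1]
    te <- side == dirs[[i]][2]
    pred <- train_and_predict(
      x[tr, , drop = FALSE], y[tr],
      x[te, , drop = FALSE], settings
    )
    confusion <- confusion + unclass(table(y[te], pred))
    per_fold[[i]] <- tibble::tibble(
      fold = i, run = NA_integer_,
      accuracy = mean(pred == y[te]), n_test = sum(te)
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  per_fold$direction <- c("A_to_B", "B_to_A")
  new_accuracy_result(scheme, per_fold, confusion)
}

# Dispatch on the scheme's mode.
decode_patterns <- function(patterns, scheme,
                            settings = classifier_settings()) {
  if (scheme$mode == "cross_validation") {
    cross_validate(patterns, scheme, settings)
  } else {
    cross_classify(patterns, scheme, settings)
  }
}

#' Decode every subject/ROI cell of a cohort
#'
#' Runs each requested scheme through the leave-one-run-out or
#' cross-classification engine for every subject-by-ROI cell and returns a
#' tidy accuracy table.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (or any tibble
#'   with `subject`, `roi`, `network`, `person`, `valence`, `run`,
#'   `voxel_*` columns).
#' @param schemes Character vector of scheme names (default: all seven).
#' @param settings A [classifier_settings()].
#' @param keep_fits Keep the full `mvpa_accuracy` objects (with confusion
#'   matrices) in a list-column `fit`? Default `TRUE`.
#' @return A tibble with one row per subject x ROI x scheme: `subject`,
#'   `roi`, `network`, `scheme`, `mode`, `accuracy`, `chance`, `n_folds`
#'   and optionally `fit`.
#' @export
decode_cohort <- function(cohort, schemes = scheme_names(),
                          settings = classifier_settings(),
                          keep_fits = TRUE) {
  scheme_objs <- lapply(schemes, make_scheme)
  cells <- dplyr::group_split(
    dplyr::group_by(cohort, .data$subject, .data$roi, .data$network)
  )
  rows <- purrr::map(cells, function(cell) {
    purrr::map(scheme_objs, function(sch) {
      res <- decode_patterns(cell, sch, settings)
      out <- tibble::tibble(
        subject = cell$subject[1], roi = cell$roi[1],
        network = cell$network[1], scheme = sch$name, mode = sch$mode,
        accuracy = res$accuracy, chance = res$chance, n_folds = res$n_folds
      )
      if (keep_fits) out$fit <- list(res)
      out
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Pairwise condition decoding accuracies
#'
#' Leave-one-run-out binary decoding of every pair of the four persons,
#' separately within each valence context (one example per condition per
#' run). Used for the similarity/accuracy concordance analysis.
#'
#' @param patterns Pattern tibble for one subject/ROI.
#' @param settings A [classifier_settings()].
#' @return A tibble with columns `valence`, `person_a`, `person_b`, `pair`,
#'   `accuracy`.
#' @export
pairwise_condition_accuracy <- function(patterns,
                                        settings = classifier_settings()) {
  check_pattern_design(patterns)
  pm <- pattern_matrix(patterns)
  pairs <- person_pairs()
  out <- tidyr::expand_grid(
    valence = factor(valences(), levels = valences()),
    pair = pairs$pair
  )
  out <- dplyr::left_join(out, pairs, by = "pair")
  acc <- numeric(nrow(out))
  runs <- sort(unique(pm$design$run))
  for (i in seq_len(nrow(out))) {
    keep <- pm$design$valence == out$valence[i] &
      pm$design$person %in% c(
        as.character(out$person_a[i]),
        as.character(out$person_b[i])
      )
    x <- pm$x[keep, , drop = FALSE]
    y <- droplevels(pm$design$person[keep])
    run <- pm$design$run[keep]
    fold_acc <- vapply(runs, function(r) {
      te <- run == r
      pred <- train_and_predict(
        x[!te, , drop = FALSE], y[!te],
        x[te, , drop = FALSE], settings
      )
      mean(pred == y[te])
    }, numeric(1))
    acc[i] <- mean(fold_acc)
  }
  out$accuracy <- acc
  out[, c("valence", "person_a", "person_b", "pair", "accuracy")]
}

#' Row-normalized confusion percentages
#'
#' @param result An `mvpa_accuracy` (or a raw confusion count matrix).
#' @return A matrix of percentages; each row sums to 100 (rows with no test
#'   examples are `NaN`).
#' @export
confusion_percentages <- function(result) {
  counts <- if (inherits(result, "mvpa_accuracy")) result$confusion else result
  100 * counts / rowSums(counts)
}
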