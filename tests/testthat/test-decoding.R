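test_that("scheme definitions match the seven analyses", {
  s1 <- make_scheme("self_vs_other")
  expect_equal(s1$chance, 0.5)
  expect_equal(s1$mode, "cross_validation")
  expect_equal(
    unique(s1$map$class[s1$map$person %in% c("PresentSelf", "PastSelf")]),
    "self"
  )

  s4 <- make_scheme("four_way")
  expect_equal(s4$n_classes, 4)
  expect_equal(s4$chance, 0.25)

  s6 <- make_scheme("xclass_distance_across_domain")
  expect_equal(s6$mode, "cross_classification")
  train <- unique(s6$map$person[s6$map$side == "A"])
  test <- unique(s6$map$person[s6$map$side == "B"])
  expect_setequal(as.character(train), c("PresentSelf", "PastSelf"))
  expect_setequal(as.character(test), c("Mother", "Queen"))
  expect_length(intersect(train, test), 0)

  # all cross-classification schemes keep train and test conditions disjoint
  for (nm in grep("^xclass", scheme_names(), value = TRUE)) {
    sch <- make_scheme(nm)
    a <- paste(sch$map$person, sch$map$valence)[sch$map$side == "A"]
    b <- paste(sch$map$person, sch$map$valence)[sch$map$side == "B"]
    expect_length(intersect(a, b), 0)
  }

  # valence split of scheme (7): 32 examples per side with 8 runs
  s7 <- make_scheme("xclass_four_way_across_valence")
  expect_equal(sum(s7$map$side == "A") * 8, 32)
  expect_equal(sum(s7$map$side == "B") * 8, 32)

  expect_error(make_scheme("nope"), "unknown scheme")
})

test_that("binary scheme splits 64 examples into 32 per class", {
  p <- noise_free_patterns(n_runs = 8)
  s <- make_scheme("self_vs_other")
  res <- cross_validate(p, s)
  expect_equal(sum(res$confusion), 64)
  expect_equal(unname(rowSums(res$confusion)), c(32, 32))
})

test_that("linear SVM finds the max-margin boundary on a toy problem", {
  train_x <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  train_y <- c("A", "A", "B", "B")
  # margin midline at x = 1
  pred <- train_and_predict(train_x, train_y, rbind(c(-1, 0.5), c(3, 0.5)))
  expect_equal(as.character(pred), c("A", "B"))
  # a training vector of a well-separated class classifies as that class
  pred2 <- train_and_predict(train_x, train_y, train_x[4, , drop = FALSE])
  expect_equal(as.character(pred2), "B")
  # default cost is 1
  expect_equal(classifier_settings()$cost, 1)
  expect_error(classifier_settings(cost = 0), "cost")
  expect_error(
    train_and_predict(train_x, train_y, matrix(0, 1, 3)),
    "dimensions differ"
  )
  expect_error(
    train_and_predict(train_x, factor(train_y, levels = c("A", "B", "C")),
      test_x = train_x
    ),
    "training example"
  )
})

test_that("train-fold z-scoring is applied from training statistics only", {
  set.seed(1)
  train_x <- cbind(rnorm(10, mean = 100, sd = 5), rnorm(10))
  train_y <- rep(c("A", "B"), each = 5)
  train_x[train_y == "B", 2] <- train_x[train_y == "B", 2] + 4
  pred <- train_and_predict(train_x, train_y, train_x,
    settings = classifier_settings(scaling = "train_fold_zscore")
  )
  expect_equal(as.character(pred), train_y)
})

test_that("leave-one-run-out folds are one per run with clean hygiene", {
  p <- simulate_roi_patterns(
    geometry_params(),
    roi_spec("x", "DN", n_voxels = 20), 8,
    seed = 1
  )
  res <- cross_validate(p, make_scheme("self_vs_other"))
  expect_equal(res$n_folds, 8)
  expect_equal(sort(res$per_fold$run), 1:8) # each run held out exactly once
  expect_equal(res$accuracy, mean(res$per_fold$accuracy))
  expect_true(all(res$per_fold$n_test == 8))
  # confusion percentages: rows sum to 100
  expect_equal(unname(rowSums(confusion_percentages(res))), c(100, 100))
  # mode mismatch errors
  expect_error(
    cross_validate(p, make_scheme("xclass_distance_across_domain")),
    "not a cross-validation"
  )
  expect_error(
    cross_classify(p, make_scheme("four_way")),
    "not a cross-classification"
  )
})

test_that("separable noise-free patterns decode perfectly in both engines", {
  p <- noise_free_patterns(geometry_params(d_self_other = 2, d_distance = 1))
  for (nm in c("self_vs_other", "present_vs_past", "mother_vs_queen", "four_way")) {
    expect_equal(cross_validate(p, make_scheme(nm))$accuracy, 1)
  }
  for (nm in grep("^xclass", scheme_names(), value = TRUE)) {
    expect_equal(cross_classify(p, make_scheme(nm))$accuracy, 1)
  }
})

test_that("cross-classification averages both directions symmetrically", {
  p <- simulate_roi_patterns(
    geometry_params(),
    roi_spec("x", "DN", n_voxels = 30), 8,
    seed = 3
  )
  sch <- make_scheme("xclass_self_other_across_distance")
  res <- cross_classify(p, sch)
  expect_equal(res$n_folds, 2)
  expect_equal(res$accuracy, mean(res$per_fold$accuracy))
  # relabeling which partition is side A leaves the result unchanged
  sch_flip <- sch
  sch_flip$map$side <- ifelse(sch$map$side == "A", "B", "A")
  res_flip <- cross_classify(p, sch_flip)
  expect_equal(res_flip$accuracy, res$accuracy)
  expect_setequal(res_flip$per_fold$accuracy, res$per_fold$accuracy)
})

test_that("cross-classification reads the shared axis, not the nuisance axis", {
  # self/other axis shared across distances; distance axis is present too.
  # A classifier trained on the near pair must transfer to the far pair.
  params <- geometry_params(d_self_other = 3, d_distance = 1)
  roi <- roi_spec("x", "DN",
    n_voxels = 40, info_scale = 1,
    noise_sd_run = 0.2, noise_sd_voxel = 0.5
  )
  accs <- vapply(1:5, function(s) {
    p <- simulate_roi_patterns(params, roi, 8, seed = 100 + s)
    cross_classify(p, make_scheme("xclass_self_other_across_distance"))$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.9)
  # with the shared axis silenced the same transfer collapses to chance
  params0 <- geometry_params(d_self_other = 0, d_distance = 1)
  accs0 <- vapply(1:10, function(s) {
    p <- simulate_roi_patterns(params0, roi, 8, seed = 200 + s)
    cross_classify(p, make_scheme("xclass_self_other_across_distance"))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs0) - 0.5), 0.15)
})

test_that("cohort decoding returns one tidy row per cell and scheme", {
  acc <- decode_cohort(small_cohort(),
    schemes = c("self_vs_other", "xclass_four_way_across_valence")
  )
  expect_equal(nrow(acc), 5 * 4 * 2)
  expect_setequal(unique(acc$chance), c(0.5, 0.25))
  expect_s3_class(acc$fit[[1]], "mvpa_accuracy")
  g <- glance(acc$fit[[1]])
  expect_equal(g$accuracy, acc$accuracy[1])
  td <- tidy(acc$fit[[1]])
  expect_equal(nrow(td), 8)
})

test_that("pairwise condition decoding covers all person pairs per valence", {
  cell <- dplyr::filter(small_cohort(), subject == "sub01", roi == "PCC")
  pw <- pairwise_condition_accuracy(cell)
  expect_equal(nrow(pw), 12) # 6 pairs x 2 valences
  expect_true(all(pw$accuracy >= 0 & pw$accuracy <= 1))
  # the widest separation (PresentSelf vs Queen) should decode best on average
  agg <- tapply(pw$accuracy, pw$pair, mean)
  expect_gt(agg["PresentSelf-Queen"], agg["PresentSelf-PastSelf"])
})
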