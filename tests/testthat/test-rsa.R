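test_that("lower triangle has m(m-1)/2 entries", {
  expect_length(lower_tri(diag(4)), 6)
  expect_length(lower_tri(diag(8)), 28)
})

test_that("condition similarity matrices are Pearson correlations of averages", {
  # 3-voxel toy: opposite patterns correlate at exactly -1
  x <- matrix(0, 16, 3)
  x[seq(1, 16, by = 8), ] <- rep(c(1, 2, 3), each = 2) # PresentSelf.Positive
  x[seq(2, 16, by = 8), ] <- rep(c(3, 2, 1), each = 2) # PresentSelf.Negative
  x[, 1] <- x[, 1] + 1e-8 * seq_len(16) # break zero variance elsewhere
  p <- patterns_from_matrix(x, n_runs = 2)
  r <- suppressWarnings(condition_rdm(p))
  expect_equal(dim(unclass(r)), c(8, 8))
  expect_equal(r["PresentSelf.Positive", "PresentSelf.Negative"], -1)
  expect_true(isSymmetric(unclass(r)))
  expect_equal(unname(diag(unclass(r))), rep(1, 8))

  # identical averaged patterns correlate at exactly 1
  y <- matrix(rep(c(5, 1, 4), times = 16), 16, 3, byrow = TRUE)
  p2 <- patterns_from_matrix(y, n_runs = 2)
  r2 <- condition_rdm(p2)
  expect_equal(r2["Mother.Positive", "Queen.Negative"], 1)

  # distance view is 1 - r with a zero diagonal
  d <- rdm_distance(r2)
  expect_equal(unname(diag(d)), rep(0, 8))
  expect_equal(d[1, 2], 1 - unclass(r2)[1, 2])
})

test_that("four-person matrices average the valence variants first", {
  set.seed(4)
  x <- matrix(rnorm(16 * 5), 16, 5)
  p <- patterns_from_matrix(x, n_runs = 2)
  r4 <- condition_rdm(p, "four_person")
  expect_equal(dim(unclass(r4)), c(4, 4))
  # oracle: average the 4 rows of each person (2 valences x 2 runs) by hand
  idx <- function(person) which(rep(condition_table()$person, 2) == person)
  avg <- t(vapply(persons(), function(pp) colMeans(x[idx(pp), ]), numeric(5)))
  expect_equal(unclass(r4), cor(t(avg)), ignore_attr = TRUE)
})

test_that("zero-variance patterns are flagged", {
  x <- matrix(1, 16, 3)
  p <- patterns_from_matrix(x, n_runs = 2)
  expect_warning(condition_rdm(p), "zero-variance")
})

test_that("tau-a and Spearman match brute-force enumeration", {
  expect_equal(kendall_tau_a(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_equal(kendall_tau_a(1:5, 1:5), 1)
  expect_equal(rank_correlation(1:4, 1:4, "spearman_rho"), 1)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- sample(c(rnorm(n), round(rnorm(n))), n) # sometimes tied
    expect_equal(kendall_tau_a(x, y), brute_tau_a(x, y))
    expect_equal(
      rank_correlation(x, y, "spearman_rho"),
      cor(rank(x), rank(y))
    )
  }
  # tie-free inputs: tau-a agrees with the tau implementation in base R
  set.seed(12)
  x <- rnorm(8)
  y <- rnorm(8)
  expect_equal(kendall_tau_a(x, y), cor(x, y, method = "kendall"))
  # with ties, tau-a keeps the full denominator (no tie correction)
  xt <- c(1, 1, 2, 3)
  yt <- c(1, 2, 3, 4)
  expect_equal(kendall_tau_a(xt, yt), 5 / 6)
  expect_warning(out <- rank_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
})

test_that("cross-valence consistency is exact without valence signal or noise", {
  p <- noise_free_patterns(geometry_params(d_valence = 0))
  pos <- condition_rdm(p, "four_person", valence = "Positive")
  neg <- condition_rdm(p, "four_person", valence = "Negative")
  # d_valence = 0, no noise: the two matrices are literally identical
  expect_equal(unclass(pos), unclass(neg))
  expect_equal(
    rank_correlation(lower_tri(pos), lower_tri(neg), "spearman_rho"), 1
  )
  # tau-a of a vector with itself reaches 1 only without ties; the
  # symmetric default geometry ties PresentSelf-PastSelf with Mother-Queen
  tau <- rank_correlation(lower_tri(pos), lower_tri(neg), "kendall_tau_a")
  expect_equal(tau, brute_tau_a(lower_tri(pos), lower_tri(pos)))
})

test_that("independent patterns across valence give near-zero consistency", {
  set.seed(30)
  coefs <- replicate(40, {
    x <- matrix(rnorm(32 * 12), 32, 12)
    p <- patterns_from_matrix(x, n_runs = 4)
    pos <- condition_rdm(p, "four_person", valence = "Positive")
    neg <- condition_rdm(p, "four_person", valence = "Negative")
    rank_correlation(lower_tri(pos), lower_tri(neg))
  })
  se <- sd(coefs) / sqrt(length(coefs))
  expect_lt(abs(mean(coefs)), 3 * se + 0.05)
})

test_that("cross-valence consistency holds in every ROI of the planted cohort", {
  cv <- cross_valence_consistency(rsa_cohort())
  expect_equal(nrow(cv$by_roi), 8)
  expect_true(all(cv$by_roi$mean_coefficient > 0))
  expect_true(all(cv$by_roi$p[cv$by_roi$network == "DN"] < 0.05))
})

test_that("noise ceiling brackets behave under shared-template structure", {
  template <- matrix(rnorm(16), 4, 4)
  template <- (template + t(template)) / 2
  diag(template) <- 1
  # identical subjects: lower = upper = 1
  nc <- noise_ceiling(rep(list(template), 5))
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)
  # template plus noise: lower <= upper in every simulation, both shrink
  # as noise grows
  set.seed(9)
  gaps <- replicate(30, {
    make <- function(sd) {
      lapply(1:6, function(i) {
        n <- matrix(rnorm(16, sd = sd), 4, 4)
        m <- template + (n + t(n)) / 2
        diag(m) <- 1
        m
      })
    }
    lo <- noise_ceiling(make(0.3))
    hi <- noise_ceiling(make(2))
    c(lo$lower <= lo$upper + 1e-9, hi$lower <= hi$upper + 1e-9,
      lo$lower, hi$lower)
  })
  expect_true(all(gaps[1, ] == 1))
  expect_true(all(gaps[2, ] == 1))
  expect_gt(mean(gaps[3, ]), mean(gaps[4, ]))
  expect_error(noise_ceiling(rep(list(template), 2)), ">= 3")
})

test_that("average linkage matches the brute-force agglomeration oracle", {
  # the trivial pair with distance 0 merges first
  d0 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tr0 <- hierarchical_clustering(d0)
  expect_equal(sort(tr0$hclust$merge[1, ]), c(-2, -1))
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    m <- matrix(runif(n * n, 0.1, 2), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tree <- hierarchical_clustering(m, "average")
    oracle <- brute_average_linkage(m)
    expect_equal(tree$hclust$height, oracle$height)
    # same partition at every merge step (row order of pairs may differ)
    expect_equal(
      apply(abs(tree$hclust$merge), 1, sort),
      apply(abs(oracle$merge), 1, sort)
    )
  }
  expect_error(
    hierarchical_clustering(matrix(c(0, 1, 2, 0), 2)),
    "symmetric"
  )
})

test_that("merge heights are non-decreasing and newick export keeps leaves", {
  set.seed(15)
  m <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(m) <- list(LETTERS[1:6], LETTERS[1:6])
  tree <- hierarchical_clustering(m)
  expect_true(all(diff(tree$hclust$height) >= -1e-12))
  nwk <- as_newick(tree)
  for (l in LETTERS[1:6]) expect_match(nwk, l)
  expect_equal(length(cut_clusters(tree, 3)), 6)
})

test_that("model RDMs encode binary, graded and behavioral structure", {
  b <- model_rdm("binary")
  expect_equal(b["PresentSelf", "PastSelf"], 0)
  expect_equal(b["PastSelf", "Mother"], 1)
  expect_equal(b["Mother", "Queen"], 0)
  g <- model_rdm("graded")
  expect_equal(
    g["PresentSelf", "Queen"],
    3 * g["PresentSelf", "PastSelf"]
  )
  expect_true(isSymmetric(unclass(g)))
  ratings <- tibble::tibble(
    subject = "s1",
    person_a = factor(c("PresentSelf", "PresentSelf", "PresentSelf", "PastSelf", "PastSelf", "Mother"), levels = persons()),
    person_b = factor(c("PastSelf", "Mother", "Queen", "Mother", "Queen", "Queen"), levels = persons()),
    pair = person_pairs()$pair,
    rating = c(80, 60, 0, 50, 10, 20)
  )
  m <- model_rdm("behavioral", ratings)
  expect_equal(m["PresentSelf", "PastSelf"], 0.2)
  expect_equal(m["PresentSelf", "Queen"], 1)
  flat <- ratings
  flat$rating <- 50
  expect_warning(mf <- model_rdm("behavioral", flat), "zero variance")
  expect_true(attr(mf, "degenerate"))
  expect_error(model_rdm("behavioral"), "requires ratings")
})

test_that("a model correlates perfectly with data generated from it", {
  # binary-structured geometry, no noise: neural person distances are a
  # monotone transform of the binary model
  p <- noise_free_patterns(geometry_params(d_self_other = 2, d_distance = 0))
  neural <- rdm_distance(condition_rdm(p, "four_person"))
  expect_equal(
    rank_correlation(
      lower_tri(neural), lower_tri(unclass(model_rdm("binary"))),
      "spearman_rho"
    ),
    1
  )
})

test_that("model comparison recovers the planted binary-plus-graded landscape", {
  co <- rsa_cohort()
  spec <- cohort_spec(n_subjects = 6, rois = default_rois(n_voxels = 30L))
  ratings <- simulate_behavioral_ratings(spec, seed = 77)
  mc <- model_comparison(co,
    models = c("binary", "graded", "behavioral"),
    ratings = ratings
  )
  expect_true(all(mc$by_roi$p[mc$by_roi$model == "binary"] < 0.05))
  expect_true(all(mc$by_roi$p[mc$by_roi$model == "graded"] < 0.05))
  expect_lte(mc$noise_ceiling$lower, mc$noise_ceiling$upper)
  expect_equal(nrow(mc$contrasts), 3)
  bincon <- mc$contrasts[mc$contrasts$model_a == "binary" &
    mc$contrasts$model_b == "behavioral", ]
  expect_gt(bincon$mean_difference, 0)
})

test_that("second-order region similarity clusters regions by structure", {
  # regions with literally identical patterns have identical matrices, so
  # all off-diagonal second-order coefficients are exactly 1
  one <- dplyr::filter(small_cohort(), roi == "PCC")
  dup <- dplyr::bind_rows(
    one,
    dplyr::mutate(one, roi = "copy1"),
    dplyr::mutate(one, roi = "copy2", network = factor("SN"))
  )
  rs <- second_order_region_similarity(dup)
  expect_equal(unname(lower_tri(rs$similarity)), rep(1, 3))

  # two region groups built from distinct templates + noise separate
  rs2 <- second_order_region_similarity(small_cohort())
  sim <- rs2$similarity
  nets <- rs2$networks
  within <- c(
    lower_tri(sim[nets == "DN", nets == "DN"]),
    lower_tri(sim[nets == "SN", nets == "SN"])
  )
  between <- as.vector(sim[nets == "DN", nets == "SN"])
  expect_gt(mean(within), mean(between))
  expect_s3_class(rs2$tree, "mvpa_dendrogram")
})

test_that("network membership drives similarity; valence does not", {
  wb <- within_between_network_effect(rsa_cohort())
  for (meth in c("kendall_tau_a", "spearman_rho")) {
    a <- wb$anova[[meth]]
    expect_lt(a$p[a$factor == "membership"], 0.05)
    expect_gt(a$p[a$factor == "valence"], 0.05)
    expect_true(all(a$pes >= 0 & a$pes <= 1))
  }
  cm <- wb$cell_means
  agg <- tapply(cm$similarity, cm$membership, mean)
  expect_gt(agg["within"], agg["between"])
})

test_that("similar condition pairs are harder to decode (negative concordance)", {
  cell <- dplyr::filter(small_cohort(), subject == "sub02", roi == "PCC")
  conc <- similarity_accuracy_concordance(cell)
  expect_equal(nrow(conc), 2)
  expect_true(all(conc$coefficient < 0))
  # constant accuracies are flagged undefined: noise-free, fully separable
  p <- noise_free_patterns(geometry_params(d_self_other = 4, d_distance = 2))
  w <- capture_warnings(conc0 <- similarity_accuracy_concordance(p))
  expect_true(any(grepl("constant", w))) # one flag per valence context
  expect_true(all(is.na(conc0$coefficient)))
})
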