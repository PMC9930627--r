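test_that("condition set spans the 4 x 2 factorial design", {
  ct <- condition_table()
  expect_equal(nrow(ct), 8)
  expect_equal(length(unique(ct$condition)), 8)
  expect_equal(sort(unique(ct$position)), 0:3)
  expect_equal(ct$position[ct$person == "Queen"], c(3L, 3L))
})

test_that("latent geometry realizes the configured separations", {
  # null geometry: 8 identical zero vectors
  mu0 <- build_geometry(null_geometry())
  expect_true(all(mu0 == 0))
  expect_equal(dim(mu0), c(8L, 6L))

  # direct arithmetic on the returned coordinates
  mu <- build_geometry(geometry_params(
    d_self_other = 2, d_distance = 1,
    d_valence = 0
  ))
  d <- as.matrix(dist(mu))
  ps <- "PresentSelf.Positive"
  expect_equal(d[ps, "PastSelf.Positive"], 1) # within-domain
  expect_equal(d[ps, "Mother.Positive"], 2) # between-domain, near
  expect_equal(d[ps, "Queen.Positive"], sqrt(2^2 + 1^2)) # between, far
  expect_gt(d[ps, "Queen.Positive"], d[ps, "PastSelf.Positive"])

  # valence separation on its own axis
  muv <- build_geometry(geometry_params(d_valence = 0.5))
  expect_equal(
    as.numeric(dist(muv[c("Mother.Positive", "Mother.Negative"), ])), 0.5
  )
})

test_that("geometry recovery: between-domain beats within-domain distances", {
  for (seed in 1:3) {
    params <- geometry_params(
      d_self_other = 1 + seed, d_distance = 1,
      seed = seed
    )
    d <- as.matrix(dist(build_geometry(params)))
    within <- c(
      d["PresentSelf.Positive", "PastSelf.Positive"],
      d["Mother.Positive", "Queen.Positive"]
    )
    between <- c(
      d["PresentSelf.Positive", "Mother.Positive"],
      d["PastSelf.Positive", "Queen.Positive"]
    )
    expect_true(all(between > max(within)))
  }
})

test_that("geometry parameter validation rejects bad configurations", {
  expect_error(geometry_params(d_self_other = -1), "separations")
  expect_error(geometry_params(latent_dim = 1), "latent_dim")
  expect_error(
    geometry_params(d_self_other = 1, d_distance = 1, d_valence = 1, latent_dim = 2),
    "cannot embed"
  )
  expect_error(roi_spec("x", "DN", n_voxels = 0), "positive")
  expect_error(
    simulate_roi_patterns(geometry_params(), roi_spec("x", "DN"), n_runs = 1),
    "n_runs"
  )
})

test_that("ROI simulation yields 64 beta vectors over 8 runs, reproducibly", {
  roi <- roi_spec("PCC", "DN", n_voxels = 25L)
  p1 <- simulate_roi_patterns(geometry_params(), roi, n_runs = 8, seed = 11)
  expect_equal(nrow(p1), 64)
  expect_equal(length(grep("^voxel_", names(p1))), 25)
  expect_equal(nrow(dplyr::distinct(p1[, c("person", "valence", "run")])), 64)
  # bit-identical under the same seed
  p2 <- simulate_roi_patterns(geometry_params(), roi, n_runs = 8, seed = 11)
  expect_identical(p1, p2)
  p3 <- simulate_roi_patterns(geometry_params(), roi, n_runs = 8, seed = 12)
  expect_false(identical(p1, p3))
})

test_that("noise-free patterns repeat exactly across runs and decode perfectly", {
  roi <- roi_spec("t", "DN",
    n_voxels = 20, info_scale = 1,
    noise_sd_run = 0, noise_sd_voxel = 0
  )
  p <- simulate_roi_patterns(geometry_params(), roi, n_runs = 8, seed = 5)
  vox <- grep("^voxel_", names(p))
  r1 <- p[p$run == 1, ]
  for (r in 2:8) {
    rr <- p[p$run == r, ]
    expect_equal(as.matrix(rr[, vox]), as.matrix(r1[, vox]))
  }
  expect_equal(cross_validate(p, make_scheme("self_vs_other"))$accuracy, 1)
})

test_that("cohort simulation is deterministic with the study's structure", {
  spec <- cohort_spec(
    n_subjects = 3, n_runs = 8,
    rois = default_rois(n_voxels = 15L),
    geometry = geometry_params(seed = 9)
  )
  co1 <- simulate_cohort(spec)
  expect_equal(length(unique(co1$subject)), 3)
  expect_equal(length(unique(co1$roi)), 8)
  expect_equal(sum(co1$subject == "sub01" & co1$roi == "PCC"), 64)
  expect_setequal(unique(co1$network), c("DN", "SN"))
  expect_equal(sum(co1$network == "DN") / 64 / 3, 5) # 5 DN ROIs
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
})

test_that("DN carries more 4-way information than SN in the planted cohort", {
  acc <- decode_cohort(small_cohort(),
    schemes = "four_way",
    keep_fits = FALSE
  )
  means <- tapply(acc$accuracy, acc$network, mean)
  expect_gt(means["DN"], means["SN"])
})

test_that("behavioral ratings respect the scale and configured pattern", {
  spec <- cohort_spec(n_subjects = 12, rois = default_rois(n_voxels = 10L))
  r <- simulate_behavioral_ratings(spec, rating_sd = 15, seed = 3)
  expect_true(all(r$rating >= 0 & r$rating <= 100))
  expect_equal(nrow(r), 12 * 6)
  means <- tapply(r$rating, r$pair, mean)
  expect_gt(means["PresentSelf-Mother"], means["PresentSelf-Queen"])
  expect_gt(means["PresentSelf-Mother"], means["PresentSelf-PastSelf"])
  # sd = 0 reproduces the configured means exactly
  r0 <- simulate_behavioral_ratings(spec, rating_sd = 0, seed = 3)
  expect_equal(
    as.numeric(tapply(r0$rating, r0$pair, mean)[names(default_rating_means())]),
    unname(default_rating_means())
  )
  m <- rating_matrix(r0[r0$subject == "sub01", ])
  expect_true(isSymmetric(m))
  expect_equal(m["PresentSelf", "Mother"], 78)
  expect_error(simulate_behavioral_ratings(spec, rating_sd = -1), "rating_sd")
})

test_that("planted volumes confine signal to in-mask sphere voxels", {
  dim3 <- c(8L, 8L, 8L)
  mask <- array(TRUE, dim3)
  mask[1:2, , ] <- FALSE
  vol <- simulate_brain_volume(
    dim = dim3, voxel_size_mm = 3, mask = mask,
    spheres = data.frame(x = 5, y = 4, z = 4, radius_mm = 4),
    geometry = geometry_params(d_self_other = 5),
    info_scale = 3, n_runs = 4, seed = 2
  )
  expect_equal(dim(vol$betas), c(dim3, 32L))
  expect_equal(vol$truth_centers, matrix(c(5L, 4L, 4L), 1))
  # out-of-mask voxels carry nothing at all
  out_mask <- vol$betas[1:2, , , ]
  expect_true(all(out_mask == 0))
  expect_error(
    simulate_brain_volume(
      dim = dim3,
      spheres = data.frame(x = 20, y = 4, z = 4, radius_mm = 3)
    ),
    "outside the grid"
  )
})

test_that("cohort round-trips through the CSV + manifest format", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(
    dplyr::arrange(
      tibble::as_tibble(back),
      subject, roi, run, person, valence
    ),
    dplyr::arrange(
      tibble::as_tibble(co),
      subject, roi, run, person, valence
    ),
    ignore_attr = TRUE,
    tolerance = 1e-12
  )
  sp <- attr(back, "spec")
  expect_s3_class(sp, "cohort_spec")
  expect_equal(sp$n_subjects, 5L)
})

test_that("volumes round-trip through NIfTI", {
  vol <- simulate_brain_volume(
    dim = c(6, 6, 6),
    spheres = data.frame(x = 3, y = 3, z = 3, radius_mm = 3),
    n_runs = 3, seed = 4
  )
  dir <- withr::local_tempdir()
  write_volume(vol, dir)
  back <- read_volume(dir)
  expect_equal(back$betas, vol$betas, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$mask, vol$mask, ignore_attr = TRUE)
  expect_equal(back$truth_centers, vol$truth_centers)
  expect_equal(back$conditions$person, vol$conditions$person)
})
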