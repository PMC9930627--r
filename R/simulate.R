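#' Generative parameters of the representational geometry
#'
#' The synthetic cohort plants a low-dimensional latent geometry over the
#' eight conditions: a principal bipartite axis separating the aggregate self
#' (`PresentSelf`, `PastSelf`) from the aggregate other (`Mother`, `Queen`),
#' a nested social-distance (near/far) axis shared across the two domains
#' (`PresentSelf`/`Mother` near, `PastSelf`/`Queen` far), and an optional
#' valence axis. Separations are in arbitrary beta units; voxel noise has
#' unit scale by default, so a separation of 2 corresponds to a
#' whole-pattern discriminability of about 2 noise SDs.
#'
#' Setting all three separations to zero defines the null, signal-free
#' geometry used for chance calibration.
#'
#' @param d_self_other Distance between the self and other centroids.
#' @param d_distance Distance between the near and far person within each
#'   domain (must not exceed `d_self_other` for the nested default geometry,
#'   though this is not enforced).
#' @param d_valence Distance between the positive and negative variant of
#'   the same person (0 = valence-invariant identity coding, the default).
#' @param latent_dim Number of latent axes (>= 2; >= 3 when all three
#'   separations are nonzero).
#' @param seed Integer seed consumed by downstream simulation.
#' @return A list of class `geometry_params`.
#' @export
geometry_params <- function(d_self_other = 2, d_distance = 1, d_valence = 0,
                            latent_dim = 6L, seed = 1L) {
  if (any(c(d_self_other, d_distance, d_valence) < 0)) {
    stop("separations must be >= 0", call. = FALSE)
  }
  if (latent_dim < 2) stop("latent_dim must be >= 2", call. = FALSE)
  n_axes <- sum(c(d_self_other, d_distance, d_valence) > 0)
  if (latent_dim < n_axes) {
    stop(
      "latent_dim = ", latent_dim, " cannot embed ", n_axes,
      " nonzero separations",
      call. = FALSE
    )
  }
  structure(
    list(
      d_self_other = d_self_other, d_distance = d_distance,
      d_valence = d_valence, latent_dim = as.integer(latent_dim),
      seed = as.integer(seed)
    ),
    class = "geometry_params"
  )
}

#' @rdname geometry_params
#' @export
null_geometry <- function(latent_dim = 6L, seed = 1L) {
  geometry_params(0, 0, 0, latent_dim = latent_dim, seed = seed)
}

#' Latent condition means implied by a geometry
#'
#' Places the eight condition means in the latent space: axis 1 codes
#' self/other, axis 2 codes near/far social distance (shared across the two
#' domains so that distance information generalizes from the self pair to
#' the other pair), axis 3 codes valence; remaining axes are zero.
#'
#' @param params A [geometry_params()] object.
#' @return An 8 x `latent_dim` matrix of condition means, with rownames
#'   `person.valence` in the order of [condition_table()].
#' @examples
#' mu <- build_geometry(geometry_params(d_self_other = 2, d_distance = 1))
#' dist(mu[c("PresentSelf.Positive", "Queen.Positive"), ])
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  conds <- condition_table()
  mu <- matrix(0, nrow = 8L, ncol = params$latent_dim,
    dimnames = list(conds$condition, NULL)
  )
  other <- conds$person %in% c("Mother", "Queen")
  far <- conds$person %in% c("PastSelf", "Queen")
  negative <- conds$valence == "Negative"
  mu[, 1L] <- ifelse(other, +0.5, -0.5) * params$d_self_other
  mu[, 2L] <- ifelse(far, +0.5, -0.5) * params$d_distance
  if (params$latent_dim >= 3L) {
    mu[, 3L] <- ifelse(negative, +0.5, -0.5) * params$d_valence
  } else if (params$d_valence > 0) {
    # latent_dim 2 with all three separations > 0 is rejected upstream;
    # here d_valence > 0 can only coexist with a zero separation, so fold
    # valence onto whichever axis is free.
    free <- which(c(params$d_self_other, params$d_distance) == 0)[1]
    mu[, free] <- ifelse(negative, +0.5, -0.5) * params$d_valence
  }
  mu
}

#' Region-of-interest specification
#'
#' @param name ROI label.
#' @param network Network membership: `"DN"` (default-mode), `"SN"`
#'   (semantic) or `"control"`.
#' @param n_voxels Number of voxels (> 0).
#' @param info_scale Multiplier applied to all condition separations; 0
#'   makes the ROI signal-free regardless of geometry.
#' @param noise_sd_run SD of the run-level additive offset (shared by all
#'   conditions within a run).
#' @param noise_sd_voxel SD of independent voxel-level noise.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(name, network = c("DN", "SN", "control"),
                     n_voxels = 80L, info_scale = 1,
                     noise_sd_run = 0.5, noise_sd_voxel = 1) {
  network <- match.arg(network)
  if (n_voxels < 1) stop("n_voxels must be positive", call. = FALSE)
  if (info_scale < 0) stop("info_scale must be >= 0", call. = FALSE)
  if (noise_sd_run < 0 || noise_sd_voxel < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(
      name = name, network = network, n_voxels = as.integer(n_voxels),
      info_scale = info_scale, noise_sd_run = noise_sd_run,
      noise_sd_voxel = noise_sd_voxel
    ),
    class = "roi_spec"
  )
}

#' Default eight-ROI set
#'
#' Five default-network regions (dmPFC, vmPFC, PCC, left/right IPL) and
#' three semantic-network regions (left/right ATL, left IFG). DN regions
#' carry twice the information scale of SN regions, planting the
#' DN-over-SN asymmetry that the decoding, combinatorial and RSA stages are
#' expected to recover. All ROIs share the same voxel count so that
#' combinatorial joint patterns are exactly dimension-matched.
#'
#' @param n_voxels Voxel count shared by all ROIs.
#' @param info_dn,info_sn Information scale for DN and SN regions.
#' @param noise_sd_run,noise_sd_voxel Noise SDs passed to [roi_spec()].
#' @return A list of eight `roi_spec` objects.
#' @export
default_rois <- function(n_voxels = 80L, info_dn = 2, info_sn = 1,
                         noise_sd_run = 0.5, noise_sd_voxel = 1) {
  dn <- c("dmPFC", "vmPFC", "PCC", "lIPL", "rIPL")
  sn <- c("lATL", "rATL", "lIFG")
  c(
    lapply(dn, roi_spec,
      network = "DN", n_voxels = n_voxels, info_scale = info_dn,
      noise_sd_run = noise_sd_run, noise_sd_voxel = noise_sd_voxel
    ),
    lapply(sn, roi_spec,
      network = "SN", n_voxels = n_voxels, info_scale = info_sn,
      noise_sd_run = noise_sd_run, noise_sd_voxel = noise_sd_voxel
    )
  )
}

#' Cohort specification
#'
#' Defaults reproduce the study structure: 24 subjects, 8 runs, 8 ROIs
#' (5 DN + 3 SN).
#'
#' @param n_subjects,n_runs Positive integers.
#' @param rois List of [roi_spec()] objects.
#' @param geometry A [geometry_params()] object.
#' @param subject_jitter_sd SD of the per-subject Gaussian jitter applied to
#'   the latent condition means, so subjects share structure but differ in
#'   detail (nondegenerate noise ceilings). Default 10% of `d_self_other`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 24L, n_runs = 8L, rois = default_rois(),
                        geometry = geometry_params(),
                        subject_jitter_sd = 0.1 * geometry$d_self_other) {
  if (n_subjects < 1 || n_runs < 2) {
    stop("need n_subjects >= 1 and n_runs >= 2", call. = FALSE)
  }
  stopifnot(all(vapply(rois, inherits, logical(1), "roi_spec")))
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
      rois = rois, geometry = geometry, subject_jitter_sd = subject_jitter_sd
    ),
    class = "cohort_spec"
  )
}

# Draw an n_voxels x latent_dim loading matrix with (near-)orthonormal,
# zero-mean columns: latent separations survive the embedding unchanged up
# to info_scale, and every embedded signal has zero spatial mean, so the
# cohort is amplitude-matched across conditions by construction (pattern
# information without univariate differences). Falls back to normalized
# Gaussian columns when the voxel count is below the latent dimension.
embedding_matrix <- function(n_voxels, latent_dim) {
  raw <- matrix(stats::rnorm(n_voxels * latent_dim), n_voxels, latent_dim)
  if (n_voxels > latent_dim) {
    raw <- sweep(raw, 2, colMeans(raw)) # span excludes the constant vector
    qr.Q(qr(raw))
  } else {
    sweep(raw, 2, sqrt(colSums(raw^2)), "/")
  }
}

#' Simulate condition-by-run beta patterns for one ROI
#'
#' Each (condition, run) beta vector is a random near-orthonormal linear
#' embedding of the latent condition mean into voxel space, scaled by the
#' ROI's `info_scale`, plus a run-level offset (shared by the 8 conditions
#' of a run) and independent voxel-level Gaussian noise. This emulates GLM
#' beta estimates per regressor per run; with 8 runs an ROI yields 64 beta
#' vectors.
#'
#' @param geometry Either a [geometry_params()] object or an 8 x d latent
#'   mean matrix as returned by [build_geometry()].
#' @param roi A [roi_spec()].
#' @param n_runs Number of runs (>= 2).
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return A tibble with columns `person`, `valence`, `run` and
#'   `voxel_1` ... `voxel_V`.
#' @export
simulate_roi_patterns <- function(geometry, roi, n_runs = 8L, seed = 1L) {
  if (inherits(geometry, "geometry_params")) geometry <- build_geometry(geometry)
  stopifnot(is.matrix(geometry), nrow(geometry) == 8L)
  stopifnot(inherits(roi, "roi_spec"))
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  set.seed(seed)
  v <- roi$n_voxels
  loading <- embedding_matrix(v, ncol(geometry))
  means_vox <- roi$info_scale * (geometry %*% t(loading)) # 8 x V
  rows <- vector("list", n_runs)
  conds <- condition_table()
  for (r in seq_len(n_runs)) {
    run_offset <- stats::rnorm(v, sd = roi$noise_sd_run)
    noise <- matrix(stats::rnorm(8L * v, sd = roi$noise_sd_voxel), 8L, v)
    rows[[r]] <- sweep(means_vox + noise, 2, run_offset, "+")
  }
  x <- do.call(rbind, rows)
  colnames(x) <- paste0("voxel_", seq_len(v))
  out <- tidyr::expand_grid(run = seq_len(n_runs), idx = 1:8)
  out <- dplyr::bind_cols(
    tibble::tibble(
      person = conds$person[out$idx],
      valence = conds$valence[out$idx],
      run = out$run
    ),
    tibble::as_tibble(x)
  )
  out
}

#' Simulate a full cohort of beta patterns
#'
#' Draws per-subject jittered latent condition means (shared by all of the
#' subject's ROIs) and simulates each ROI with its own random voxel
#' embedding and noise. Fully reproducible from `spec$geometry$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `mvpa_cohort` with columns `subject`, `roi`,
#'   `network`, `person`, `valence`, `run`, `voxel_*`; the spec is attached
#'   as attribute `"spec"`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$geometry$seed)
  mu <- build_geometry(spec$geometry)
  n_cells <- spec$n_subjects * length(spec$rois)
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, n_cells),
    nrow = spec$n_subjects
  )
  jitters <- lapply(seq_len(spec$n_subjects), function(s) {
    matrix(stats::rnorm(length(mu), sd = spec$subject_jitter_sd),
      nrow = nrow(mu)
    )
  })
  pieces <- vector("list", n_cells)
  k <- 1L
  for (s in seq_len(spec$n_subjects)) {
    mu_s <- mu + jitters[[s]]
    for (r in seq_along(spec$rois)) {
      rs <- spec$rois[[r]]
      pat <- simulate_roi_patterns(mu_s, rs, spec$n_runs,
        seed = sub_seeds[s, r]
      )
      pieces[[k]] <- dplyr::bind_cols(
        tibble::tibble(
          subject = sprintf("sub%02d", s),
          roi = rs$name, network = rs$network
        )[rep(1L, nrow(pat)), ],
        pat
      )
      k <- k + 1L
    }
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "spec") <- spec
  class(out) <- c("mvpa_cohort", class(out))
  out
}

#' Default pairwise similarity-rating means
#'
#' Qualitative reconstruction of the reported behavioral pattern: the mother
#' is rated close to the self (more similar to the present self than the
#' past self is), the Queen is distant from everyone, so the three
#' personally familiar targets cluster apart from the Queen.
#'
#' @return A named numeric vector over the six unordered person pairs, on
#'   the 0 (most dissimilar) to 100 (most similar) scale.
#' @export
default_rating_means <- function() {
  c(
    "PresentSelf-PastSelf" = 70, "PresentSelf-Mother" = 78,
    "PresentSelf-Queen" = 15, "PastSelf-Mother" = 65,
    "PastSelf-Queen" = 20, "Mother-Queen" = 25
  )
}

#' Simulate behavioral similarity ratings
#'
#' Per subject, draws one rating per unordered person pair around the
#' configured means and clips to the 0-100 scale.
#'
#' @param spec A [cohort_spec()] (only `n_subjects` is used).
#' @param rating_means Named vector over the six pairs (see
#'   [default_rating_means()] for the naming).
#' @param rating_sd Gaussian SD of ratings around their means (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `subject`, `person_a`, `person_b`, `pair`,
#'   `rating`.
#' @export
simulate_behavioral_ratings <- function(spec,
                                        rating_means = default_rating_means(),
                                        rating_sd = 10, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (rating_sd < 0) stop("rating_sd must be >= 0", call. = FALSE)
  pairs <- person_pairs()
  if (!setequal(names(rating_means), pairs$pair)) {
    stop("rating_means must be named over the six person pairs", call. = FALSE)
  }
  if (any(rating_means < 0 | rating_means > 100)) {
    stop("rating_means must lie in [0, 100]", call. = FALSE)
  }
  set.seed(seed)
  out <- tidyr::expand_grid(
    subject = sprintf("sub%02d", seq_len(spec$n_subjects)),
    pair = pairs$pair
  )
  out <- dplyr::left_join(out, pairs, by = "pair")
  out$rating <- pmin(100, pmax(0, rating_means[out$pair] +
    stats::rnorm(nrow(out), sd = rating_sd)))
  out[, c("subject", "person_a", "person_b", "pair", "rating")]
}

#' Expand per-pair ratings into a symmetric 4 x 4 rating matrix
#'
#' @param ratings Output of [simulate_behavioral_ratings()], filtered to one
#'   subject (or averaged over subjects beforehand).
#' @return A symmetric 4 x 4 matrix (diagonal 100) over the four persons.
#' @export
rating_matrix <- function(ratings) {
  p <- persons()
  m <- matrix(100, 4, 4, dimnames = list(p, p))
  for (i in seq_len(nrow(ratings))) {
    a <- as.character(ratings$person_a[i])
    b <- as.character(ratings$person_b[i])
    m[a, b] <- m[b, a] <- ratings$rating[i]
  }
  m
}
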