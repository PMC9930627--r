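# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small planted cohort for unit tests: 5 subjects, 4 ROIs (2 DN + 2 SN),
# 30 voxels, default geometry.
small_cohort <- function() {
  cached("small_cohort", function() {
    rois <- c(
      lapply(c("PCC", "vmPFC"), roi_spec,
        network = "DN", n_voxels = 30L,
        info_scale = 2
      ),
      lapply(c("lATL", "lIFG"), roi_spec,
        network = "SN", n_voxels = 30L,
        info_scale = 1
      )
    )
    simulate_cohort(cohort_spec(
      n_subjects = 5L, n_runs = 8L, rois = rois,
      geometry = geometry_params(seed = 42L)
    ))
  })
}

# Mid-sized cohort with the full 8-ROI layout, for the RSA group analyses
# (network structure needs all five DN and three SN regions).
rsa_cohort <- function() {
  cached("rsa_cohort", function() {
    simulate_cohort(cohort_spec(
      n_subjects = 6L, n_runs = 8L,
      rois = default_rois(n_voxels = 30L),
      geometry = geometry_params(seed = 7L)
    ))
  })
}

# Full-scale default cohort shared by the planted-structure acceptance
# checks (24 subjects, 8 ROIs, 80 voxels).
default_cohort <- function() {
  cached("default_cohort", function() {
    simulate_cohort(cohort_spec(geometry = geometry_params(seed = 20260101L)))
  })
}

default_cohort_decoding <- function() {
  cached("default_cohort_decoding", function() {
    decode_cohort(default_cohort(), keep_fits = TRUE)
  })
}

# Build a pattern tibble from an explicit matrix whose rows follow
# condition_table() order within each run (8 conditions x n_runs rows).
patterns_from_matrix <- function(x, n_runs) {
  stopifnot(nrow(x) == 8 * n_runs)
  conds <- condition_table()
  idx <- rep(1:8, times = n_runs)
  colnames(x) <- paste0("voxel_", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(
      person = conds$person[idx],
      valence = conds$valence[idx],
      run = rep(seq_len(n_runs), each = 8)
    ),
    tibble::as_tibble(x)
  )
}

# Noise-free patterns realizing a latent geometry directly (identity
# embedding into latent_dim voxels), repeated across runs.
noise_free_patterns <- function(params = geometry_params(), n_runs = 8) {
  mu <- build_geometry(params)
  patterns_from_matrix(
    mu[rep(1:8, times = n_runs), , drop = FALSE], n_runs
  )
}

# Brute-force average-linkage agglomeration used as clustering oracle.
brute_average_linkage <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(seq_len(nrow(d)))
  active <- rep(TRUE, nrow(d))
  ids <- -seq_len(nrow(d)) # hclust convention: negatives are leaves
  merges <- NULL
  heights <- c()
  next_id <- 1L
  cluster_dist <- function(a, b) {
    mean(d[a, b, drop = FALSE])
  }
  while (sum(active) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    act <- which(active)
    for (i in act) {
      for (j in act) {
        if (i >= j) next
        h <- cluster_dist(clusters[[i]], clusters[[j]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    merges <- rbind(merges, c(ids[best[1]], ids[best[2]]))
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
    ids[best[1]] <- next_id
    next_id <- next_id + 1L
  }
  list(merge = merges, height = heights)
}

# Exact signed-rank p by full enumeration (oracle).
brute_signed_rank_p <- function(d, tail = "one") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  if (tail == "one") {
    mean(v_all >= v)
  } else {
    mu <- n * (n + 1) / 4
    mean(abs(v_all - mu) >= abs(v - mu) - 1e-12)
  }
}

# Kendall tau-a by explicit pair enumeration (oracle).
brute_tau_a <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (n * (n - 1) / 2)
}
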