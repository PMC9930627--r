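#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for decoding results
#'
#' `tidy()` returns per-fold rows; `glance()` a one-row summary.
#'
#' @param x An `mvpa_accuracy`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mvpa_accuracy
#' @export
tidy.mvpa_accuracy <- function(x, ...) {
  out <- x$per_fold
  out$scheme <- x$scheme
  out$chance <- x$chance
  out
}

#' @rdname tidy.mvpa_accuracy
#' @method glance mvpa_accuracy
#' @export
glance.mvpa_accuracy <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, mode = x$mode, accuracy = x$accuracy,
    chance = x$chance, n_folds = x$n_folds
  )
}

#' Tidy a statistical test result
#'
#' @param x An `mvpa_test`.
#' @param ... Unused.
#' @return A one-row tibble with statistic, df, p, tail, estimate, the
#'   Bonferroni-corrected alpha and significance flag, and the degenerate
#'   flag.
#' @method tidy mvpa_test
#' @export
tidy.mvpa_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, df = x$df, p = x$p,
    tail = x$tail, estimate = x$estimate,
    alpha_corrected = x$alpha_corrected,
    significant_bonferroni = x$significant_bonferroni,
    degenerate = x$degenerate
  )
}

#' Tidy a combinatorial delta matrix
#'
#' @param x A `joint_delta`.
#' @param ... Unused.
#' @return A tibble with one row per ordered ROI pair: `subject`,
#'   `original`, `added`, `original_network`, `added_network`, `baseline`
#'   (of the original ROI) and `delta`.
#' @method tidy joint_delta
#' @export
tidy.joint_delta <- function(x, ...) {
  rois <- rownames(x$delta)
  grid <- expand.grid(original = rois, added = rois, stringsAsFactors = FALSE)
  grid <- grid[grid$original != grid$added, ]
  tibble::tibble(
    subject = x$subject, scheme = x$scheme,
    original = grid$original, added = grid$added,
    original_network = unname(x$networks[grid$original]),
    added_network = unname(x$networks[grid$added]),
    baseline = unname(x$baseline[grid$original]),
    delta = x$delta[cbind(grid$original, grid$added)]
  )
}

#' Tidy a similarity or model matrix into long pair form
#'
#' @param x A `similarity_matrix` or `model_rdm`.
#' @param ... Unused.
#' @return A tibble of the lower-triangle pairs: `item_a`, `item_b`,
#'   `value`.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    item_a = rownames(m)[idx[, 1]], item_b = colnames(m)[idx[, 2]],
    value = m[idx]
  )
}

#' @rdname tidy.similarity_matrix
#' @method tidy model_rdm
#' @export
tidy.model_rdm <- tidy.similarity_matrix

#' @method tidy mvpa_dendrogram
#' @export
tidy.mvpa_dendrogram <- function(x, ...) x$merges

#' @method tidy noise_ceiling
#' @export
tidy.noise_ceiling <- function(x, ...) {
  tibble::tibble(lower = x$lower, upper = x$upper)
}

#' @method glance mvpa_group_map
#' @export
glance.mvpa_group_map <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, n_significant = sum(x$significant),
    n_permutations = x$n_permutations, chance = x$chance, alpha = x$alpha,
    n_undefined = sum(x$undefined)
  )
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf(
    "<noise_ceiling> lower = %.3f, upper = %.3f\n", x$lower, x$upper
  ))
  invisible(x)
}

#' @export
print.mvpa_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<mvpa_dendrogram> %d leaves, %s linkage\n",
    length(x$labels), x$linkage
  ))
  invisible(x)
}
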