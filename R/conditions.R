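#' Experimental condition labels
#'
#' The design crosses four person identities with two sides of emotive
#' valence, giving eight conditions. The person factor carries an ordinal
#' social-distance position relative to the present self: `PresentSelf` = 0,
#' `PastSelf` = 1, `Mother` = 2, `Queen` = 3.
#'
#' @return A tibble with one row per condition and columns `person`,
#'   `valence`, `position` (ordinal social distance of the person) and
#'   `condition` (a `person.valence` label).
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  grid <- tidyr::expand_grid(
    person = factor(persons(), levels = persons()),
    valence = factor(valences(), levels = valences())
  )
  dplyr::mutate(
    grid,
    position = as.integer(person) - 1L,
    condition = paste(person, valence, sep = ".")
  )
}

#' @rdname condition_table
#' @export
persons <- function() c("PresentSelf", "PastSelf", "Mother", "Queen")

#' @rdname condition_table
#' @export
valences <- function() c("Positive", "Negative")

# Unordered person pairs in canonical order (used by ratings and model RDMs)
person_pairs <- function() {
  p <- persons()
  idx <- utils::combn(4L, 2L)
  tibble::tibble(
    person_a = factor(p[idx[1, ]], levels = p),
    person_b = factor(p[idx[2, ]], levels = p),
    pair = paste(p[idx[1, ]], p[idx[2, ]], sep = "-")
  )
}

# Validate that a pattern tibble has the expected condition x run structure.
# Returns the (unique, sorted) run indices invisibly.
check_pattern_design <- function(patterns) {
  needed <- c("person", "valence", "run")
  missing <- setdiff(needed, names(patterns))
  if (length(missing) > 0) {
    stop("pattern data lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  runs <- sort(unique(patterns$run))
  counts <- dplyr::count(patterns, .data$person, .data$valence, .data$run)
  if (any(counts$n != 1L)) {
    stop("expected exactly one pattern per condition per run", call. = FALSE)
  }
  if (nrow(counts) != 8L * length(runs)) {
    stop("expected all 8 conditions in every run", call. = FALSE)
  }
  invisible(runs)
}

# Extract the voxel matrix (rows = condition-by-run examples) and the design
# (person, valence, run) from a pattern tibble in a fixed row order.
pattern_matrix <- function(patterns) {
  vox_cols <- grep("^voxel_", names(patterns), value = TRUE)
  if (length(vox_cols) == 0) {
    stop("no voxel_* columns found in pattern data", call. = FALSE)
  }
  ord <- order(patterns$run, patterns$person, patterns$valence)
  patterns <- patterns[ord, , drop = FALSE]
  list(
    x = as.matrix(patterns[, vox_cols, drop = FALSE]),
    design = patterns[, c("person", "valence", "run")]
  )
}
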