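#' The seven decoding schemes
#'
#' Declarative description of one decoding analysis: which conditions enter,
#' the class each condition maps to, whether it is run-wise cross-validation
#' or cross-classification across disjoint condition partitions, and the
#' nominal chance level (1 / number of classes).
#'
#' The seven named analyses are:
#' 1. `self_vs_other` — aggregate self (`PresentSelf`, `PastSelf`) vs
#'    aggregate other (`Mother`, `Queen`).
#' 2. `present_vs_past` — `PresentSelf` vs `PastSelf`.
#' 3. `mother_vs_queen` — `Mother` vs `Queen`.
#' 4. `four_way` — 4-way classification of the four persons.
#' 5. `xclass_self_other_across_distance` — self/other trained on the
#'    socially near pair (`PresentSelf` vs `Mother`), tested on the far pair
#'    (`PastSelf` vs `Queen`), and the reverse.
#' 6. `xclass_distance_across_domain` — near/far trained on the self pair
#'    (`PresentSelf` vs `PastSelf`), tested on the other pair
#'    (`Mother` vs `Queen`), and the reverse.
#' 7. `xclass_four_way_across_valence` — 4-way person classification trained
#'    on positive-valence conditions, tested on negative, and the reverse.
#'
#' @param name One of the seven scheme names above.
#' @return A list of class `decoding_scheme` with elements `name`, `mode`
#'   (`"cross_validation"` or `"cross_classification"`), `map` (a tibble
#'   mapping conditions to `class` and, for cross-classification, to a
#'   train/test `side`), `n_classes` and `chance`.
#' @examples
#' make_scheme("four_way")$chance
#' @export
make_scheme <- function(name) {
  conds <- condition_table()
  p <- as.character(conds$person)
  self <- ifelse(p %in% c("PresentSelf", "PastSelf"), "self", "other")
  near <- ifelse(p %in% c("PresentSelf", "Mother"), "near", "far")
  map <- conds[, c("person", "valence")]
  map$side <- NA_character_
  scheme <- switch(name,
    self_vs_other = {
      map$class <- self
      list(mode = "cross_validation", map = map)
    },
    present_vs_past = {
      map$class <- ifelse(p %in% c("PresentSelf", "PastSelf"), p, NA)
      list(mode = "cross_validation", map = map)
    },
    mother_vs_queen = {
      map$class <- ifelse(p %in% c("Mother", "Queen"), p, NA)
      list(mode = "cross_validation", map = map)
    },
    four_way = {
      map$class <- p
      list(mode = "cross_validation", map = map)
    },
    xclass_self_other_across_distance = {
      map$class <- self
      map$side <- ifelse(p %in% c("PresentSelf", "Mother"), "A", "B")
      list(mode = "cross_classification", map = map)
    },
    xclass_distance_across_domain = {
      map$class <- near
      map$side <- ifelse(p %in% c("PresentSelf", "PastSelf"), "A", "B")
      list(mode = "cross_classification", map = map)
    },
    xclass_four_way_across_valence = {
      map$class <- p
      map$side <- ifelse(conds$valence == "Positive", "A", "B")
      list(mode = "cross_classification", map = map)
    },
    stop("unknown scheme: ", name, call. = FALSE)
  )
  classes <- sort(unique(stats::na.omit(scheme$map$class)))
  structure(
    list(
      name = name, mode = scheme$mode, map = scheme$map,
      classes = classes, n_classes = length(classes),
      chance = 1 / length(classes)
    ),
    class = "decoding_scheme"
  )
}

#' @rdname make_scheme
#' @export
scheme_names <- function() {
  c(
    "self_vs_other", "present_vs_past", "mother_vs_queen", "four_way",
    "xclass_self_other_across_distance", "xclass_distance_across_domain",
    "xclass_four_way_across_valence"
  )
}

#' Classifier settings
#'
#' Linear support vector machine with fixed regularization `C` (default 1)
#' and no hyperparameter search. Multiclass problems use one-vs-one
#' (pairwise) voting. Feature scaling is off by default; train-fold
#' z-scoring (means/SDs estimated on the training fold only, applied to
#' both folds) is available behind `scaling`.
#'
#' @param cost Positive SVM cost parameter.
#' @param scaling `"none"` (default) or `"train_fold_zscore"`.
#' @return A list of class `classifier_settings`.
#' @export
classifier_settings <- function(cost = 1,
                                scaling = c("none", "train_fold_zscore")) {
  if (cost <= 0) stop("cost must be > 0", call. = FALSE)
  structure(
    list(cost = cost, scaling = match.arg(scaling), multiclass = "one_vs_one"),
    class = "classifier_settings"
  )
}
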