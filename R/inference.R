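new_test_result <- function(method, statistic, df = NA_real_, p, tail,
                            estimate = NA_real_, alpha = 0.05, m = 1L,
                            degenerate = FALSE) {
  alpha_corrected <- alpha / m
  structure(
    list(
      method = method, statistic = statistic, df = df, p = p, tail = tail,
      estimate = estimate, alpha = alpha, m = as.integer(m),
      alpha_corrected = alpha_corrected,
      significant_bonferroni = is.finite(p) && p < alpha_corrected,
      degenerate = degenerate
    ),
    class = "mvpa_test"
  )
}

#' @export
print.mvpa_test <- function(x, ...) {
  cat(sprintf(
    "<mvpa_test> %s: statistic = %.4g, p = %.4g (%s-tailed)%s\n",
    x$method, x$statistic, x$p, x$tail,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' One-sample t test against the chance level
#'
#' Tests per-subject accuracies (or any values) against a fixed chance
#' level; one-tailed ("greater than chance") by default, matching the use
#' against 50% for binary and 25% for 4-way decoding. With zero variance
#' the t statistic is undefined: the result is flagged degenerate, with
#' p = 0 when every value exceeds chance and p = 1 otherwise (sign
#' convention for batch runs).
#'
#' @param values Numeric vector (>= 2 values).
#' @param chance Null value.
#' @param tail `"one"` (greater) or `"two"`.
#' @param alpha Nominal significance level.
#' @param m Number of comparisons for the Bonferroni flag.
#' @return An `mvpa_test` with fields `statistic`, `df`, `p`, `estimate`
#'   (mean), `alpha_corrected` and `significant_bonferroni`.
#' @export
one_sample_t_vs_chance <- function(values, chance = 0.5,
                                   tail = c("one", "two"),
                                   alpha = 0.05, m = 1L) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need >= 2 values", call. = FALSE)
  mu <- mean(values)
  s <- stats::sd(values)
  df <- n - 1
  if (s == 0) {
    diff <- mu - chance
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (tail == "one") {
      if (diff > 0) 0 else 1
    } else {
      if (diff == 0) 1 else 0
    }
    return(new_test_result("one-sample t (vs chance)", stat, df, p, tail,
      estimate = mu, alpha = alpha, m = m, degenerate = TRUE
    ))
  }
  stat <- (mu - chance) / (s / sqrt(n))
  p <- if (tail == "one") {
    stats::pt(stat, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  }
  new_test_result("one-sample t (vs chance)", stat, df, p, tail,
    estimate = mu, alpha = alpha, m = m
  )
}

#' Wilcoxon signed-rank test (exact for small n)
#'
#' Signed-rank test of paired differences (or of values against a null
#' value). Zero differences are dropped (Wilcoxon's convention). The p
#' value is exact by enumeration of all sign assignments for n <= 12
#' retained differences (midranks under ties, so the enumeration remains
#' exact), and a normal approximation with continuity and tie correction
#' above. One-tailed tests reject for large positive rank sums.
#'
#' @param values Numeric vector of differences (or raw values).
#' @param null_value Subtracted from `values` before testing.
#' @param tail `"one"` (greater) or `"two"`.
#' @param alpha,m As in [one_sample_t_vs_chance()].
#' @param exact_max Largest n for the exact enumeration.
#' @return An `mvpa_test`; `statistic` is the positive-rank sum V.
#' @examples
#' # five positive differences: exact one-tailed p = 1/32
#' signed_rank_test(c(1, 2, 3, 4, 5))$p
#' @export
signed_rank_test <- function(values, null_value = 0, tail = c("one", "two"),
                             alpha = 0.05, m = 1L, exact_max = 12L) {
  tail <- match.arg(tail)
  d <- values[!is.na(values)] - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_result("signed rank", 0, NA_real_, 1, tail,
      estimate = 0, alpha = alpha, m = m, degenerate = TRUE
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- if (tail == "one") {
      mean(v_all >= v)
    } else {
      mean(abs(v_all - mu) >= abs(v - mu) - 1e-12)
    }
  } else {
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48)
    if (tail == "one") {
      z <- (v - mu - 0.5) / sigma
      p <- stats::pnorm(z, lower.tail = FALSE)
    } else {
      z <- (abs(v - mu) - 0.5) / sigma
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
      p <- min(1, p)
    }
  }
  new_test_result("signed rank", v, NA_real_, p, tail,
    estimate = stats::median(d), alpha = alpha, m = m
  )
}

#' Bonferroni-corrected alpha level
#'
#' @param alpha Nominal familywise level.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m` (0.05 over 8 ROIs gives 0.00625).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Two-by-two repeated-measures ANOVA
#'
#' Fully within-subject 2 x 2 design with one observation per subject per
#' cell, decomposed by standard within-subject sums of squares: each
#' effect is tested against its own subject-by-effect interaction error
#' term, and the effect size is partial eta squared
#' SS_effect / (SS_effect + SS_error_effect).
#'
#' @param data A data frame.
#' @param subject,factor_a,factor_b,value Column names (strings).
#' @return An object of class `mvpa_anova`: a tibble with one row per
#'   effect (`A`, `B`, `A:B`) and columns `effect`, `F`, `df1`, `df2`,
#'   `p`, `pes`.
#' @export
rm_anova_2x2 <- function(data, subject = "subject", factor_a = "A",
                         factor_b = "B", value = "value") {
  d <- data.frame(
    s = factor(data[[subject]]), a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]]), y = data[[value]]
  )
  if (nlevels(d$a) != 2 || nlevels(d$b) != 2) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  n <- nlevels(d$s)
  if (n < 3) stop("need >= 3 subjects", call. = FALSE)
  counts <- table(d$s, d$a, d$b)
  if (any(counts != 1)) {
    stop("design must be complete with one observation per cell", call. = FALSE)
  }
  g <- mean(d$y)
  m_a <- tapply(d$y, d$a, mean)
  m_b <- tapply(d$y, d$b, mean)
  m_s <- tapply(d$y, d$s, mean)
  m_ab <- tapply(d$y, list(d$a, d$b), mean)
  m_sa <- tapply(d$y, list(d$s, d$a), mean)
  m_sb <- tapply(d$y, list(d$s, d$b), mean)
  ss_a <- 2 * n * sum((m_a - g)^2)
  ss_b <- 2 * n * sum((m_b - g)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
  ss_sa <- 2 * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + g)^2)
  ss_sb <- 2 * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + g)^2)
  ss_s <- 4 * sum((m_s - g)^2)
  ss_tot <- sum((d$y - g)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  ss_sab <- max(ss_sab, 0)
  eff <- function(name, ss_e, ss_err) {
    df1 <- 1
    df2 <- n - 1
    f <- if (ss_err == 0) {
      if (ss_e == 0) 0 else Inf
    } else {
      (ss_e / df1) / (ss_err / df2)
    }
    p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
    pes <- if (ss_e + ss_err == 0) 0 else ss_e / (ss_e + ss_err)
    tibble::tibble(
      effect = name, F = f, df1 = df1, df2 = df2, p = p, pes = pes
    )
  }
  out <- dplyr::bind_rows(
    eff("A", ss_a, ss_sa),
    eff("B", ss_b, ss_sb),
    eff("A:B", ss_ab, ss_sab)
  )
  out$factor <- c(factor_a, factor_b, paste(factor_a, factor_b, sep = ":"))
  class(out) <- c("mvpa_anova", class(out))
  out
}

#' Univariate condition contrasts per ROI
#'
#' Averages each condition's betas over voxels and runs per subject/ROI and
#' runs paired t tests for every condition pair within each ROI, with a
#' Bonferroni flag over the number of ROIs. In the default amplitude-matched
#' cohort no contrast is expected to be reliable, while multivoxel decoding
#' succeeds — the dissociation between mean amplitude and pattern
#' information.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param alpha Nominal significance level.
#' @return A list with `means` (subject x ROI x condition mean betas) and
#'   `tests` (tibble: roi, condition pair, t, df, p, significant flag at
#'   `alpha / n_rois`).
#' @export
univariate_contrast <- function(cohort, alpha = 0.05) {
  vox <- grep("^voxel_", names(cohort), value = TRUE)
  means <- dplyr::summarise(
    dplyr::group_by(
      cohort, .data$subject, .data$roi, .data$network,
      .data$person, .data$valence
    ),
    mean_beta = mean(rowMeans(dplyr::pick(dplyr::all_of(vox)))),
    .groups = "drop"
  )
  if (length(unique(means$subject)) < 2) {
    stop("need >= 2 subjects for paired contrasts", call. = FALSE)
  }
  means$condition <- paste(means$person, means$valence, sep = ".")
  rois <- unique(means$roi)
  m_rois <- length(rois)
  conds <- condition_table()$condition
  pairs <- utils::combn(conds, 2)
  tests <- purrr::map(rois, function(r) {
    d <- tidyr::pivot_wider(
      means[means$roi == r, c("subject", "condition", "mean_beta")],
      names_from = "condition", values_from = "mean_beta"
    )
    purrr::map(seq_len(ncol(pairs)), function(i) {
      diff <- d[[pairs[1, i]]] - d[[pairs[2, i]]]
      res <- one_sample_t_vs_chance(diff,
        chance = 0, tail = "two",
        alpha = alpha, m = m_rois
      )
      tibble::tibble(
        roi = r, condition_a = pairs[1, i], condition_b = pairs[2, i],
        t = res$statistic, df = res$df, p = res$p,
        significant_bonferroni = res$significant_bonferroni
      )
    })
  })
  list(means = means, tests = dplyr::bind_rows(purrr::flatten(tests)))
}
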