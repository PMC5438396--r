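#' Two-sample pooled t-test from summary statistics
#'
#' Student's t for two groups given only (n, mean, sd) — the form needed to
#' check published group-comparison tables. Pooled variance, df = n1+n2-2,
#' two-sided p.
#'
#' @param n1,mean1,sd1 Summary of group 1 (n >= 2, sd >= 0).
#' @param n2,mean2,sd2 Summary of group 2.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @examples
#' summary_t_test(18, 2.5486, 0.1114, 18, 2.4398, 0.1394)
#' @export
summary_t_test <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("sd must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    (mean1 - mean2) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  tibble::tibble(test = "student_t", statistic = t, df = df, p_value = p)
}

#' Chi-squared test of a contingency table
#'
#' Pearson's chi-squared, `sum((O - E)^2 / E)` with expected counts from
#' the margin product, no continuity correction, df = (r-1)(c-1).
#'
#' @param observed Integer matrix of counts (groups x categories).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(matrix(c(7, 10, 11, 8), nrow = 2)) # sex table, ~1.003
#' @export
chi_square_test <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers")
  }
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  if (any(expected == 0)) stop("zero expected cell count")
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  tibble::tibble(test = "chi_square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

# Mann-Whitney U via the rank-sum relation; p from wilcox.test (exact for
# small untied samples, normal approximation with tie correction above).
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                            correct = TRUE))
  tibble::tibble(test = "mann_whitney_u", statistic = unname(wt$statistic),
                 df = NA_real_, p_value = unname(wt$p.value))
}

#' Univariate group comparison over cohort features
#'
#' For every feature: a Shapiro-Wilk normality gate (alpha = 0.05 in each
#' group) selects Student's t (pooled) for normal-looking features and the
#' Mann-Whitney U test otherwise. Raw and Bonferroni-adjusted p values are
#' both reported (family = number of features tested in the call), plus
#' Cohen's d as a convenience effect size. Constant features are skipped
#' with a flag rather than aborting the scan.
#'
#' @param cohort Cohort tibble.
#' @param features Character vector of feature columns; defaults to all
#'   schema features present.
#' @param group_col Grouping column (two levels required).
#' @param alpha Significance level applied to the adjusted p.
#' @param normality_alpha Alpha of the per-group Shapiro-Wilk gate.
#' @return Tibble, one row per feature: `feature`, `test`, `statistic`,
#'   `df`, `p_raw`, `p_adjusted`, `significant`, `cohens_d`, `skipped`.
#' @export
compare_groups <- function(cohort, features = cohort_features(cohort),
                           group_col = "group", alpha = 0.05,
                           normality_alpha = 0.05) {
  g <- cohort[[group_col]]
  lev <- unique(g)
  if (length(lev) != 2) stop("compare_groups requires exactly 2 groups")
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects")

  res <- purrr::map_dfr(features, function(f) {
    x <- cohort[[f]][g == lev[[1]]]
    y <- cohort[[f]][g == lev[[2]]]
    if (stats::sd(c(x, y)) == 0) {
      return(tibble::tibble(feature = f, test = NA_character_,
                            statistic = NA_real_, df = NA_real_,
                            p_raw = NA_real_, cohens_d = NA_real_,
                            skipped = TRUE))
    }
    normal <- function(v) {
      if (stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value >= normality_alpha
    }
    row <- if (normal(x) && normal(y)) {
      summary_t_test(length(x), mean(x), stats::sd(x),
                     length(y), mean(y), stats::sd(y))
    } else {
      mann_whitney(x, y)
    }
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
    row <- dplyr::rename(row, p_raw = "p_value")
    dplyr::mutate(row, feature = f, cohens_d = d, skipped = FALSE,
                  .before = 1)
  })
  res$p_adjusted <- pmin(1, res$p_raw * sum(!res$skipped))
  res$significant <- !res$skipped & res$p_adjusted < alpha
  res[c("feature", "test", "statistic", "df", "p_raw", "p_adjusted",
        "significant", "cohens_d", "skipped")]
}

#' Compact letter display for pairwise group comparisons
#'
#' Assigns subscript letters by insert-and-absorb so that two groups share
#' a letter iff their Bonferroni-adjusted pairwise p value (pooled t-test;
#' family = number of pairs) is >= alpha. Groups of size 1 can participate
#' when summary SDs are supplied externally via `summaries`.
#'
#' @param data Data frame with a value column and a group column, or `NULL`
#'   when `summaries` is given.
#' @param value,group Column names in `data`.
#' @param alpha Significance level after Bonferroni adjustment.
#' @param summaries Optional tibble `group`, `n`, `mean`, `sd` used instead
#'   of raw data (summary-statistics t-tests).
#' @return Tibble: `group`, `letters` (e.g. `"a"`, `"ab"`), ordered by
#'   group mean.
#' @export
pairwise_letter_groups <- function(data = NULL, value = "value",
                                   group = "group", alpha = 0.05,
                                   summaries = NULL) {
  if (is.null(summaries)) {
    summaries <- data |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::summarise(
        n = dplyr::n(), mean = mean(.data[[value]]),
        sd = stats::sd(.data[[value]]), .groups = "drop"
      ) |>
      dplyr::rename(group = 1)
  }
  summaries <- dplyr::arrange(summaries, mean)
  k <- nrow(summaries)
  if (k < 2) stop("need at least 2 groups")
  m <- k * (k - 1) / 2
  # adjacency: TRUE where not significantly different after Bonferroni
  same <- diag(TRUE, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (summaries$n[[i]] < 2 || summaries$n[[j]] < 2) {
        # singleton group: no variance estimate of its own; pooled t with
        # df from the other group's variance only
        ni <- summaries$n[[i]]; nj <- summaries$n[[j]]
        s2 <- stats::weighted.mean(
          c(summaries$sd[[i]]^2, summaries$sd[[j]]^2),
          c(max(ni - 1, 0), max(nj - 1, 0))
        )
        df <- max(ni + nj - 2, 1)
        se <- sqrt(s2 * (1 / ni + 1 / nj))
        p <- if (se == 0) 1 else
          2 * stats::pt(-abs((summaries$mean[[i]] - summaries$mean[[j]]) / se),
                        df)
      } else {
        p <- summary_t_test(summaries$n[[i]], summaries$mean[[i]],
                            summaries$sd[[i]], summaries$n[[j]],
                            summaries$mean[[j]], summaries$sd[[j]])$p_value
      }
      same[i, j] <- same[j, i] <- min(1, p * m) >= alpha
    }
  }
  # insert-and-absorb: start from one set of all groups; split every set
  # containing a significantly-different pair, then absorb subsets
  sets <- list(seq_len(k))
  absorb <- function(sets) {
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a != b && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
            (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets[keep]
  }
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (same[i, j]) next
      hit <- vapply(sets, function(s) all(c(i, j) %in% s), logical(1))
      if (!any(hit)) next
      split <- unlist(lapply(sets[hit], function(s)
        list(setdiff(s, i), setdiff(s, j))), recursive = FALSE)
      sets <- absorb(c(sets[!hit], split))
    }
  }
  sets <- sets[lengths(sets) > 0]
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letter_of <- function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }
  tibble::tibble(
    group = summaries$group,
    n = summaries$n, mean = summaries$mean, sd = summaries$sd,
    letters = vapply(seq_len(k), letter_of, character(1))
  )
}
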