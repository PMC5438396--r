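#' Equal-frequency discretization of a continuous feature
#'
#' Bins a feature into (approximately) equal-frequency bins for the
#' frequency-based information measures. Ties at a bin edge go to the
#' lower bin; when fewer distinct values than bins exist, bins collapse
#' gracefully and the result is flagged degenerate if only one bin
#' survives.
#'
#' @param values Numeric vector.
#' @param n_bins Number of bins, >= 2.
#' @return List of class `discretized_feature`: `bins` (1-based bin index
#'   per observation), `edges` (strictly increasing upper edges),
#'   `n_bins` (effective count), `degenerate` flag.
#' @export
discretize <- function(values, n_bins = 3) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  n <- length(values)
  sorted <- sort(values)
  cut_pos <- round(n * seq_len(n_bins - 1) / n_bins)
  cut_pos <- cut_pos[cut_pos >= 1 & cut_pos < n]
  edges <- unique(sorted[cut_pos])
  edges <- edges[edges < max(values)]  # guarantee a non-empty top bin
  # x <= edge -> lower bin, i.e. ties at an edge go to the lower bin
  bins <- as.integer(
    vapply(values, function(x) sum(x > edges), numeric(1)) + 1L
  )
  eff <- length(edges) + 1L
  structure(
    list(bins = bins, edges = edges, n_bins = eff,
         degenerate = eff < 2),
    class = "discretized_feature"
  )
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

gini_impurity <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

# bins x class contingency table from integer bins and labels
bin_class_table <- function(bins, labels) {
  table(factor(bins), factor(labels))
}

#' Chi-squared relevance of a discretized feature
#'
#' `sum((O - E)^2 / E)` over the bins-by-class contingency table.
#'
#' @param feature A `discretized_feature` (or integer bin vector).
#' @param labels Class labels.
#' @return Non-negative score (0 for a degenerate feature or single class).
#' @export
score_chi2 <- function(feature, labels) {
  bins <- if (inherits(feature, "discretized_feature")) feature$bins else
    feature
  O <- bin_class_table(bins, labels)
  if (nrow(O) < 2 || ncol(O) < 2) return(0)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

#' Information gain (bits) of a discretized feature
#'
#' H(class) minus the bin-weighted conditional entropy of the class.
#'
#' @inheritParams score_chi2
#' @export
score_info_gain <- function(feature, labels) {
  bins <- if (inherits(feature, "discretized_feature")) feature$bins else
    feature
  O <- bin_class_table(bins, labels)
  if (ncol(O) < 2) return(0)
  h_class <- entropy_bits(colSums(O))
  pb <- rowSums(O) / sum(O)
  h_cond <- sum(pb * apply(O, 1, entropy_bits))
  max(h_class - h_cond, 0)
}

#' Gain ratio of a discretized feature
#'
#' Information gain divided by the entropy of the bin partition (the
#' intrinsic value); 0 when the partition entropy is 0.
#'
#' @inheritParams score_chi2
#' @export
score_gain_ratio <- function(feature, labels) {
  bins <- if (inherits(feature, "discretized_feature")) feature$bins else
    feature
  O <- bin_class_table(bins, labels)
  h_bins <- entropy_bits(rowSums(O))
  if (h_bins == 0) return(0)
  score_info_gain(feature, labels) / h_bins
}

#' Gini gain of a discretized feature
#'
#' Gini(class) minus the bin-weighted conditional Gini impurity.
#'
#' @inheritParams score_chi2
#' @export
score_gini <- function(feature, labels) {
  bins <- if (inherits(feature, "discretized_feature")) feature$bins else
    feature
  O <- bin_class_table(bins, labels)
  if (ncol(O) < 2) return(0)
  g_class <- gini_impurity(colSums(O))
  pb <- rowSums(O) / sum(O)
  g_cond <- sum(pb * apply(O, 1, gini_impurity))
  max(g_class - g_cond, 0)
}

#' Symmetrical uncertainty of a discretized feature
#'
#' `2 IG / (H(class) + H(bins))`, in `[0, 1]`. The `literal` variant
#' evaluates the published relevance expression
#' `2 (P(class) - P(class|feature)) / P(class) + P(feature)` with the
#' positive class and an expectation over feature bins; it is not bounded
#' in `[0, 1]` and is provided for comparison only.
#'
#' @inheritParams score_chi2
#' @param variant `"symmetrical"` (default) or `"literal"`.
#' @param positive Positive class for the literal variant (default: last
#'   level alphabetically).
#' @export
score_uncertainty <- function(feature, labels, variant = "symmetrical",
                              positive = NULL) {
  bins <- if (inherits(feature, "discretized_feature")) feature$bins else
    feature
  O <- bin_class_table(bins, labels)
  if (variant == "literal") {
    if (is.null(positive)) positive <- rev(colnames(O))[[1]]
    pc <- sum(O[, positive]) / sum(O)
    pb <- rowSums(O) / sum(O)
    pcb <- O[, positive] / rowSums(O)
    return(sum(pb * (2 * (pc - pcb) / pc + pb)))
  }
  h_class <- entropy_bits(colSums(O))
  h_bins <- entropy_bits(rowSums(O))
  if (h_class + h_bins == 0) return(0)
  2 * score_info_gain(feature, labels) / (h_class + h_bins)
}

#' One-rule (single-threshold) training accuracy of a raw feature
#'
#' Training accuracy of the best rule of the form `feature <= theta ->
#' class` over all midpoint thresholds between consecutive distinct sorted
#' values, both orientations, plus the trivial all-one-side rule
#' (majority).
#'
#' @param values Numeric feature values.
#' @param labels Class labels.
#' @return Accuracy in `[0, 1]`.
#' @export
score_rule_accuracy <- function(values, labels) {
  n <- length(values)
  if (n < 2) stop("need at least 2 subjects")
  lab <- factor(labels)
  ord <- order(values)
  v <- values[ord]
  y <- lab[ord]
  classes <- levels(lab)
  # cumulative class counts left of each split point
  cum <- apply(stats::model.matrix(~ y - 1), 2, cumsum)
  tot <- cum[n, ]
  best <- max(tot) / n  # trivial majority rule
  splits <- which(diff(v) > 0)
  for (s in splits) {
    left <- cum[s, ]
    right <- tot - left
    acc <- (max(left) + max(right)) / n
    if (acc > best) best <- acc
  }
  best
}

measure_names <- c("chi2", "rule_accuracy", "info_gain", "gain_ratio",
                   "gini", "uncertainty")

#' Six-measure ensemble feature ranking
#'
#' Scores every feature with the six univariate measures (chi-squared,
#' one-rule accuracy, information gain, gain ratio, Gini gain and
#' symmetrical uncertainty), min-max normalizes each measure to `[0, 1]`
#' across the features being ranked, averages the six normalized scores
#' with equal weights, and ranks features in descending order of the
#' average (ties broken lexicographically by name). Frequency-based
#' measures operate on an equal-frequency discretization of each feature;
#' one-rule accuracy uses the raw values. Degenerate (constant) features
#' receive all-zero scores rather than aborting the ranking.
#'
#' @param cohort Cohort tibble (or any data frame with a label column).
#' @param subset Ranked feature subset: `"all"`, `"thickness"`,
#'   `"roughness"` or `"volume"` (resolved against the cohort schema).
#' @param features Explicit feature columns (overrides `subset`).
#' @param label_col Class label column.
#' @param n_bins Bins for equal-frequency discretization.
#' @param uncertainty `"symmetrical"` or `"literal"` (see
#'   [score_uncertainty()]).
#' @return A tibble of class `feature_ranking`, one row per feature in rank
#'   order: `rank`, `feature`, `average`, the six raw scores and the six
#'   `norm_*` columns, and `degenerate`.
#' @export
rank_features <- function(cohort, subset = "all", features = NULL,
                          label_col = "group", n_bins = 3,
                          uncertainty = "symmetrical") {
  if (is.null(features)) features <- cohort_features(cohort, subset)
  labels <- cohort[[label_col]]
  if (length(unique(labels)) < 2) {
    warning("single-class labels: all scores are 0")
  }
  if (nrow(cohort) < 4) stop("need at least 4 subjects to rank")

  raw <- purrr::map_dfr(features, function(f) {
    x <- cohort[[f]]
    if (stats::sd(x) == 0 || length(unique(labels)) < 2) {
      return(tibble::tibble(
        feature = f, chi2 = 0, rule_accuracy = 0, info_gain = 0,
        gain_ratio = 0, gini = 0, uncertainty = 0, degenerate = TRUE
      ))
    }
    d <- discretize(x, n_bins)
    tibble::tibble(
      feature = f,
      chi2 = score_chi2(d, labels),
      rule_accuracy = score_rule_accuracy(x, labels),
      info_gain = score_info_gain(d, labels),
      gain_ratio = score_gain_ratio(d, labels),
      gini = score_gini(d, labels),
      uncertainty = score_uncertainty(d, labels, variant = uncertainty),
      degenerate = d$degenerate
    )
  })

  norm <- raw
  for (m in measure_names) {
    v <- raw[[m]]
    rng <- range(v)
    norm[[paste0("norm_", m)]] <- if (diff(rng) == 0) rep(0, length(v)) else
      (v - rng[1]) / diff(rng)
  }
  norm$average <- rowMeans(norm[paste0("norm_", measure_names)])
  out <- norm[order(-norm$average, norm$feature), ]
  out$rank <- seq_len(nrow(out))
  out <- out[c("rank", "feature", "average", measure_names,
               paste0("norm_", measure_names), "degenerate")]
  class(out) <- c("feature_ranking", class(out))
  out
}
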