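# Independent brute-force oracles for the information measures, written
# directly from the defining probability formulas (no shared code with the
# package implementations).

oracle_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_chi2 <- function(bins, labels) {
  O <- table(bins, labels)
  if (nrow(O) < 2 || ncol(O) < 2) return(0)
  total <- sum(O)
  out <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- sum(O[i, ]) * sum(O[, j]) / total
      out <- out + (O[i, j] - E)^2 / E
    }
  }
  out
}

oracle_info_gain <- function(bins, labels) {
  h <- oracle_entropy(labels)
  for (b in unique(bins)) {
    sel <- bins == b
    h <- h - mean(sel) * oracle_entropy(labels[sel])
  }
  max(h, 0)
}

oracle_gain_ratio <- function(bins, labels) {
  hb <- oracle_entropy(bins)
  if (hb == 0) 0 else oracle_info_gain(bins, labels) / hb
}

oracle_gini <- function(bins, labels) {
  gini <- function(l) {
    p <- as.numeric(table(l)) / length(l)
    1 - sum(p^2)
  }
  g <- gini(labels)
  for (b in unique(bins)) {
    sel <- bins == b
    g <- g - mean(sel) * gini(labels[sel])
  }
  max(g, 0)
}

oracle_su <- function(bins, labels) {
  denom <- oracle_entropy(labels) + oracle_entropy(bins)
  if (denom == 0) 0 else 2 * oracle_info_gain(bins, labels) / denom
}

# exhaustive one-rule oracle (binary labels): try every observed value as
# threshold and both orientations
oracle_rule_accuracy <- function(x, y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  best <- max(table(y)) / length(y)
  if (length(classes) != 2) return(best)
  for (thr in sort(unique(x))) {
    left <- x <= thr
    acc_a <- (sum(y[left] == classes[1]) + sum(y[!left] == classes[2])) /
      length(y)
    acc_b <- (sum(y[left] == classes[2]) + sum(y[!left] == classes[1])) /
      length(y)
    best <- max(best, acc_a, acc_b)
  }
  best
}

# a tiny three-feature schema for degenerate-case tests
mini_schema <- function() {
  tibble::tibble(
    name = c("lh-superiorfrontal-thickness", "lh-superiorfrontal-roughness",
             "lh-hippocampus-volume"),
    hemisphere = c("lh", "lh", "lh"),
    region = c("superiorfrontal", "superiorfrontal", "hippocampus"),
    feature_type = c("thickness_mean", "thickness_roughness", "volume"),
    units = c("mm", "mm", "mm^3")
  )
}

# data frame with exactly the requested sample mean and SD
constructed_sample <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}
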