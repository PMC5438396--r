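test_that("equal-frequency discretization balances bins and honors ties", {
  d <- discretize(1:36, 3)
  expect_equal(as.numeric(table(d$bins)), c(12, 12, 12))
  expect_equal(d$n_bins, 3)
  expect_false(d$degenerate)

  const <- discretize(rep(2.5, 10), 3)
  expect_true(const$degenerate)
  expect_equal(const$n_bins, 1)

  # ties at an edge go to the lower bin
  x <- c(1, 1, 1, 1, 2, 3)
  dt <- discretize(x, 3)
  expect_true(all(dt$bins[x == 1] == 1))
  # tie-heavy data: bin sizes within tie multiplicity of the ideal
  set.seed(2)
  y <- sample(1:5, 60, replace = TRUE)
  dy <- discretize(y, 3)
  ideal <- 60 / dy$n_bins
  mult <- max(table(y))
  expect_true(all(abs(table(dy$bins) - ideal) <= mult))

  expect_error(discretize(1:10, 1), "at least 2")
})

test_that("closed-form scores hold for perfect and independent predictors", {
  labels <- rep(c("control", "ET"), each = 18)
  perfect <- rep(c(1L, 2L), each = 18)
  expect_equal(score_info_gain(perfect, labels), 1.0)
  expect_equal(score_uncertainty(perfect, labels), 1.0)
  expect_equal(score_gini(perfect, labels), 0.5)
  expect_equal(score_gain_ratio(perfect, labels), 1.0)
  expect_equal(score_chi2(perfect, labels), 36)

  indep <- rep(c(1L, 2L, 1L, 2L), each = 9)  # same class mix in each bin
  expect_equal(score_info_gain(indep, labels), 0)
  expect_equal(score_chi2(indep, labels), 0)
  expect_equal(score_gini(indep, labels), 0)
  expect_equal(score_gain_ratio(indep, labels), 0)
  expect_equal(score_uncertainty(indep, labels), 0)
})

test_that("worked 2-bin table matches the entropy and chi-squared oracles", {
  bins <- rep(c(1L, 2L), c(8, 28))
  labels <- c(rep("control", 6), rep("ET", 2),
              rep("control", 12), rep("ET", 16))
  expect_equal(score_info_gain(bins, labels),
               oracle_info_gain(bins, labels), tolerance = 1e-12)
  expect_equal(score_chi2(bins, labels), oracle_chi2(bins, labels),
               tolerance = 1e-12)
})

test_that("one-rule accuracy equals the exhaustive threshold search", {
  sep <- c(1:5, 11:15)
  lab <- rep(c("a", "b"), each = 5)
  expect_equal(score_rule_accuracy(sep, lab), 1.0)
  expect_equal(score_rule_accuracy(rep(1, 36),
                                   rep(c("a", "b"), each = 18)), 0.5)
  expect_equal(score_rule_accuracy(1:8, rep(c("a", "b"), 4)), 0.625)

  set.seed(6)
  for (i in 1:50) {
    x <- sample(1:6, 12, replace = TRUE) + stats::runif(12, 0, 0.01)
    y <- sample(c("a", "b"), 12, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    expect_equal(score_rule_accuracy(x, y), oracle_rule_accuracy(x, y),
                 tolerance = 1e-12)
  }
})

test_that("all measures equal brute-force oracles on random small tables", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(8:20, 1)
    n_bins <- sample(2:4, 1)
    bins <- sample(seq_len(n_bins), n, replace = TRUE)
    labels <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labels)) < 2 || length(unique(bins)) < 2) next
    expect_equal(score_chi2(bins, labels), oracle_chi2(bins, labels),
                 tolerance = 1e-10)
    expect_equal(score_info_gain(bins, labels),
                 oracle_info_gain(bins, labels), tolerance = 1e-10)
    expect_equal(score_gain_ratio(bins, labels),
                 oracle_gain_ratio(bins, labels), tolerance = 1e-10)
    expect_equal(score_gini(bins, labels), oracle_gini(bins, labels),
                 tolerance = 1e-10)
    expect_equal(score_uncertainty(bins, labels), oracle_su(bins, labels),
                 tolerance = 1e-10)
  }
})

test_that("score ranges and bounds hold on random inputs", {
  set.seed(23)
  labels <- sample(c("a", "b"), 30, replace = TRUE)
  for (i in 1:50) {
    bins <- sample(1:3, 30, replace = TRUE)
    ig <- score_info_gain(bins, labels)
    expect_gte(ig, 0)
    expect_true(score_gain_ratio(bins, labels) >= 0 &&
                  score_gain_ratio(bins, labels) <= 1)
    expect_true(score_uncertainty(bins, labels) >= 0 &&
                  score_uncertainty(bins, labels) <= 1)
    g <- score_gini(bins, labels)
    gini_class <- 1 - sum((table(labels) / 30)^2)
    expect_true(g >= 0 && g <= gini_class + 1e-12)
  }
})

test_that("measures are invariant under strictly monotone transforms", {
  co <- generate_cohort(seed = 12)
  x <- co[["rh-fusiform-roughness"]]
  lab <- co$group
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) 10 * v - 2)) {
    d1 <- discretize(x, 3); d2 <- discretize(f(x), 3)
    expect_equal(d1$bins, d2$bins)
    expect_equal(score_rule_accuracy(x, lab),
                 score_rule_accuracy(f(x), lab), tolerance = 1e-12)
  }
})

test_that("ensemble ranking surfaces an injected informative feature", {
  hits <- 0
  for (s in 1:100) {
    set.seed(5000 + s)
    n <- 36
    lab <- rep(c("control", "ET"), each = n / 2)
    dat <- tibble::as_tibble(
      stats::setNames(as.data.frame(matrix(rnorm(n * 50), n)),
                      sprintf("noise%02d", 1:50))
    )
    dat$informative <- rnorm(n, ifelse(lab == "ET", 2, 0), 1)
    dat$group <- lab
    rk <- rank_features(dat, features = c("informative",
                                          sprintf("noise%02d", 1:50)))
    hits <- hits + (rk$feature[1] == "informative")
  }
  expect_gte(hits, 95)
})

test_that("ranking output is normalized, complete and deterministically tied", {
  co <- generate_cohort(seed = 2)
  rk <- rank_features(co, subset = "roughness")
  expect_equal(nrow(rk), 76)
  norms <- as.matrix(rk[paste0("norm_", etminer:::measure_names)])
  expect_true(all(norms >= 0 & norms <= 1))
  expect_true(all(rk$average >= 0 & rk$average <= 1))
  expect_true(all(diff(rk$average) <= 1e-12))
  # per measure, max normalized is 1 and min is 0
  expect_true(all(abs(apply(norms, 2, max) - 1) < 1e-12))
  expect_true(all(apply(norms, 2, min) == 0))

  # duplicated feature: identical scores, adjacent name-ordered ranks
  co2 <- co
  co2[["aa-duplicate-roughness"]] <- co2[["rh-fusiform-roughness"]]
  rk2 <- rank_features(co2, features = c("aa-duplicate-roughness",
                                         cohort_features(co, "roughness")))
  i <- which(rk2$feature == "aa-duplicate-roughness")
  j <- which(rk2$feature == "rh-fusiform-roughness")
  expect_equal(rk2$average[i], rk2$average[j], tolerance = 1e-12)
  # everything ranked between the two copies belongs to the same tie
  # block, which is ordered lexicographically by name
  block <- rk2[i:j, ]
  expect_true(all(block$average == rk2$average[i]))
  expect_equal(block$feature, sort(block$feature))

  # identical pure-noise features: all normalized scores 0, name order
  same <- tibble::tibble(group = rep(c("control", "ET"), each = 18))
  set.seed(1); v <- rnorm(36)
  for (f in c("f3", "f1", "f2")) same[[f]] <- v
  rk3 <- rank_features(same, features = c("f3", "f1", "f2"))
  expect_true(all(rk3$average == 0))
  expect_equal(rk3$feature, c("f1", "f2", "f3"))
})

test_that("degenerate inputs degrade gracefully", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                      f1 = rep(1, 20), f2 = rnorm(20))
  rk <- rank_features(d, features = c("f1", "f2"))
  expect_true(rk$degenerate[rk$feature == "f1"])
  expect_equal(rk$average[rk$feature == "f1"], 0)

  single <- tibble::tibble(group = rep("a", 10), f = rnorm(10))
  expect_warning(rank_features(single, features = "f"), "single-class")
})
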