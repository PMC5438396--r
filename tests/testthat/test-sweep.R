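test_that("fragment sizes follow round-half-up with the odd grid plus 100", {
  grid76 <- fragment_grid(76)
  expect_equal(nrow(grid76), 49)
  expect_equal(grid76$percentage, c(seq(5, 99, 2), 100))
  expect_true(all(diff(grid76$n_features) >= 0))
  expect_equal(grid76$n_features[grid76$percentage == 13], 10)
  expect_equal(grid76$n_features[grid76$percentage == 47], 36)
  expect_equal(grid76$n_features[grid76$percentage == 100], 76)

  # printed feature counts consistent with round-half-up sizing
  expect_equal(fragment_grid(281, percentages = 22)$n_features, 62L)
  grid152 <- fragment_grid(152)
  expect_equal(grid152$n_features[grid152$percentage == 15], 23)
  grid129 <- fragment_grid(129)
  expect_equal(grid129$n_features[grid129$percentage == 15], 19)
  expect_equal(grid129$n_features[grid129$percentage == 5], 6)
  # minimum fragment is one feature
  expect_equal(fragment_grid(3)$n_features[1], 1)
})

test_that("stratified folds balance size and class composition", {
  labels <- rep(c("control", "ET"), each = 18)
  f <- stratified_kfold(labels, k = 10, seed = 42)
  sizes <- as.numeric(table(f))
  expect_equal(sort(sizes), c(3, 3, 3, 3, 4, 4, 4, 4, 4, 4))
  for (k in 1:10) {
    expect_true(all(table(labels[f == k]) >= 1))
  }
  expect_identical(stratified_kfold(labels, 10, 7),
                   stratified_kfold(labels, 10, 7))
  expect_false(identical(stratified_kfold(labels, 10, 7),
                         stratified_kfold(labels, 10, 8)))
  expect_error(stratified_kfold(labels, k = 1), "at least 2")
  expect_error(stratified_kfold(rep("a", 10), k = 10), "2 classes")
  expect_warning(stratified_kfold(c(rep("a", 2), rep("b", 20)), k = 10),
                 "smallest class")
})

test_that("cross-validation confines fitting to training folds", {
  d <- tibble::tibble(
    group = rep(c("control", "ET"), each = 10),
    f1 = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  )
  folds <- stratified_kfold(d$group, 5, seed = 1)
  cv <- cross_validate("knn", d, "f1", folds)
  expect_equal(cv$mean_accuracy, 1)
  expect_length(cv$fold_accuracy, 5)

  # a training split with a single class is skipped with a warning
  d2 <- tibble::tibble(group = c("a", "a", "a", "b"), f1 = 1:4)
  folds2 <- c(1, 1, 2, 2)
  expect_warning(cv2 <- cross_validate("knn", d2, "f1", folds2),
                 "single-class")
  expect_true(is.na(cv2$fold_accuracy[2]))
  expect_equal(cv2$mean_accuracy, cv2$fold_accuracy[1])
})

test_that("the sweep populates the grid and its summaries coherently", {
  co <- generate_cohort(seed = 1)
  sw <- run_sweep(co, subsets = "roughness", classifiers = c("nb", "knn"),
                  percentages = c(5, 25, 50, 100), seed = 1)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw$accuracy), 2 * 4)
  expect_true(all(sw$accuracy$accuracy >= 0 & sw$accuracy$accuracy <= 1))
  expect_equal(sw$accuracy$n_features[sw$accuracy$percentage == 100][1], 76)

  # grand average is the exact arithmetic mean of the grid row; the
  # maximum can never fall below it
  for (cl in c("nb", "knn")) {
    row <- sw$accuracy[sw$accuracy$classifier == cl, ]
    srow <- sw$summary[sw$summary$classifier == cl, ]
    expect_identical(srow$grand_average, mean(row$accuracy))
    expect_gte(srow$maximum, srow$grand_average)
    expect_equal(srow$argmax_n_features,
                 row$n_features[which.max(row$accuracy)])
  }
  # per-fold accuracies are retained and consistent with the cell mean
  fa <- sw$accuracy$fold_accuracy[[1]]
  expect_equal(mean(fa, na.rm = TRUE), sw$accuracy$accuracy[[1]])

  g <- glance(sw)
  expect_equal(g$best_accuracy, max(sw$summary$maximum))
  td <- tidy(sw)
  expect_false("fold_accuracy" %in% names(td))
})

test_that("rank-per-fold mode shields ranking from a test-fold canary", {
  # canary feature: equals the class on test rows, noise on train rows --
  # any leakage of validation subjects into the ranking would select it
  set.seed(33)
  n <- 36
  lab <- rep(c("control", "ET"), each = n / 2)
  sch <- tibble::tibble(
    name = c(sprintf("lh-f%02d-roughness", 1:6), "lh-canary-roughness"),
    hemisphere = "lh", region = c(sprintf("f%02d", 1:6), "canary"),
    feature_type = "thickness_roughness", units = "mm"
  )
  d <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(rnorm(n * 6), n)), sch$name[1:6])
  )
  d$group <- lab
  d[[sch$name[2]]] <- rnorm(n, ifelse(lab == "ET", 2, 0), 1)  # informative
  folds <- stratified_kfold(lab, 6, seed = 2)
  canary <- rnorm(n)
  test_fold <- folds == 1
  canary[test_fold] <- ifelse(lab[test_fold] == "ET", 10, -10)
  d[["lh-canary-roughness"]] <- canary
  attr(d, "schema") <- sch
  class(d) <- c("et_cohort", class(d))
  rk_train <- rank_features(d[folds != 1, ], subset = "roughness")
  expect_false(rk_train$feature[1] == "lh-canary-roughness")
  expect_equal(rk_train$feature[1], sch$name[2])
})

test_that("label permutation keeps cross-validated accuracy at chance", {
  co <- generate_cohort(seed = 2)
  feats <- cohort_features(co, "roughness")[1:10]  # fixed, unranked list
  specs <- list(
    nb = classifier_spec("nb"), svm = classifier_spec("svm"),
    rule = classifier_spec("rule"), knn = classifier_spec("knn"),
    ann = classifier_spec("ann", epochs = 300)
  )
  n_perm <- 12
  for (nm in names(specs)) {
    accs <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      set.seed(300 + p)
      perm <- co
      perm$group <- sample(perm$group)
      folds <- stratified_kfold(perm$group, 10, seed = p)
      accs[p] <- cross_validate(specs[[nm]], perm, feats,
                                folds)$mean_accuracy
    }
    ci <- t.test(accs, mu = 0.5, conf.level = 0.99)$conf.int
    expect_true(ci[1] <= 0.5 && 0.5 <= ci[2],
                info = paste0(nm, ": CI [", round(ci[1], 3), ", ",
                              round(ci[2], 3), "]"))
  }
})

test_that("accuracy at small fragments survives noise dilution", {
  # with informative features ranked first, adding the noise tail should
  # not improve accuracy by more than a small margin
  diffs <- numeric(3)
  for (s in 1:3) {
    co <- generate_cohort(seed = 400 + s)
    sw <- run_sweep(co, subsets = "roughness", classifiers = "nb",
                    percentages = c(5, 100), seed = s)
    a <- sw$accuracy
    diffs[s] <- a$accuracy[a$percentage == 5] -
      a$accuracy[a$percentage == 100]
  }
  expect_gte(mean(diffs), -0.05)
})

test_that("subset comparison letters reflect the accuracy separations", {
  mk_sweep <- function(acc_by_subset) {
    cells <- purrr::imap_dfr(acc_by_subset, function(v, s)
      tibble::tibble(subset = s, classifier = "nb",
                     percentage = seq_along(v), n_features = seq_along(v),
                     accuracy = v, fold_accuracy = list(NULL)))
    structure(list(accuracy = cells, seed = 1, mode = "rank-once", k = 10),
              class = "sweep_result")
  }
  same <- rep(0.6, 48)
  sw1 <- mk_sweep(list(all = same, thickness = same))
  expect_equal(unique(compare_subsets(sw1)$letters), "a")

  sw2 <- mk_sweep(list(
    all = constructed_sample(48, 0.5, 0.01, 1),
    thickness = constructed_sample(48, 0.7, 0.01, 2)
  ))
  cl2 <- compare_subsets(sw2)
  expect_false(cl2$letters[cl2$subset == "all"] ==
                 cl2$letters[cl2$subset == "thickness"])

  # four same-distribution subsets usually share a letter
  share <- 0
  for (r in 1:60) {
    set.seed(600 + r)
    sw3 <- mk_sweep(list(a = rnorm(48, 0.6, 0.05), b = rnorm(48, 0.6, 0.05),
                         c = rnorm(48, 0.6, 0.05), d = rnorm(48, 0.6, 0.05)))
    cl3 <- compare_subsets(sw3)
    common <- Reduce(intersect, strsplit(cl3$letters, ""))
    share <- share + (length(common) > 0)
  }
  expect_gte(share / 60, 0.9)
})

test_that("autoplot methods return ggplot objects", {
  co <- generate_cohort(seed = 1)
  sw <- run_sweep(co, subsets = "roughness", classifiers = "nb",
                  percentages = c(10, 50), seed = 1)
  expect_s3_class(autoplot(sw), "ggplot")
  rk <- rank_features(co, subset = "roughness")
  expect_s3_class(autoplot(rk, top_n = 10), "ggplot")
})
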