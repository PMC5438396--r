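test_that("printed model fires the expected rules on constructed vectors", {
  pm <- printed_rule_model()
  # case-subgroup mean vector: rule 1 fails (0.720 > 0.666), rule 2 fires
  et2 <- tibble::tibble(
    "rh-inferiorparietal-roughness" = 0.720,
    "lh-lateraloccipital-roughness" = 0.65,
    "rh-fusiform-roughness" = 0.6429,
    "lh-medialorbitofrontal-roughness" = 0.75,
    "lh-frontal-lobe-roughness" = 0.52,
    "lh-parstriangularis-roughness" = 0.60
  )
  r <- apply_rules(pm, et2)
  expect_equal(r$rule_index, 2L)
  expect_equal(r$label, "ET")

  # both rule-1 conditions strictly below the printed thresholds
  ctrl <- et2
  ctrl[["rh-inferiorparietal-roughness"]] <- 0.60
  ctrl[["lh-lateraloccipital-roughness"]] <- 0.50
  r1 <- apply_rules(pm, ctrl)
  expect_equal(r1$rule_index, 1L)
  expect_equal(r1$label, "control")

  # failing rules 1-4 falls through to the default
  fall <- tibble::tibble(
    "rh-inferiorparietal-roughness" = 0.70,
    "lh-lateraloccipital-roughness" = 0.70,
    "rh-fusiform-roughness" = 0.75,
    "lh-medialorbitofrontal-roughness" = 0.90,
    "lh-frontal-lobe-roughness" = 0.50,
    "lh-parstriangularis-roughness" = 0.50
  )
  r5 <- apply_rules(pm, fall)
  expect_equal(r5$rule_index, 5L)
  expect_equal(r5$label, "control")
})

test_that("printed model thresholds and JSON serialization round-trip", {
  pm <- printed_rule_model()
  td <- tidy(pm)
  expect_equal(sort(td$threshold[!is.na(td$threshold)]),
               sort(c(0.666, 0.609, 0.696, 0.841, 0.558, 0.514)))
  expect_equal(td$predicted_class[match(1:5, td$rule)],
               c("control", "ET", "control", "ET", "control"))
  path <- file.path(withr::local_tempdir(), "rules.json")
  write_rule_model(pm, path)
  back <- read_rule_model(path)
  expect_identical(tidy(back), td)
  expect_identical(back$rules[[1]]$coverage, pm$rules[[1]]$coverage)
})

test_that("rule model construction enforces the decision-list invariants", {
  expect_error(rule_model(list(
    list(conditions = list(), predicted_class = "a"),
    list(conditions = list(list(feature = "f", op = "le", threshold = 1)),
         predicted_class = "b")
  )), "final")
  expect_error(rule_model(list(
    list(conditions = list(list(feature = "f", op = "lt", threshold = 1)),
         predicted_class = "a"),
    list(conditions = list(), predicted_class = "b")
  )), "op")
  expect_error(rule_model(list(
    list(conditions = list(list(feature = "f", op = "le", threshold = NaN)),
         predicted_class = "a"),
    list(conditions = list(), predicted_class = "b")
  )), "finite")
})

test_that("application is order-sensitive across rules, commutative within", {
  mk <- function(conds1) rule_model(list(
    list(conditions = conds1, predicted_class = "A"),
    list(conditions = list(list(feature = "x", op = "gt", threshold = 0)),
         predicted_class = "B"),
    list(conditions = list(), predicted_class = "C")
  ))
  c1 <- list(list(feature = "x", op = "le", threshold = 5),
             list(feature = "y", op = "gt", threshold = 1))
  m <- mk(c1)
  m_swapped_conditions <- mk(rev(c1))
  d <- tibble::tibble(x = c(2, 8, -1), y = c(3, 3, 0))
  expect_equal(apply_rules(m, d)$label, c("A", "B", "C"))
  expect_equal(apply_rules(m_swapped_conditions, d), apply_rules(m, d))

  m_perm <- rule_model(list(m$rules[[2]], m$rules[[1]], m$rules[[3]]))
  expect_false(identical(apply_rules(m_perm, d)$label,
                         apply_rules(m, d)$label))
})

test_that("subjects with missing model features are skipped, not dropped", {
  pm <- printed_rule_model()
  d <- tibble::tibble(
    subject_id = c("a", "b"),
    "rh-inferiorparietal-roughness" = c(0.6, NA),
    "lh-lateraloccipital-roughness" = 0.5,
    "rh-fusiform-roughness" = 0.65,
    "lh-medialorbitofrontal-roughness" = 0.75,
    "lh-frontal-lobe-roughness" = 0.6,
    "lh-parstriangularis-roughness" = 0.5
  )
  r <- apply_rules(pm, d)
  expect_equal(r$skipped, c(FALSE, TRUE))
  expect_true(is.na(r$label[2]))
  expect_error(apply_rules(pm, d[, -2]), "lacks model features")
})

test_that("induction solves separable and XOR-structured data exactly", {
  d <- tibble::tibble(group = rep(c("control", "ET"), each = 6),
                      x = c(-(6:1) / 10, (1:6) / 10))
  m <- induce_rules(d, features = "x")
  expect_equal(length(m$rules), 2)
  expect_equal(mean(apply_rules(m, d)$label == d$group), 1)
  td <- tidy(m)
  expect_equal(td$threshold[1], 0, tolerance = 1e-12)

  # XOR-structured classes (unequal corner counts so that greedy
  # information gain has a usable first split)
  xor <- tibble::tibble(
    x = c(0, 0, 0, 1, 1, 0, 0, 1),
    y = c(0, 0, 0, 1, 1, 1, 1, 0),
    group = c(rep("control", 5), rep("ET", 3))
  )
  mx <- induce_rules(xor, features = c("x", "y"))
  n_cond_rules <- sum(vapply(mx$rules, function(r)
    length(r$conditions) > 0, logical(1)))
  expect_gte(n_cond_rules, 2)
  expect_equal(mean(apply_rules(mx, xor)$label == xor$group), 1)
})

test_that("induction respects the pureness stopping criterion", {
  set.seed(4)
  d <- tibble::tibble(
    group = rep(c("control", "ET"), each = 50),
    x = c(rnorm(50, 0), rnorm(50, 3))
  )
  m <- induce_rules(d, features = "x", pureness = 0.99)
  for (r in m$rules) {
    if (length(r$conditions) == 0) next
    expect_gte(max(r$coverage) / sum(r$coverage), 0.99 - 1e-12)
  }
  expect_error(induce_rules(d, features = "x", pureness = 0.4),
               "pureness")
  expect_error(induce_rules(d, features = "x", pureness = 1.2),
               "pureness")
  single <- d; single$group <- "control"
  expect_error(induce_rules(single, features = "x"), "two classes")
})

test_that("raising pureness to 1 with free rules never hurts training fit", {
  co <- generate_cohort(seed = 20)
  feats <- cohort_features(co, "roughness")
  m99 <- induce_rules(co, feats, pureness = 0.99, min_coverage = 2)
  m100 <- induce_rules(co, feats, pureness = 1, min_coverage = 1)
  acc99 <- mean(apply_rules(m99, co)$label == co$group)
  acc100 <- mean(apply_rules(m100, co)$label == co$group)
  expect_gte(acc100, acc99)
})

test_that("induced model fits its training cohort at least as well as the printed one", {
  co <- generate_cohort(seed = 6)
  feats <- cohort_features(co, "roughness")
  m <- induce_rules(co, feats)
  acc_induced <- mean(apply_rules(m, co)$label == co$group)
  acc_printed <- mean(apply_rules(printed_rule_model(), co)$label ==
                        co$group)
  expect_gte(acc_induced, acc_printed)
})

test_that("subgroup assignment partitions subjects by firing rule", {
  co <- generate_cohort(seed = 3)
  sa <- subgroup_assign(printed_rule_model(), co)
  expect_equal(sum(sa$summary$n), 36)
  et_rules <- sa$summary$rule_index[sa$summary$predicted == "ET"]
  expect_true(all(et_rules %in% c(2, 4)))

  default_only <- rule_model(list(
    list(conditions = list(), predicted_class = "control")
  ))
  sa1 <- subgroup_assign(default_only, co)
  expect_equal(nrow(sa1$summary), 1)
  expect_equal(sa1$summary$n, 36)
})

test_that("strong generator separation recovers subgroup weights", {
  spec <- study_cohort_spec()
  spec$subgroup_params$sd <- spec$subgroup_params$sd / 5
  spec$subgroups$n <- c(250L, 333L, 222L, 167L, 28L)
  co <- generate_cohort(spec, seed = 13)
  asg <- apply_rules(printed_rule_model(), co)
  w <- spec$subgroups$n / 1000
  for (i in 1:5) {
    p_hat <- mean(asg$rule_index == i)
    se <- sqrt(w[i] * (1 - w[i]) / 1000)
    expect_lt(abs(p_hat - w[i]), 3 * se + 0.01)
  }
})
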