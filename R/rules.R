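#' Construct an ordered decision-list rule model
#'
#' A rule model is an ordered list of rules with first-match semantics:
#' each rule is a conjunction of thresholded conditions
#' (`feature <= threshold` or `feature > threshold`) with a predicted
#' class; the final rule has no conditions and matches everything.
#'
#' @param rules List of rules; each rule a list with `conditions` (list of
#'   `list(feature, op, threshold)` with `op` in `le`/`gt`), a
#'   `predicted_class`, and optional `coverage` (named counts on the
#'   reference data).
#' @param metadata Optional list (induction configuration, provenance).
#' @return Object of class `rule_model`.
#' @export
rule_model <- function(rules, metadata = list()) {
  stopifnot(length(rules) >= 1)
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (length(r$conditions) == 0 && i != length(rules)) {
      stop("only the final (default) rule may have no conditions")
    }
    for (cond in r$conditions) {
      if (!cond$op %in% c("le", "gt")) stop("condition op must be le or gt")
      if (!is.finite(cond$threshold)) stop("threshold must be finite")
    }
  }
  if (length(rules[[length(rules)]]$conditions) != 0) {
    stop("the final rule must be an unconditional default")
  }
  structure(list(rules = rules, metadata = metadata), class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    conds <- if (length(r$conditions) == 0) "(default)" else
      paste(vapply(r$conditions, function(cc)
        sprintf("%s %s %.4g", cc$feature,
                if (cc$op == "le") "<=" else ">", cc$threshold),
        character(1)), collapse = " and ")
    cov <- if (is.null(r$coverage)) "" else
      sprintf("  (%s)", paste(r$coverage, collapse = "/"))
    cat(sprintf("Rule %d: if %s then %s%s\n", i, conds,
                r$predicted_class, cov))
  }
  invisible(x)
}

#' Tidy a rule model into a condition-level tibble
#'
#' @param x A `rule_model`.
#' @param ... Unused.
#' @return Tibble with one row per condition (default rules appear with
#'   `NA` condition fields): `rule`, `predicted_class`, `feature`, `op`,
#'   `threshold`.
#' @method tidy rule_model
#' @export
tidy.rule_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$rules), function(i) {
    r <- x$rules[[i]]
    if (length(r$conditions) == 0) {
      return(tibble::tibble(rule = i, predicted_class = r$predicted_class,
                            feature = NA_character_, op = NA_character_,
                            threshold = NA_real_))
    }
    purrr::map_dfr(r$conditions, function(cc)
      tibble::tibble(rule = i, predicted_class = r$predicted_class,
                     feature = cc$feature, op = cc$op,
                     threshold = cc$threshold))
  })
}

#' The printed five-rule diagnostic model
#'
#' The ordered decision list reported by the study (thresholds on the
#' roughness of six cortical areas), packaged as a fixture with its
#' original-cohort coverage stored as metadata. The coverage counts are a
#' property of the unavailable original cohort and are informational only.
#'
#' @return A `rule_model`.
#' @export
printed_rule_model <- function() {
  path <- system.file("extdata", "printed_rules.json", package = "etminer")
  read_rule_model(path)
}

#' Serialize / deserialize a rule model as JSON
#'
#' @param model A `rule_model`.
#' @param path JSON file path.
#' @return `write_rule_model`: `path`, invisibly. `read_rule_model`: a
#'   `rule_model`.
#' @export
write_rule_model <- function(model, path) {
  rules <- lapply(model$rules, function(r) {
    if (!is.null(r$coverage)) r$coverage <- as.list(r$coverage)
    r
  })
  jsonlite::write_json(
    list(rules = rules, metadata = model$metadata), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_rule_model
#' @export
read_rule_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    list(
      conditions = lapply(r$conditions, function(cc)
        list(feature = cc$feature, op = cc$op,
             threshold = as.numeric(cc$threshold))),
      predicted_class = r$predicted_class,
      coverage = if (is.null(r$coverage)) NULL else
        unlist(r$coverage)
    )
  })
  rule_model(rules, metadata = obj$metadata)
}

# logical vector: which rows of `data` satisfy every condition of `rule`
rule_matches <- function(rule, data) {
  ok <- rep(TRUE, nrow(data))
  for (cc in rule$conditions) {
    v <- data[[cc$feature]]
    ok <- ok & if (cc$op == "le") v <= cc$threshold else v > cc$threshold
  }
  ok
}

#' Apply a rule model to subjects
#'
#' First-match semantics: for each subject the first rule whose conditions
#' all hold fires and supplies the label. Subjects with a missing value in
#' any model feature are skipped with a flag.
#'
#' @param model A `rule_model`.
#' @param data Data frame of subjects (cohort tibble or feature rows).
#' @return Tibble: `subject_id` (row index when absent), `label`,
#'   `rule_index`, `skipped`.
#' @export
apply_rules <- function(model, data) {
  feats <- unique(unlist(lapply(model$rules, function(r)
    vapply(r$conditions, function(cc) cc$feature, character(1)))))
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0) {
    stop("data lacks model features: ", paste(missing, collapse = ", "))
  }
  n <- nrow(data)
  bad <- rep(FALSE, n)
  for (f in feats) bad <- bad | !is.finite(data[[f]])
  rule_index <- rep(NA_integer_, n)
  unassigned <- !bad
  for (i in seq_along(model$rules)) {
    m <- unassigned & rule_matches(model$rules[[i]], data)
    rule_index[m] <- i
    unassigned <- unassigned & !m
  }
  label <- vapply(rule_index, function(i)
    if (is.na(i)) NA_character_ else model$rules[[i]]$predicted_class,
    character(1))
  tibble::tibble(
    subject_id = if ("subject_id" %in% names(data)) data$subject_id else
      as.character(seq_len(n)),
    label = label, rule_index = rule_index, skipped = bad
  )
}

# best single (feature, op, threshold) condition on `data[rows, features]`
# by information gain of the induced binary split of labels; candidate
# thresholds are midpoints between consecutive distinct sorted values;
# sides smaller than min_coverage are not eligible as the covered side.
# Ties: lexicographic feature, then smaller threshold, then op le before gt.
best_condition <- function(data, rows, features, labels, min_coverage) {
  y <- factor(labels[rows])
  if (nlevels(y) != 2) stop("rule growth requires binary labels")
  n <- length(rows)
  y2 <- as.integer(y) == 2L
  h0 <- entropy_bits(table(y))
  # two-class entropy of (a, b) count pairs, vectorized
  ent2 <- function(a, b) {
    tot <- a + b
    p <- a / tot; q <- b / tot
    -(ifelse(a == 0, 0, p * log2(pmax(p, 1e-300)))) -
      ifelse(b == 0, 0, q * log2(pmax(q, 1e-300)))
  }
  best <- NULL
  for (f in sort(features)) {
    v <- data[[f]][rows]
    ord <- order(v)
    vs <- v[ord]
    s <- which(diff(vs) > 0)           # split after position s
    if (length(s) == 0) next
    c2 <- cumsum(y2[ord])[s]
    c1 <- s - c2
    t2 <- sum(y2); t1 <- n - sum(y2)
    gain <- h0 - (s / n) * ent2(c1, c2) -
      ((n - s) / n) * ent2(t1 - c1, t2 - c2)
    pur_le <- pmax(c1, c2) / s
    pur_gt <- pmax(t1 - c1, t2 - c2) / (n - s)
    thr <- (vs[s] + vs[s + 1]) / 2
    cand_op <- ifelse(pur_gt > pur_le, "gt", "le")   # cover the purer side
    purity <- pmax(pur_le, pur_gt)
    n_cov <- ifelse(cand_op == "le", s, n - s)
    ok <- gain > 1e-12 & n_cov >= min_coverage
    # a side below min_coverage may still be eligible via the other op
    alt <- gain > 1e-12 & !ok &
      ifelse(cand_op == "le", n - s, s) >= min_coverage
    cand_op[alt] <- ifelse(cand_op[alt] == "le", "gt", "le")
    purity[alt] <- ifelse(cand_op[alt] == "le", pur_le[alt], pur_gt[alt])
    n_cov[alt] <- ifelse(cand_op[alt] == "le", s[alt], n - s[alt])
    ok <- ok | alt
    if (!any(ok)) next
    pick <- which(ok)[order(-gain[ok], -purity[ok], thr[ok])[1]]
    if (is.null(best) ||
        gain[pick] > best$gain + 1e-12 ||
        (abs(gain[pick] - best$gain) <= 1e-12 &&
           purity[pick] > best$purity + 1e-12)) {
      best <- list(feature = f, op = cand_op[[pick]],
                   threshold = thr[[pick]], gain = gain[[pick]],
                   purity = purity[[pick]], n_cov = n_cov[[pick]])
    }
  }
  best
}

#' Induce an ordered decision list by sequential covering
#'
#' Greedy sequential covering: grow one rule at a time by repeatedly
#' adding the (feature, op, midpoint-threshold) condition that maximizes
#' the information gain of the split on the currently covered subjects,
#' keeping the purer side, until the covered set reaches the pureness
#' threshold (fraction of covered subjects in their majority class) or no
#' condition improves; commit the rule predicting the covered majority
#' class; remove covered subjects; repeat while at least `min_coverage`
#' subjects and two classes remain. A final unconditional default rule
#' predicts the majority of the remainder. Deterministic: candidate ties
#' break lexicographically by feature name, then smaller threshold.
#'
#' @param data Data frame of subjects.
#' @param features Feature columns to search; defaults to all schema
#'   features present.
#' @param label_col Binary class column.
#' @param pureness Stopping purity in (0.5, 1]; default 0.99.
#' @param min_coverage Minimum covered subjects per non-default rule.
#' @param max_conditions Safety cap on conditions per rule.
#' @return A `rule_model` with per-rule coverage counts on the training
#'   data.
#' @export
induce_rules <- function(data, features = cohort_features(data),
                         label_col = "group", pureness = 0.99,
                         min_coverage = 2, max_conditions = 8) {
  if (pureness <= 0.5 || pureness > 1) {
    stop("pureness must be in (0.5, 1]")
  }
  labels <- as.character(data[[label_col]])
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need two classes to induce rules")
  full_majority <- names(which.max(table(factor(labels, classes))))

  remaining <- seq_len(nrow(data))
  rules <- list()
  while (length(remaining) >= min_coverage &&
         length(unique(labels[remaining])) > 1) {
    conds <- list()
    covered <- remaining
    repeat {
      if (length(conds) >= max_conditions) break
      tab <- table(factor(labels[covered], classes))
      if (max(tab) / sum(tab) >= pureness) break
      bc <- best_condition(data, covered, features, labels, min_coverage)
      if (is.null(bc)) break
      conds <- c(conds, list(list(feature = bc$feature, op = bc$op,
                                  threshold = bc$threshold)))
      keep <- if (bc$op == "le") {
        data[[bc$feature]][covered] <= bc$threshold
      } else {
        data[[bc$feature]][covered] > bc$threshold
      }
      covered <- covered[keep]
    }
    if (length(conds) == 0) break
    tab <- table(factor(labels[covered], classes))
    if (max(tab) / sum(tab) < pureness) {
      warning("committing best-effort rule with purity ",
              round(max(tab) / sum(tab), 3), " < pureness ", pureness)
    }
    pred <- names(which.max(tab))
    rules <- c(rules, list(list(
      conditions = conds, predicted_class = pred,
      coverage = stats::setNames(as.integer(tab), names(tab))
    )))
    remaining <- setdiff(remaining, covered)
  }
  tab <- if (length(remaining) > 0) {
    table(factor(labels[remaining], classes))
  } else {
    table(factor(labels, classes))
  }
  default_pred <- if (length(remaining) > 0) names(which.max(tab)) else
    full_majority
  rules <- c(rules, list(list(
    conditions = list(), predicted_class = default_pred,
    coverage = stats::setNames(as.integer(tab), names(tab))
  )))
  rule_model(rules, metadata = list(
    pureness = pureness, min_coverage = min_coverage,
    scoring = "information_gain", n_train = nrow(data)
  ))
}

#' Assign subjects to rule-defined subgroups
#'
#' Partitions subjects by the rule that fires for them and summarizes each
#' subgroup (size, class composition, covariate means when present).
#'
#' @param model A `rule_model`.
#' @param cohort Cohort tibble.
#' @param label_col Optional true-label column used in the composition
#'   summary.
#' @return List with `assignments` (as [apply_rules()], plus the true
#'   group when available) and `summary` (one row per rule).
#' @export
subgroup_assign <- function(model, cohort, label_col = "group") {
  asg <- apply_rules(model, cohort)
  if (label_col %in% names(cohort)) asg$group <- cohort[[label_col]]
  for (cov in c("age", "sex", "education")) {
    if (cov %in% names(cohort)) asg[[cov]] <- cohort[[cov]]
  }
  summary <- asg |>
    dplyr::filter(!.data$skipped) |>
    dplyr::group_by(rule_index = .data$rule_index) |>
    dplyr::summarise(
      n = dplyr::n(),
      predicted = .data$label[[1]],
      n_control = if ("group" %in% names(asg))
        sum(.data$group == "control") else NA_integer_,
      n_et = if ("group" %in% names(asg))
        sum(.data$group == "ET") else NA_integer_,
      age_mean = if ("age" %in% names(asg)) mean(.data$age) else NA_real_,
      education_mean = if ("education" %in% names(asg))
        mean(.data$education) else NA_real_,
      .groups = "drop"
    )
  list(assignments = asg, summary = summary)
}
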