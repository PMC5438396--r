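round_half_up <- function(x) floor(x + 0.5)

#' Fragment grid of a ranked feature subset
#'
#' The sweep evaluates nested prefixes ("fragments") of the ranked feature
#' list at percentages 5, 7, ..., 99 and 100 (the 2-point grid started at
#' 5 never reaches 100, which is appended). Fragment size in features is
#' round-half-up(p/100 x subset size), with a minimum of 1.
#'
#' @param n_features Size of the ranked subset.
#' @param percentages Percentage grid.
#' @return Tibble: `percentage`, `n_features`.
#' @export
fragment_grid <- function(n_features,
                          percentages = c(seq(5, 99, by = 2), 100)) {
  tibble::tibble(
    percentage = percentages,
    n_features = pmax(1L, as.integer(round_half_up(
      percentages / 100 * n_features)))
  )
}

#' Stratified k-fold partition
#'
#' Deterministic per seed; fold sizes differ by at most 1 and class
#' proportions per fold are as equal as the arithmetic allows (each class
#' is dealt round-robin into folds, continuing the dealing position across
#' classes).
#'
#' @param labels Class label vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per observation.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("stratification requires >= 2 classes")
  if (k > 2 * min(table(labels))) {
    warning("k exceeds twice the smallest class size; ",
            "some folds will lack a class")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  pos <- 0L
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- (pos + length(idx)) %% k
  }
  fold
}

#' Cross-validated accuracy of one classifier on one feature list
#'
#' All fitting (including standardization parameters) is confined to the
#' training folds. A fold whose training split has a single class is
#' skipped with a warning and the mean taken over the remaining folds.
#'
#' @param spec A [classifier_spec()] or kind string.
#' @param data Cohort tibble.
#' @param features Feature columns used.
#' @param folds Integer fold assignment from [stratified_kfold()].
#' @param label_col Class label column.
#' @return List: `mean_accuracy`, `fold_accuracy` (NA for skipped folds).
#' @export
cross_validate <- function(spec, data, features, folds,
                           label_col = "group") {
  labels <- as.character(data[[label_col]])
  ks <- sort(unique(folds))
  acc <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    test <- folds == ks[[i]]
    if (length(unique(labels[!test])) < 2) {
      warning("fold ", ks[[i]], " skipped: single-class training split")
      next
    }
    model <- train_classifier(spec, data[!test, , drop = FALSE], features,
                              label_col)
    pred <- predict(model, data[test, , drop = FALSE])
    acc[i] <- mean(pred == labels[test], na.rm = FALSE)
  }
  list(mean_accuracy = mean(acc, na.rm = TRUE), fold_accuracy = acc)
}

#' Ranked-fragment sweep under stratified k-fold cross-validation
#'
#' For each feature-type subset, ranks the subset's features with the
#' six-measure ensemble, then evaluates every classifier on each top-n%
#' fragment of the ranking under stratified k-fold CV with a shared fold
#' assignment. By default the ranking is computed once on the full dataset
#' and fragments are fixed across folds (`mode = "rank-once"`, mirroring
#' the descriptive design it reproduces; optimistically biased since the
#' ranking has seen the validation subjects). `mode = "rank-per-fold"`
#' re-ranks within every training split and is the leakage-safe choice for
#' new studies.
#'
#' @param cohort Cohort tibble.
#' @param subsets Character vector among `"all"`, `"thickness"`,
#'   `"roughness"`, `"volume"`.
#' @param classifiers Character kinds or list of [classifier_spec()]s.
#' @param percentages Fragment percentage grid.
#' @param k Folds.
#' @param seed Seed for the fold assignment (and ANN initialization).
#' @param mode `"rank-once"` (default) or `"rank-per-fold"`.
#' @param label_col Class label column.
#' @param n_bins Discretization bins for the ranking.
#' @return Object of class `sweep_result`: `accuracy` (tibble subset x
#'   classifier x percentage with `n_features`, `accuracy`, list-column
#'   `fold_accuracy`), `summary` (grand average, maximum and argmax
#'   feature count per subset x classifier), `seed`, `mode`.
#' @export
run_sweep <- function(cohort, subsets = c("all", "thickness", "roughness",
                                          "volume"),
                      classifiers = c("nb", "svm", "rule", "knn", "ann"),
                      percentages = c(seq(5, 99, by = 2), 100),
                      k = 10, seed = 1, mode = c("rank-once",
                                                 "rank-per-fold"),
                      label_col = "group", n_bins = 3) {
  mode <- match.arg(mode)
  if (is.character(classifiers)) {
    classifiers <- stats::setNames(
      lapply(classifiers, function(kd) classifier_spec(kd, seed = seed)),
      classifiers
    )
  }
  folds <- stratified_kfold(cohort[[label_col]], k = k, seed = seed)
  labels <- as.character(cohort[[label_col]])

  cells <- list()
  for (subset in subsets) {
    feats <- cohort_features(cohort, subset)
    grid <- fragment_grid(length(feats), percentages)
    ranking_full <- if (mode == "rank-once") {
      rank_features(cohort, features = feats, label_col = label_col,
                    n_bins = n_bins)$feature
    } else NULL
    per_fold_rank <- if (mode == "rank-per-fold") {
      lapply(sort(unique(folds)), function(f)
        rank_features(cohort[folds != f, , drop = FALSE], features = feats,
                      label_col = label_col, n_bins = n_bins)$feature)
    } else NULL

    for (ci in seq_along(classifiers)) {
      spec <- classifiers[[ci]]
      for (gi in seq_len(nrow(grid))) {
        nf <- grid$n_features[[gi]]
        cell <- tryCatch({
          if (mode == "rank-once") {
            cross_validate(spec, cohort, ranking_full[seq_len(nf)], folds,
                           label_col)
          } else {
            ks <- sort(unique(folds))
            acc <- rep(NA_real_, length(ks))
            for (i in seq_along(ks)) {
              test <- folds == ks[[i]]
              if (length(unique(labels[!test])) < 2) next
              m <- train_classifier(spec, cohort[!test, , drop = FALSE],
                                    per_fold_rank[[i]][seq_len(nf)],
                                    label_col)
              p <- predict(m, cohort[test, , drop = FALSE])
              acc[i] <- mean(p == labels[test])
            }
            list(mean_accuracy = mean(acc, na.rm = TRUE),
                 fold_accuracy = acc)
          }
        }, error = function(e) {
          warning("sweep cell failed (", subset, ", ",
                  names(classifiers)[[ci]], ", ", grid$percentage[[gi]],
                  "%): ", conditionMessage(e))
          list(mean_accuracy = NA_real_, fold_accuracy = NULL)
        })
        cells[[length(cells) + 1]] <- tibble::tibble(
          subset = subset, classifier = names(classifiers)[[ci]],
          percentage = grid$percentage[[gi]], n_features = nf,
          accuracy = cell$mean_accuracy,
          fold_accuracy = list(cell$fold_accuracy)
        )
      }
    }
  }
  accuracy <- dplyr::bind_rows(cells)
  summary <- accuracy |>
    dplyr::group_by(.data$subset, .data$classifier) |>
    dplyr::summarise(
      grand_average = mean(.data$accuracy, na.rm = TRUE),
      maximum = max(.data$accuracy, na.rm = TRUE),
      argmax_n_features = .data$n_features[which.max(.data$accuracy)],
      .groups = "drop"
    )
  structure(list(accuracy = accuracy, summary = summary, seed = seed,
                 mode = mode, k = k),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> mode=", x$mode, ", ", x$k, "-fold CV, seed ",
      x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Glance at a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return One-row tibble: best accuracy and where it was attained.
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$maximum), ]
  tibble::tibble(
    best_accuracy = best$maximum, best_subset = best$subset,
    best_classifier = best$classifier,
    best_n_features = best$argmax_n_features,
    grand_average = mean(x$summary$grand_average)
  )
}

#' Tidy a sweep result into the accuracy grid
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The accuracy tibble without list columns.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) {
  dplyr::select(x$accuracy, -"fold_accuracy")
}

#' Compare feature-type subsets by their per-fragment accuracies
#'
#' For each classifier: pairwise pooled t-tests between subsets on the
#' vectors of per-fragment mean accuracies, Bonferroni-corrected over the
#' subset pairs, summarized as a compact letter display (subsets sharing
#' no letter differ significantly).
#'
#' @param sweep A `sweep_result`.
#' @param alpha Significance level.
#' @return Tibble: `classifier`, `subset`, `n`, `mean`, `sd`, `letters`.
#' @export
compare_subsets <- function(sweep, alpha = 0.05) {
  acc <- sweep$accuracy[!is.na(sweep$accuracy$accuracy), ]
  purrr::map_dfr(unique(acc$classifier), function(cl) {
    sub <- acc[acc$classifier == cl, ]
    summaries <- sub |>
      dplyr::group_by(group = .data$subset) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$accuracy),
                       sd = stats::sd(.data$accuracy), .groups = "drop")
    out <- pairwise_letter_groups(summaries = summaries, alpha = alpha)
    dplyr::mutate(out, classifier = cl, .before = 1) |>
      dplyr::rename(subset = "group")
  })
}
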