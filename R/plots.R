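#' Accuracy curves of a fragment sweep
#'
#' One panel per classifier, classification accuracy against the
#' percentage of the ranked subset used, one line per feature-type subset.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  dat <- tidy.sweep_result(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$percentage,
                                    y = .data$accuracy,
                                    colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$classifier)) +
    ggplot2::labs(x = "% of ranked features used",
                  y = "mean CV accuracy", colour = "feature subset") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Top of a feature ranking
#'
#' Horizontal bars of the average normalized score for the top-ranked
#' features.
#'
#' @param object A `feature_ranking`.
#' @param top_n Number of features shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, top_n = 20, ...) {
  dat <- utils::head(object, top_n)
  dat$feature <- stats::reorder(dat$feature, dat$average)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$average, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "average normalized score", y = NULL) +
    ggplot2::theme_minimal()
}
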