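# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per metric (`metric`, `value`).
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("f_measure", "precision", "recall", "accuracy", "auc"),
    value = c(x$f_measure, x$precision, x$recall, x$accuracy, x$auc)
  )
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with the metrics, the confusion cells and the
#'   test-set size.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    f_measure = x$f_measure, precision = x$precision, recall = x$recall,
    accuracy = x$accuracy, auc = x$auc,
    tp = x$confusion["rigor", "rigor"],
    fp = x$confusion["rigor", "nonrigor"],
    fn = x$confusion["nonrigor", "rigor"],
    tn = x$confusion["nonrigor", "nonrigor"],
    n_test = x$n_test
  )
}

#' Tidy a trained classifier bundle
#'
#' @param x An `eqrm_bundle`.
#' @param ... Unused.
#' @return Tibble with one row per stack member plus the ensemble row,
#'   carrying the member kind and (for the ensemble) the held-out metrics.
#' @export
tidy.eqrm_bundle <- function(x, ...) {
  tibble::tibble(
    member = c(names(x$model$members), "ensemble"),
    level = c(ifelse(startsWith(names(x$model$members), "adaboost_"),
                     "adaboost", "base"), "voting"),
    accuracy = c(rep(NA_real_, length(x$model$members)), x$report$accuracy),
    auc = c(rep(NA_real_, length(x$model$members)), x$report$auc)
  )
}

#' One-row summary of a trained classifier bundle
#'
#' @param x An `eqrm_bundle`.
#' @param ... Unused.
#' @return One-row tibble: combiner, member count, vocabulary size, seed
#'   and held-out metrics.
#' @export
glance.eqrm_bundle <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(combiner = x$spec$combiner,
                   n_members = length(x$model$members),
                   vocab_size = nrow(x$vocabulary), seed = x$seed),
    glance(x$report)
  )
}

#' Plot an evaluation report
#'
#' Bar chart of the report's metrics.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("autoplot requires ggplot2")
  }
  df <- tidy(object)
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Rigor classifier evaluation") +
    ggplot2::theme_minimal()
}

#' Plot a ranked article set
#'
#' Dot plot of ranked articles: evidence rank position against rigor
#' probability, colored by cross-context grade.
#'
#' @param ranked Tibble from [rank_articles()].
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranked) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_ranking requires ggplot2")
  }
  ranked <- tibble::as_tibble(ranked)
  ranked$position <- seq_len(nrow(ranked))
  ggplot2::ggplot(ranked,
                  ggplot2::aes(x = .data$position, y = .data$rigor_prob,
                               color = .data$context_grade)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_manual(
      values = c(H = "#1b7837", M = "#fdae61", L = "#d73027",
                 U = "grey60"),
      limits = rev(grade_levels())) +
    ggplot2::labs(x = "rank position", y = "P(rigor)",
                  color = "grade") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
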