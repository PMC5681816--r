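# ggplot2 visualisations of ranking and evaluation results.

#' Plot a z-score ranking
#'
#' `type = "ranking"` draws the summed z-score per method with leave-one-out
#' error bars; `type = "violin"` shows the distribution of per-statistic
#' z-scores per method.
#'
#' @param object a `zscore_table`
#' @param type `"ranking"` or `"violin"`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.zscore_table <- function(object, type = c("ranking", "violin"), ...) {
  type <- match.arg(type)
  if (type == "ranking") {
    d <- object$summary
    d$method <- factor(d$method, levels = d$method)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$sum_z)) +
      ggplot2::geom_col(fill = "firebrick3") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$loo_min,
                                          ymax = .data$loo_max),
                             width = 0.25) +
      ggplot2::labs(x = NULL, y = "summed z-score",
                    title = "Assembly ranking (summed z-scores)") +
      ggplot2::theme_minimal()
  } else {
    d <- object$z
    d$method <- factor(d$method, levels = object$summary$method)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$z)) +
      ggplot2::geom_violin(fill = "firebrick3", alpha = 0.6) +
      ggplot2::geom_boxplot(width = 0.1, outlier.shape = NA) +
      ggplot2::labs(x = NULL, y = "z-score",
                    title = "Per-statistic z-scores") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot misassembly counts per assembly
#'
#' @param evals named list of `assembly_eval` tibbles
#' @return a ggplot object
#' @export
plot_misassemblies <- function(evals) {
  d <- dplyr::bind_rows(lapply(names(evals), function(m) {
    ev <- attr(evals[[m]], "events")
    tibble::tibble(method = m, type = ev$type)
  })) |>
    dplyr::count(.data$method, .data$type)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$n,
                                  fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "events", fill = "misassembly",
                  title = "Misassemblies by type") +
    ggplot2::theme_minimal()
}
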