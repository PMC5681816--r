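# Summed z-score ranking of assembly methods over the statistic registry,
# with leave-one-out error bars and one-sided Wilcoxon rank-sum comparisons.

# orient a statistic so that larger is always better
orient_value <- function(value, orientation) {
  switch(orientation,
         higher = value,
         lower = -value,
         near_one = -abs(value - 1),
         stop("unknown orientation: ", orientation))
}

#' Rank assembly methods by summed z-scores
#'
#' For every statistic, values are oriented so that larger is better,
#' standardized across methods (`z = (x - mean) / sd`, sample sd; columns
#' with zero sd contribute zeros) and summed per method. Leave-one-out error
#' bars report the best and worst summed z-score attainable by omitting one
#' statistic.
#'
#' @param stats either a named list of `assembly_eval` tibbles or a long
#'   tibble with columns `method`, `stat`, `value`, `orientation`
#' @return an object of class `zscore_table` with elements `z` (long tibble
#'   of per-statistic z-scores), `summary` (per-method summed z and
#'   leave-one-out range) and `stats` (the input values)
#' @export
zscore_rank <- function(stats) {
  if (is.list(stats) && !is.data.frame(stats)) {
    if (is.null(names(stats))) stop("the list of stat vectors must be named")
    stats <- dplyr::bind_rows(
      lapply(names(stats), function(m) {
        dplyr::mutate(tibble::as_tibble(stats[[m]]), method = m)
      }))
  }
  stopifnot(all(c("method", "stat", "value", "orientation") %in% names(stats)))
  methods <- unique(stats$method)
  if (length(methods) < 2) stop("at least two methods are required")
  per_stat <- split(stats, stats$stat)
  sets <- lapply(per_stat, function(d) sort(d$method))
  if (length(unique(vapply(sets, paste, "", collapse = "|"))) != 1) {
    stop("all methods must share an identical statistic set")
  }
  z <- dplyr::bind_rows(lapply(per_stat, function(d) {
    v <- vapply(seq_len(nrow(d)),
                function(i) orient_value(d$value[i], d$orientation[i]), 0)
    s <- stats::sd(v)
    d$z <- if (is.na(s) || s == 0) rep(0, nrow(d)) else (v - mean(v)) / s
    d
  }))
  summary <- z |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(sum_z = sum(.data$z),
                     loo_max = sum(.data$z) - min(.data$z),
                     loo_min = sum(.data$z) - max(.data$z),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$sum_z))
  structure(list(z = z, summary = summary, stats = stats),
            class = "zscore_table")
}

#' @export
print.zscore_table <- function(x, ...) {
  cat("z-score ranking over", length(unique(x$z$stat)), "statistics and",
      nrow(x$summary), "methods\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a z-score table into a long tibble
#'
#' @param x a `zscore_table`
#' @param ... unused
#' @return long tibble with `method`, `stat`, `value`, `orientation`, `z`
#' @export
tidy.zscore_table <- function(x, ...) {
  tibble::as_tibble(x$z[, c("method", "stat", "value", "orientation", "z")])
}

#' One-row-per-method summary of a z-score table
#'
#' @param x a `zscore_table`
#' @param ... unused
#' @return tibble with `method`, `sum_z`, `loo_min`, `loo_max`
#' @export
glance.zscore_table <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' One-sided Wilcoxon rank-sum test over z-scores
#'
#' Tests whether the first method's z-scores are stochastically greater than
#' the second's (rank-sum over the pooled values). Exact mid-rank permutation
#' p-value when the pooled sample size is at most 20; tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param z_a,z_b numeric z-score vectors
#' @return one-sided p-value for "a greater than b"
#' @export
wilcoxon_one_sided <- function(z_a, z_b) {
  na <- length(z_a); nb <- length(z_b)
  pooled <- c(z_a, z_b)
  n <- na + nb
  if (n <= 20) {
    r <- rank(pooled)  # mid-ranks under ties
    obs <- sum(r[seq_len(na)])
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(r[combos], nrow = na))
    mean(sums >= obs - 1e-9)
  } else {
    suppressWarnings(
      stats::wilcox.test(z_a, z_b, alternative = "greater", exact = FALSE,
                         correct = TRUE)$p.value)
  }
}

#' Pairwise one-sided Wilcoxon p-values between ranked methods
#'
#' @param ranking a `zscore_table`
#' @return tibble of ordered method pairs (`better`, `worse`, `p_value`),
#'   higher-ranked method first
#' @export
pairwise_wilcoxon <- function(ranking) {
  ord <- ranking$summary$method
  zl <- split(ranking$z$z, ranking$z$method)
  out <- list()
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i >= j) next
      out[[length(out) + 1L]] <- tibble::tibble(
        better = ord[i], worse = ord[j],
        p_value = wilcoxon_one_sided(zl[[ord[i]]], zl[[ord[j]]]))
    }
  }
  dplyr::bind_rows(out)
}
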