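# Tidiers and plots for run reports and hit tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a run report into one row per pipeline stage
#'
#' @param x A `run_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with columns `stage` and `hits`, in pipeline order.
#' @export
tidy.run_report <- function(x, ...) {
  tibble(
    stage = factor(
      c("parsed", "merged", "filtered", "best_n", "extracted"),
      levels = c("parsed", "merged", "filtered", "best_n", "extracted")
    ),
    hits = c(
      x$hits_parsed, x$hits_after_merge, x$hits_after_filter,
      x$hits_after_best_n, x$sequences_extracted
    )
  )
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.run_report
#' @return A one-row tibble of run totals and elapsed time.
#' @export
glance.run_report <- function(x, ...) {
  tibble(
    hits_parsed = x$hits_parsed,
    hits_after_merge = x$hits_after_merge,
    hits_after_filter = x$hits_after_filter,
    hits_after_best_n = x$hits_after_best_n,
    groups = x$groups,
    sequences_extracted = x$sequences_extracted,
    n_warnings = length(x$warnings),
    elapsed_s = x$elapsed
  )
}

#' Bar chart of hit counts surviving each pipeline stage
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.run_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$stage, y = .data$hits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$hits), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "hits",
      title = "Hits surviving each pipeline stage"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of hit span lengths, colored by group
#'
#' Useful for judging length-filter thresholds: merged full-length loci and
#' fragmentary hits separate clearly on this axis.
#'
#' @param hits A hit tibble.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_hit_lengths <- function(hits, bins = 30) {
  validate_hits(hits)
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$seq_length, fill = .data$group_label)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8, position = "identity") +
    ggplot2::labs(
      x = "hit span (bases)", y = "count", fill = "group",
      title = "Hit length distribution"
    ) +
    ggplot2::theme_minimal()
}
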