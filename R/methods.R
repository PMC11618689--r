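# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @rdname burden_test
#' @param x A `raretrio_burden` object.
#' @param ... Unused.
tidy.raretrio_burden <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
#' @rdname burden_test
glance.raretrio_burden <- function(x, ...) {
  tibble::tibble(
    n_affected = attr(x, "n_affected"),
    n_unaffected = attr(x, "n_unaffected"),
    n_categories = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    n_perm = attr(x, "n_perm")
  )
}

#' @export
#' @rdname sea_enrichment
#' @param x A `sea_enrichment` object.
#' @param ... Unused.
tidy.sea_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
#' @rdname sea_enrichment
glance.sea_enrichment <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_significant = sum(x$significant),
    min_q = if (nrow(x) > 0) min(x$q_value) else NA_real_,
    alpha = attr(x, "alpha")
  )
}

#' Plot enrichment q-values per gene set
#'
#' Bar chart of -log10 q-values with the significance level marked.
#'
#' @param object A `sea_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sea_enrichment <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(neglog_q = -log10(pmax(q_value, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(set_id, neglog_q),
                                  y = neglog_q, fill = significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "q-value"),
                  fill = "q < alpha") +
    ggplot2::theme_minimal()
}

#' Plot per-category burden comparison
#'
#' Group means per burden category for affected vs unaffected samples.
#'
#' @param object A `raretrio_burden` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raretrio_burden <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c(mean_affected, mean_unaffected),
                        names_to = "group", values_to = "mean_count") |>
    dplyr::mutate(group = sub("mean_", "", group))
  ggplot2::ggplot(d, ggplot2::aes(x = category, y = mean_count,
                                  fill = group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean rare variants per sample",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-exome counts across filtration stages
#'
#' Distribution of per-sample variant counts at each pipeline stage, on a
#' log10 scale.
#'
#' @param counts Output of [summarize_exome_counts()].
#' @return A ggplot object.
#' @export
plot_exome_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = stage, y = n)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pipeline stage", y = "variants per exome (log10)") +
    ggplot2::theme_minimal()
}

#' Plot CNV call fates
#'
#' Counts of CNV segments by dropped reason (kept calls shown as "none"),
#' split by direction where assigned.
#'
#' @param calls Output of [cnv_pipeline()].
#' @return A ggplot object.
#' @export
plot_cnv_fates <- function(calls) {
  d <- calls |>
    dplyr::count(dropped_reason,
                 direction = dplyr::coalesce(direction, "unassigned"))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(dropped_reason, n),
                                  y = n, fill = direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "segments") +
    ggplot2::theme_minimal()
}
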