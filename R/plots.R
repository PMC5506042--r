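#' Plot an eigen decomposition
#'
#' `type = "scree"` shows each component's contribution percentage (linear in
#' the singular values); `type = "loadings"` shows the sorted sample loadings
#' of the requested components, colored by diet and labeled by week — the
#' standard way to read the macro-biology of a component.
#'
#' @param object an [eigen_decompose()] result.
#' @param type `"scree"` or `"loadings"`.
#' @param components components shown when `type = "loadings"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eigen_decomposition <- function(object, type = c("loadings", "scree"),
                                         components = 1:2, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    d <- tidy(object, "d")
    return(
      ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$percent)) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::geom_line(ggplot2::aes(y = .data$cum_percent), color = "firebrick") +
        ggplot2::geom_point(ggplot2::aes(y = .data$cum_percent), color = "firebrick") +
        ggplot2::labs(x = "component", y = "contribution (%)",
                      title = "Singular value contributions") +
        ggplot2::theme_minimal()
    )
  }
  components <- components[components <= length(object$rho)]
  v <- tidy(object, "v", components = components) |>
    dplyr::group_by(.data$component) |>
    dplyr::arrange(.data$loading, .by_group = TRUE) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(
    v, ggplot2::aes(x = .data$position, y = .data$loading)
  )
  if ("diet" %in% names(v)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$diet))
  } else {
    p <- p + ggplot2::geom_col(fill = "grey35")
  }
  if ("week" %in% names(v)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = paste0("W", .data$week)),
      size = 2.5, vjust = -0.3
    )
  }
  p +
    ggplot2::facet_wrap(~component, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample (sorted by loading)", y = "loading",
                  title = "Sorted sample-eigenvector loadings") +
    ggplot2::theme_minimal()
}

#' Plot the strongest enrichment results
#'
#' Bar chart of the smallest Bonferroni-adjusted p-values from
#' [enrich_collection()] (optionally per component from a pipeline report),
#' signed by the enriched end.
#'
#' @param enrichment tibble from [enrich_collection()] or the `enrichment`
#'   field of a [run_dual_eigen()] report.
#' @param top_n sets shown.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top_n = 10) {
  d <- enrichment |>
    dplyr::slice_min(.data$p_adjusted, n = top_n, with_ties = FALSE) |>
    dplyr::mutate(
      neglog = -log10(pmax(.data$p_adjusted, 1e-300)),
      signed = ifelse(.data$end == "high", .data$neglog, -.data$neglog)
    )
  ggplot2::ggplot(
    d, ggplot2::aes(x = stats::reorder(.data$set, .data$signed),
                    y = .data$signed, fill = .data$end)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 adjusted p (signed by end)",
                  title = "Gene-set enrichment at eigenvector ends") +
    ggplot2::theme_minimal()
}

#' @rdname run_dual_eigen
#' @param object a `dual_eigen_report`.
#' @export
autoplot.dual_eigen_report <- function(object, ...) {
  autoplot(object$pooled, type = "loadings",
           components = seq_len(nrow(object$components)))
}
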