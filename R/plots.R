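# ggplot2 views of the result types.

#' Bar chart of gene outcome classes
#'
#' @param report An [evaluate_report()] result (or a tibble with
#'   `outcome` and `n` columns).
#' @return A ggplot object.
#' @export
plot_gene_outcomes <- function(report) {
  tbl <- if (inherits(report, "annotation_report")) {
    report$gene_outcomes
  } else {
    report
  }
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$outcome, y = .data$n,
                                    fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "gene outcome", y = "reference genes") +
    ggplot2::theme_minimal()
}

#' ECDF comparison of per-gene F1 samples
#'
#' @param ... Named numeric vectors of per-gene F1 scores (or a single
#'   named list of them).
#' @return A ggplot object with one ECDF per sample.
#' @export
plot_f1_ecdf <- function(...) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]]) &&
        !is.numeric(samples[[1]])) {
    samples <- samples[[1]]
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample_", seq_along(samples))
  }
  tbl <- purrr::imap_dfr(samples, function(v, nm) {
    tibble::tibble(label = nm, F1 = as.numeric(v))
  })
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$F1, colour = .data$label)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "per-gene F1", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the pipeline agreement partition
#'
#' @param partition An [agreement_partition()] result.
#' @param category Which outcome category to show (default `"match"`).
#' @return A ggplot object of counts per 1000 reference genes by pipeline
#'   subset.
#' @export
plot_agreement <- function(partition, category = "match") {
  tbl <- partition$cells[partition$cells$category == category, ]
  tbl$pipelines <- stats::reorder(tbl$pipelines, -tbl$n_pipelines)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$pipelines,
                                    y = .data$per_1000)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "pipeline subset", y = "genes per 1000 reference",
                  title = paste0("outcome: ", category)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.annotation_report <- function(object, ...) {
  plot_gene_outcomes(object)
}

#' @exportS3Method ggplot2::autoplot
autoplot.agreement_partition <- function(object, ...) {
  plot_agreement(object, ...)
}
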