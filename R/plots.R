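#' Occupancy overview plots
#'
#' Histograms of per-gene taxon occupancy and per-taxon gene occupancy from
#' an [occupancy_report()].
#'
#' @param report an [occupancy_report()] result.
#' @return a ggplot object.
#' @export
plot_occupancy <- function(report) {
  df <- bind_rows(
    tibble(what = "taxa per gene", fraction = report$per_gene$taxon_fraction),
    tibble(what = "genes per taxon", fraction = report$per_taxon$gene_fraction)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0, fill = "steelblue") +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "occupancy fraction", y = "count",
                  title = sprintf("Matrix completeness %.1f%%",
                                  report$completeness)) +
    ggplot2::theme_minimal()
}
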