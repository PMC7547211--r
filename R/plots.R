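#' Chromosome paint of marker genotypes
#'
#' Plots a genotyped marker track as one horizontal bar per chromosome,
#' coloured by genotype: grey heterozygous, blue homozygous parent 1, red
#' homozygous parent 2 -- the standard allelic-profile view of a hybrid
#' diploid clone.
#'
#' @param track Tibble from [call_marker_genotypes()].
#' @return A ggplot object.
#' @export
plot_genotype_track <- function(track) {
  d <- dplyr::filter(track, .data$genotype != "missing")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$chrom,
                                  colour = .data$genotype)) +
    ggplot2::geom_point(shape = 15, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(
      het = "grey70", hom_p1 = "#2166ac", hom_p2 = "#b2182b"
    )) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "genotype") +
    ggplot2::theme_minimal()
}

#' Plot per-passage lineage dynamics
#'
#' Line plot of new mutations, fixations, eliminations and LOH changes per
#' passage from a [lineage_report()] table.
#'
#' @param report Tibble from [lineage_report()].
#' @return A ggplot object.
#' @export
plot_lineage_report <- function(report) {
  d <- report |>
    dplyr::select("passage", "n_new_mutations", "n_fixations",
                  "n_eliminations", "n_new_loh", "n_extended_loh") |>
    tidyr::pivot_longer(-"passage", names_to = "event", values_to = "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$passage, y = .data$n,
                                  colour = .data$event)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "passage", y = "events") +
    ggplot2::theme_minimal()
}
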