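#' Plot a site frequency spectrum
#'
#' Unfolded SFS, optionally contrasting the full sample with an ascertained
#' panel to visualise ascertainment distortion.
#'
#' @param pop a [simulate_base()] result.
#' @param panel optional `marker_panel` whose SFS is overlaid.
#' @param sequences sequence rows for the spectrum (default first breed).
#' @param max_class largest allele-count class shown.
#' @return a ggplot object.
#' @export
plot_sfs <- function(pop, panel = NULL, sequences = NULL, max_class = 50L) {
  sfs <- site_frequency_spectrum(pop, sequences) %>%
    mutate(set = "all sites")
  if (!is.null(panel)) {
    if (is.null(sequences)) sequences <- breed1_sequences(pop)
    k <- length(sequences)
    cnt <- hap_col_counts_cpp(pop$haplotypes,
                              as.integer(sequences))[panel$sites]
    cnt <- cnt[cnt > 0 & cnt < k]
    sfs_p <- tibble(count = seq_len(k - 1),
                    n_sites = tabulate(cnt, nbins = k - 1),
                    set = panel$label)
    sfs <- bind_rows(sfs, sfs_p)
  }
  sfs %>%
    filter(.data$count <= max_class) %>%
    ggplot2::ggplot(ggplot2::aes(.data$count, .data$n_sites)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~set, scales = "free_y") +
    ggplot2::labs(x = "derived allele count", y = "number of sites")
}

#' Plot accuracies across methods
#'
#' Per-replicate accuracies (points) and scenario means (crossbars) for
#' every evaluation method, mirroring the standard strategy-comparison
#' figure of genomic-selection simulation studies.
#'
#' @param x a `scenario_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scenario_result <- function(x, ...) {
  ord <- x$summary %>% arrange(.data$mean_accuracy)
  x$results %>%
    mutate(method = factor(.data$method, levels = ord$method)) %>%
    ggplot2::ggplot(ggplot2::aes(.data$method, .data$accuracy)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = "cross-validation accuracy") +
    ggplot2::coord_flip()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
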