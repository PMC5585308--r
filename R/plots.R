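#' Plot PCA sample scores
#'
#' @param object a `pca_qc` result.
#' @param pcs which two components to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pca_qc <- function(object, pcs = c(1, 2), ...) {
  xv <- paste0("PC", pcs[1]); yv <- paste0("PC", pcs[2])
  lab <- function(i) sprintf("PC%d (%.1f%%)", pcs[i],
                             100 * object$fractions[pcs[i]])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[xv]], .data[[yv]],
                               colour = .data$layer,
                               shape = .data$age)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot representative module profiles
#'
#' Standardized representative expression of each module across the
#' samples, faceted by module, coloured by layer.
#'
#' @param profiles tibble from [module_profiles()].
#' @return a ggplot.
#' @export
plot_module_profiles <- function(profiles) {
  profiles <- mutate(profiles, age = factor(.data$age, levels = the_ages))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$age, .data$representative,
                               colour = .data$layer,
                               group = interaction(.data$module,
                                                   .data$layer))) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(y = "representative z-scored expression") +
    ggplot2::theme_minimal()
}

#' Dot-matrix plot of enrichment results
#'
#' Terms against gene sets; dot size is the (capped) odds ratio and colour
#' the (capped) -log10 adjusted p, the usual over-representation summary
#' display.
#'
#' @param dot_matrix long tibble from [export_dot_matrix()].
#' @return a ggplot.
#' @export
plot_dot_matrix <- function(dot_matrix) {
  ggplot2::ggplot(dot_matrix,
                  ggplot2::aes(.data$gene_set, .data$term_name,
                               size = .data$or_capped,
                               colour = .data$neg_log_p_capped)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "-log10 adj. p") +
    ggplot2::scale_size_continuous(name = "odds ratio") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Empirical CDFs of pair correlations for the skew test
#'
#' @param skew result of [correlation_skew_test()].
#' @return a ggplot of the conserved and control rho ECDFs.
#' @export
plot_correlation_skew <- function(skew) {
  ggplot2::ggplot(skew$ecdf_data,
                  ggplot2::aes(.data$rho, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "Spearman rho", y = "ECDF",
                  subtitle = sprintf("one-sided Mann-Whitney p = %.2g",
                                     skew$p_one_sided)) +
    ggplot2::theme_minimal()
}
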