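#' @export
tidy.tasep_sim <- function(x, ...) {
  tibble::tibble(site = seq_along(x$density), density = x$density)
}

#' @export
glance.tasep_sim <- function(x, ...) {
  tibble::tibble(translation_rate = x$translation_rate,
                 flux_se = x$flux_se,
                 terminations = x$terminations,
                 initiations = x$initiations,
                 collisions = x$collisions,
                 mean_density = mean(x$density),
                 t_measure = x$t_measure)
}

#' Ribosome density profile of a TASEP simulation
#' @param object a `tasep_sim`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.tasep_sim <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$site, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "codon site", y = "occupancy",
                  title = sprintf("Ribosome density (flux %.3g /s)",
                                  object$translation_rate)) +
    ggplot2::theme_minimal()
}

#' Predicted New_TR against the observed response
#' @param object a `newtr_fit`.
#' @param responses the response table the fit was scored on.
#' @param ... unused.
#' @return A ggplot (log10 response vs New_TR).
#' @export
autoplot.newtr_fit <- function(object, responses, ...) {
  dat <- dplyr::inner_join(tidy(object), responses, by = "gene_id")
  ycol <- response_column(object$spec$target)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$new_tr, y = log10(.data[[ycol]]))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "New_TR", y = paste0("log10 ", object$spec$target),
                  subtitle = sprintf("Spearman: test %.3f, total %.3f",
                                     object$spearman_test, object$spearman_total)) +
    ggplot2::theme_minimal()
}

#' Best Spearman score per subset size of the feature search
#' @param object a `feature_search`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.feature_search <- function(object, ...) {
  ggplot2::ggplot(object$best, ggplot2::aes(x = .data$k, y = .data$spearman_test)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of features combined with New_TR",
                  y = "best test-set Spearman") +
    ggplot2::theme_minimal()
}

#' Positional nucleotide frequencies around the start codon
#' @param freq tibble from [nucleotide_frequency_matrix()].
#' @return A ggplot of per-position A/C/G/T frequencies.
#' @export
plot_nucleotide_frequency <- function(freq) {
  long <- tidyr::pivot_longer(freq, cols = c("A", "C", "G", "T"),
                              names_to = "base", values_to = "freq")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$freq,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position (start codon = +1..+3)", y = "frequency") +
    ggplot2::theme_minimal()
}
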