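#' Plot a coverage time course
#'
#' One line per time point: the advancing polymerase wave, with intronic
#' dips as splicing removes intron signal.
#'
#' @param object A `coverage_tc` tibble (one gene, or faceted by gene).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_tc <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$coverage,
                                    colour = factor(.data$time))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (nt from TSS)", y = "coverage",
                  colour = "time (min)") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$gene_id) > 1) {
    p <- p + ggplot2::facet_wrap(~gene_id, scales = "free")
  }
  p
}

#' Plot observed vs fitted coverage for a rate fit
#'
#' @param object A `skater_fit`.
#' @param ... Unused.
#' @return A ggplot, faceted by time point.
#' @export
autoplot.skater_fit <- function(object, ...) {
  pred <- vapply(object$times, function(tt) {
    expected_coverage(object$model, object$rates, tt, bins = object$positions)
  }, numeric(length(object$positions)))
  df <- bind_rows(
    tidyr::expand_grid(time = object$times, position = object$positions) %>%
      arrange(.data$time) %>%
      mutate(coverage = as.vector(object$observed), kind = "observed"),
    tidyr::expand_grid(time = object$times, position = object$positions) %>%
      arrange(.data$time) %>%
      mutate(coverage = as.vector(pred), kind = "fitted")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$coverage,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(title = object$gene_id, x = "position (nt)", y = "coverage") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of differential inclusion
#'
#' @param records A [delta_psi_test()] result.
#' @param fdr_threshold Highlight threshold (default 0.05).
#' @return A ggplot.
#' @export
plot_delta_psi <- function(records, fdr_threshold = 0.05) {
  df <- filter(records, !is.na(.data$q)) %>%
    mutate(significant = .data$q < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_psi, -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta * Psi), y = "-log10(FDR)") +
    ggplot2::theme_minimal()
}

#' Distribution of the transcription-block decay statistic by condition
#'
#' @param decay Tibble with `condition` and `delta` columns.
#' @return A ggplot.
#' @export
plot_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(.data$condition, .data$delta,
                                      fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = expression(log[2] * "(+block / -block)"), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Nucleotide probabilities around a splice site
#'
#' @param profile A `splice_site_profile`.
#' @return A stacked-bar ggplot over window offsets.
#' @export
plot_splice_site_profile <- function(profile) {
  df <- as_tibble(unclass(profile), rownames = "base") %>%
    tidyr::pivot_longer(-"base", names_to = "offset", values_to = "prob") %>%
    mutate(offset = factor(.data$offset, levels = colnames(profile)))
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$prob,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = sprintf("%s splice site", attr(profile, "site")),
                  x = "offset", y = "probability") +
    ggplot2::theme_minimal()
}
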