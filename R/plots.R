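#' Plot a simulation study
#'
#' Line plot of the per-cell median metric value (points for repetitions)
#' against the varied condition, colored by method and faceted by metric.
#'
#' @param object A `grn_study` from [run_simulation_study()].
#' @param x_var Grid variable for the x axis (`"n_samples"`, `"snr_db"` or
#'   `"fp_ratio"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_study <- function(object, x_var = c("n_samples", "snr_db",
                                                 "fp_ratio"), ...) {
  x_var <- match.arg(x_var)
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$value))
  med <- dplyr::summarise(
    dplyr::group_by(df, .data[[x_var]], .data$metric, .data$method),
    value = median(.data$value), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(.data[[x_var]], .data$value,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df, alpha = 0.4, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = x_var, y = "metric value", colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot GibbsOS sampling frequencies
#'
#' Top candidate genes per TF by post-burn-in sampling frequency.
#'
#' @param object A `gibbsos_fit`.
#' @param top_n Candidates shown per TF.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gibbsos_fit <- function(object, top_n = 5, ...) {
  df <- dplyr::slice_max(dplyr::group_by(object$frequency, .data$tf),
                         .data$frequency, n = top_n, with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency,
                                   stats::reorder(.data$gene, .data$frequency))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$tf), scales = "free_y") +
    ggplot2::labs(x = "sampling frequency", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot bootstrap score distributions
#'
#' Boxplots of the per-resample enrichment scores per TF (capped at the score
#' cap), faceted by direction, with the identification threshold drawn.
#'
#' @param object A `bootstrap_report`.
#' @param min_confidence Only TFs at or above this confidence are shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_report <- function(object, min_confidence = 0, ...) {
  keep <- dplyr::filter(object$confidence,
                        .data$confidence >= min_confidence)
  df <- dplyr::semi_join(dplyr::filter(object$scores,
                                       is.finite(.data$score)),
                         keep, by = c("tf", "direction"))
  ggplot2::ggplot(df, ggplot2::aes(.data$tf, .data$score)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$score_cut, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "enrichment score") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
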