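# Result-type plots: complexity distribution and risk cross-
# classification (alluvial-style counts), detection-vs-clone-fraction
# curve for recovery reports.

#' Abnormality counts by risk group
#'
#' Dot plot of per-patient countable abnormality counts split by OGM
#' complexity class, with the >= 10 cutoff marked.
#'
#' @param profiles a [count_abnormalities()] tibble.
#' @param cutoff complexity cutoff to mark.
#' @return A ggplot object.
#' @export
plot_complexity <- function(profiles, cutoff = 10) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$ogm_class, y = .data$n_ogm)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Countable abnormalities by OGM") +
    ggplot2::theme_minimal()
}

#' Cross-classification of OGM and conventional risk
#'
#' Tile plot of patient counts for OGM complexity class against the
#' combined high-complexity flag (>= 5 abnormalities by CBA and/or CMA).
#'
#' @param profiles a [count_abnormalities()] tibble with `combined_high`.
#' @return A ggplot object.
#' @export
plot_risk_cross <- function(profiles) {
  counts <- profiles |>
    dplyr::count(.data$combined_high, .data$ogm_class)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$ogm_class,
                               y = .data$combined_high,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::labs(x = "OGM complexity class",
                  y = "High complexity by CBA and/or CMA",
                  fill = "patients") +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_recovery
#' @param object a `recovery_report`.
#' @param ... unused.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$detection_curve,
                  ggplot2::aes(x = .data$cf_bin, y = .data$detection_rate)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Clone fraction", y = "Truth detection rate") +
    ggplot2::theme_minimal()
}
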