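#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_hline facet_wrap
#'   labs theme_minimal scale_colour_manual position_dodge geom_jitter
NULL

#' Plot a mismatch count table
#'
#' Bar chart of singleton-mismatch counts per directed type, coloured by
#' coding-strand stratum and faceted by alignment direction.
#'
#' @param object A `mismatch_counts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mismatch_counts <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(type = paste0(.data$ref, ">", .data$alt))
  ggplot(df, aes(x = .data$type, y = .data$n, fill = .data$strand)) +
    geom_col(position = position_dodge(preserve = "single")) +
    facet_wrap(~direction, ncol = 1) +
    labs(x = "mismatch type (forward reference sense)", y = "singleton sites",
         fill = "coding strand") +
    theme_minimal()
}

#' Plot asymmetry ratios
#'
#' Dot plot of log2 mismatch/complement ratios per pair and mode; the dashed
#' line at 0 marks symmetry.
#'
#' @param object An `asymmetry_result` tibble from [asymmetry_ratios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asymmetry_result <- function(object, ...) {
  df <- as_tibble(object) %>% filter(.data$type < .data$complement)
  ggplot(df, aes(x = .data$pair, y = .data$log2_ratio, colour = .data$mode)) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_point(size = 3, position = position_dodge(width = 0.4)) +
    labs(x = "mismatch/complement pair", y = "log2 ratio", colour = "mode") +
    theme_minimal()
}

#' Plot per-batch asymmetry summaries
#'
#' Batch medians of per-sample ratios, with the flagged top fraction
#' highlighted — the flowcell-level view used to spot shared artefact
#' intensity.
#'
#' @param object A `batch_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.batch_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = stats::reorder(.data$batch, .data$median_ratio),
                 y = .data$median_ratio, colour = .data$top_flag)) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    geom_point(size = 3) +
    scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    labs(x = "batch", y = "median ratio", colour = "top decile") +
    theme_minimal()
}
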