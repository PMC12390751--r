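.sum_counts <- function(table, ..., filter_class = NULL) {
  df <- as_tibble(table)
  if ("filter_class" %in% names(df)) {
    fc <- filter_class %||% "all"
    df <- df[df$filter_class == fc, , drop = FALSE]
  }
  value_col <- if ("rate" %in% names(df)) "rate" else "n"
  conds <- list(...)
  keep <- rep(TRUE, nrow(df))
  for (nm in names(conds)) keep <- keep & df[[nm]] %in% conds[[nm]]
  vals <- df[[value_col]][keep]
  if (value_col == "rate" && any(is.na(vals))) return(NA_real_)
  sum(vals)
}

.asym_result <- function(type, mode, num, den, pseudocount = 0) {
  if (pseudocount > 0) {
    num <- num + pseudocount
    den <- den + pseudocount
  }
  defined <- !is.na(num) && !is.na(den) && den > 0
  ratio <- if (defined) num / den else NA_real_
  structure(
    tibble(
      type = type, complement = complement_of(type),
      pair = pair_label(type), mode = mode,
      numerator = num, denominator = den,
      ratio = ratio,
      log2_ratio = if (defined && ratio > 0) log2(ratio) else NA_real_,
      defined = defined
    ),
    class = c("asymmetry_result", class(tibble()))
  )
}

#' Mismatch-versus-complement asymmetry by reference strand
#'
#' The ratio of the number of mismatches of a type (expressed on the forward
#' strand of the reference genome, all strata pooled) to the number of its
#' complementary mismatches — equivalently, the same mismatch read off the
#' reverse reference strand. A ratio above 1 for G>T/C>A is the signature of
#' capture-strand-biased oxidative damage.
#'
#' @param table A `mismatch_counts`, `normalized_counts`, or `variant_counts`
#'   tibble. For `variant_counts`, `filter_class` selects `"all"` (default)
#'   or `"pass"` calls.
#' @param type Mismatch type, e.g. `"G>T"`.
#' @param pseudocount Added to numerator and denominator when positive
#'   (default 0: a zero denominator yields an undefined, flagged result).
#' @param filter_class For variant tables only.
#' @return A one-row `asymmetry_result` tibble with `numerator`,
#'   `denominator`, `ratio`, `log2_ratio`, `defined`.
#' @examples
#' cnt <- variant_count_table(data.frame(
#'   ref = c("G", "C"), alt = c("T", "A"), strand = "+",
#'   filter_class = "all", n = c(403L, 195L)))
#' reference_strand_ratio(cnt, "G>T")
#' @export
reference_strand_ratio <- function(table, type, pseudocount = 0,
                                   filter_class = NULL) {
  comp <- complement_of(type)
  num <- .sum_counts(table, ref = substr(type, 1, 1), alt = substr(type, 3, 3),
                     filter_class = filter_class)
  den <- .sum_counts(table, ref = substr(comp, 1, 1), alt = substr(comp, 3, 3),
                     filter_class = filter_class)
  .asym_result(type, "reference", num, den, pseudocount)
}

#' Mismatch-versus-complement asymmetry by transcription strand
#'
#' Re-expresses counts relative to the transcription template strand of the
#' overlapping gene and forms the template/coding ratio. At a `+` gene the
#' template is the reverse strand, so a forward-sense type contributes to the
#' template tally through its complement; at a `-` gene the template is the
#' forward strand and the type contributes as-is. Strata without an
#' unambiguous coding direction (`strand = "none"`) are excluded.
#'
#' @inheritParams reference_strand_ratio
#' @return A one-row `asymmetry_result` tibble (`mode = "transcription"`).
#' @export
transcription_strand_ratio <- function(table, type, pseudocount = 0,
                                       filter_class = NULL) {
  comp <- complement_of(type)
  g <- function(t, strand) {
    .sum_counts(table, ref = substr(t, 1, 1), alt = substr(t, 3, 3),
                strand = strand, filter_class = filter_class)
  }
  template <- g(comp, "+") + g(type, "-")
  coding <- g(type, "+") + g(comp, "-")
  .asym_result(type, "transcription", template, coding, pseudocount)
}

#' Mismatch asymmetry by read alignment direction
#'
#' The ratio of a mismatch type's count on forward-aligned reads to its count
#' on reverse-aligned reads. Orientation-tagged oxidative lesions deviate
#' from 1 in the direction of the lesion strand.
#'
#' @inheritParams reference_strand_ratio
#' @return A one-row `asymmetry_result` tibble (`mode = "alignment_direction"`).
#' @export
alignment_direction_ratio <- function(table, type, pseudocount = 0,
                                      filter_class = NULL) {
  r <- substr(type, 1, 1)
  a <- substr(type, 3, 3)
  num <- .sum_counts(table, ref = r, alt = a, direction = "forward",
                     filter_class = filter_class)
  den <- .sum_counts(table, ref = r, alt = a, direction = "reverse",
                     filter_class = filter_class)
  .asym_result(type, "alignment_direction", num, den, pseudocount)
}

#' All asymmetry ratios of a count table
#'
#' Convenience wrapper computing one [reference_strand_ratio()],
#' [transcription_strand_ratio()], or [alignment_direction_ratio()] row per
#' mismatch type.
#'
#' @inheritParams reference_strand_ratio
#' @param mode `"reference"`, `"transcription"`, or `"alignment_direction"`.
#' @param types Mismatch types to report (default all twelve).
#' @return An `asymmetry_result` tibble with one row per type.
#' @export
asymmetry_ratios <- function(table, mode = c("reference", "transcription",
                                             "alignment_direction"),
                             types = mismatch_types(), pseudocount = 0,
                             filter_class = NULL) {
  mode <- match.arg(mode)
  fn <- switch(mode,
    reference = reference_strand_ratio,
    transcription = transcription_strand_ratio,
    alignment_direction = alignment_direction_ratio
  )
  out <- purrr::map(types, fn, table = table, pseudocount = pseudocount,
                    filter_class = filter_class) %>% bind_rows()
  structure(out, class = c("asymmetry_result", class(tibble())))
}

#' Per-batch (flowcell) summaries of per-sample asymmetry ratios
#'
#' Samples sequenced together on the same flowcell tend to share artefact
#' intensity; this summarises per-sample ratios by batch and flags the
#' batches whose median ratio falls in the top fraction (default: the top
#' decile, ties at the boundary all flagged). Outliers within a batch are
#' samples beyond 1.5 x IQR of the batch's quartiles. Non-finite or missing
#' ratios are excluded with a note.
#'
#' @param data A data frame with columns `sample`, `ratio`, `batch`.
#' @param top_fraction Fraction of batches to flag by highest median ratio.
#' @return A `batch_summary` tibble: `batch`, `n_samples`, `median_ratio`,
#'   `sd_ratio`, `outlier_samples` (list-column), `top_flag`.
#' @examples
#' batch_summary(data.frame(sample = letters[1:6], ratio = c(1, 2, 3, 2, 2, 9),
#'                          batch = rep(c("fc1", "fc2"), each = 3)))
#' @export
batch_summary <- function(data, top_fraction = 0.1) {
  stopifnot(all(c("sample", "ratio", "batch") %in% names(data)))
  df <- as_tibble(data)
  if (nrow(df) == 0) {
    return(structure(
      tibble(batch = character(), n_samples = integer(),
             median_ratio = double(), sd_ratio = double(),
             outlier_samples = list(), top_flag = logical()),
      class = c("batch_summary", class(tibble()))))
  }
  bad <- !is.finite(df$ratio)
  if (any(bad)) {
    inform(paste0(sum(bad), " sample(s) with undefined ratio excluded from batch summary"))
    df <- df[!bad, , drop = FALSE]
  }
  out <- df %>%
    group_by(.data$batch) %>%
    summarise(
      n_samples = dplyr::n(),
      median_ratio = median(.data$ratio),
      sd_ratio = sd(.data$ratio),
      outlier_samples = list({
        q <- quantile(.data$ratio, c(0.25, 0.75), names = FALSE, type = 7)
        iqr <- q[2] - q[1]
        as.character(.data$sample[.data$ratio < q[1] - 1.5 * iqr |
                                    .data$ratio > q[2] + 1.5 * iqr])
      }),
      .groups = "drop"
    )
  b <- nrow(out)
  k <- ceiling(top_fraction * b)
  thr <- sort(out$median_ratio, decreasing = TRUE)[max(k, 1L)]
  out$top_flag <- if (k >= 1) out$median_ratio >= thr else rep(FALSE, b)
  structure(out, class = c("batch_summary", class(tibble())))
}
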