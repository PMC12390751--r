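#' Tidy a capture-region set
#' @param x A [capture_regions] object.
#' @param ... Unused.
#' @return A plain tibble of regions.
#' @export
tidy.capture_regions <- function(x, ...) {
  as_tibble(unclass(x)[names(x) %in% c("chrom", "start", "end", "name",
                                       "score", "strand")])
}

#' One-row summary of a capture-region set
#' @param x A [capture_regions] object.
#' @param ... Unused.
#' @return Tibble with region, base and ambiguity totals.
#' @export
glance.capture_regions <- function(x, ...) {
  amb <- attr(x, "ambiguous")
  tibble(
    n_regions = nrow(x),
    total_bases = sum(x$end - x$start),
    ambiguous_bases = if (is.null(amb)) 0L else sum(amb$end - amb$start),
    n_chroms = dplyr::n_distinct(x$chrom)
  )
}

#' Tidy a mismatch count table
#' @param x A `mismatch_counts` tibble.
#' @param ... Unused.
#' @return A plain tibble with a `type` column added.
#' @export
tidy.mismatch_counts <- function(x, ...) {
  as_tibble(x) %>% mutate(type = paste0(.data$ref, ">", .data$alt))
}

#' One-row summary of a mismatch count table
#' @param x A `mismatch_counts` tibble.
#' @param ... Unused.
#' @return Tibble with totals and the site bookkeeping of the singleton rule.
#' @export
glance.mismatch_counts <- function(x, ...) {
  tibble(
    total_mismatches = sum(x$n),
    sites_considered = attr(x, "sites_considered") %||% NA_integer_,
    sites_excluded_multi = attr(x, "sites_excluded_multi") %||% NA_integer_
  )
}

#' One-row summary of a simulated dataset
#' @param x An `oxo_sim` object.
#' @param ... Unused.
#' @return Tibble of simulation scale and truth-event totals.
#' @export
glance.oxo_sim <- function(x, ...) {
  ev <- table(factor(x$truth$event,
                     levels = c("lesion_pre_fwd", "lesion_pre_rev",
                                "lesion_post", "germline", "somatic", "error")))
  dplyr::bind_cols(
    tibble(n_sites = x$config$n_genes * x$config$read_length,
           n_molecules = x$config$n_genes * x$config$depth,
           n_calls = nrow(x$calls)),
    as_tibble(as.list(ev))
  )
}

#' One-row summary of a batch summary
#' @param x A `batch_summary` tibble.
#' @param ... Unused.
#' @return Tibble with batch counts and flagged-batch totals.
#' @export
glance.batch_summary <- function(x, ...) {
  tibble(
    n_batches = nrow(x),
    n_flagged = sum(x$top_flag),
    n_outlier_samples = sum(lengths(x$outlier_samples))
  )
}

#' One-row summary of a pipeline run
#' @param x An `oxo_run` object.
#' @param ... Unused.
#' @return Tibble with the headline G>T/C>A ratios of the run.
#' @export
glance.oxo_run <- function(x, ...) {
  r <- as_tibble(x$ratios)
  pick <- function(mode) {
    v <- r$ratio[r$type == "G>T" & r$mode == mode]
    if (length(v) == 1) v else NA_real_
  }
  tibble(
    gt_ca_reference = pick("reference"),
    gt_ca_transcription = pick("transcription"),
    gt_ca_direction = pick("alignment_direction"),
    total_mismatches = sum(x$counts$n)
  )
}
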