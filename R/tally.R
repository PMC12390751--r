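.new_mismatch_counts <- function(df, sites_considered = NA_integer_,
                                 sites_excluded_multi = NA_integer_) {
  structure(df,
    sites_considered = sites_considered,
    sites_excluded_multi = sites_excluded_multi,
    class = c("mismatch_counts", class(tibble())))
}

# the complete (type x strand x direction) grid with zero counts
.empty_count_grid <- function() {
  grid <- tidyr::expand_grid(
    type = mismatch_types(),
    strand = c("+", "-", "none"),
    direction = c("forward", "reverse")
  )
  grid$ref <- substr(grid$type, 1, 1)
  grid$alt <- substr(grid$type, 3, 3)
  grid$n <- 0L
  grid[, c("ref", "alt", "strand", "direction", "n")]
}

#' Tally singleton mismatches by coding strand and alignment direction
#'
#' The core counting procedure: base-quality filtering, the singleton rule,
#' and stratification of each retained mismatch by the coding strand of the
#' covering capture region and by the alignment direction of the mismatching
#' read. Sites outside all capture regions are ignored; loci with conflicting
#' or absent strand annotation are tallied under `strand = "none"` (they
#' contribute to reference-strand statistics but not transcription-strand
#' ones).
#'
#' @param pileup Pileup input: a path, pileup text lines, or a per-call
#'   tibble from [parse_pileup()].
#' @param regions A [capture_regions] object.
#' @param min_bq Minimum base quality (default 37).
#' @param multiple_alleles Passed to [classify_singleton_sites()].
#' @return A `mismatch_counts` tibble: the full 12 x 3 x 2 grid of
#'   (`ref`,`alt`) x coding strand x alignment direction with integer counts
#'   `n`, plus attributes `sites_considered` and `sites_excluded_multi`.
#' @examples
#' rg <- capture_regions(data.frame(chrom = "sim1", start = 0, end = 10,
#'                                  strand = "+"))
#' tally_mismatches("sim1\t5\tG\t4\t..,T\tIIII", rg)
#' @export
tally_mismatches <- function(pileup, regions, min_bq = 37,
                             multiple_alleles = FALSE) {
  stopifnot(inherits(regions, "capture_regions"))
  calls <- if (is.data.frame(pileup)) pileup else parse_pileup(pileup)
  calls <- filter_pileup_bases(calls, min_bq = min_bq)
  # restrict to captured loci before the singleton rule
  if (nrow(calls) > 0) {
    site_key <- paste(calls$chrom, calls$pos)
    usite <- !duplicated(site_key)
    site_strand <- strand_at(regions, calls$chrom[usite], calls$pos[usite] - 1L)
    strand_map <- setNames(site_strand, site_key[usite])
    calls$site_strand <- unname(strand_map[site_key])
    calls <- calls[calls$site_strand != "outside", , drop = FALSE]
  }
  singles <- classify_singleton_sites(calls, multiple_alleles = multiple_alleles)
  grid <- .empty_count_grid()
  if (nrow(singles) > 0) {
    st <- strand_at(regions, singles$chrom, singles$pos - 1L)
    stratum <- ifelse(st %in% c("+", "-"), st, "none")
    add <- tibble(ref = singles$ref, alt = singles$alt,
                  strand = stratum, direction = singles$direction) %>%
      count(.data$ref, .data$alt, .data$strand, .data$direction, name = "add")
    grid <- grid %>%
      left_join(add, by = c("ref", "alt", "strand", "direction")) %>%
      mutate(n = .data$n + dplyr::coalesce(.data$add, 0L)) %>%
      select(-"add")
  }
  .new_mismatch_counts(grid,
    sites_considered = attr(singles, "sites_considered"),
    sites_excluded_multi = attr(singles, "sites_excluded_multi"))
}

#' Normalize mismatch counts by captured-region nucleotide composition
#'
#' Divides each count by the number of captured positions carrying the
#' relevant reference base. In the `"reference"` frame every count is divided
#' by the forward-sense total of its reference base. In the `"transcription"`
#' frame the `strand = "none"` stratum is dropped, each count is re-keyed to
#' the template strand of its stratum (a forward-sense type at a `+` gene is
#' its complement on the template; at a `-` gene it is unchanged) and divided
#' by the per-stratum composition of its original forward-sense reference
#' base (which equals the template-strand count of the re-keyed base).
#'
#' @param counts A `mismatch_counts` tibble from [tally_mismatches()].
#' @param composition A `nucleotide_composition` from
#'   [composition_of_regions()] over the same regions.
#' @param frame `"reference"` or `"transcription"`.
#' @return A `normalized_counts` tibble with columns `ref`, `alt`, `strand`,
#'   `direction`, `n`, `denominator`, `rate`, `undefined`. A zero denominator
#'   flags the row `undefined` (never silent division); zero counts with a
#'   positive denominator give rate 0.
#' @export
normalize_counts <- function(counts, composition,
                             frame = c("reference", "transcription")) {
  frame <- match.arg(frame)
  stopifnot(inherits(counts, "mismatch_counts"))
  totals <- composition_totals(composition)
  df <- as_tibble(counts)
  if (frame == "reference") {
    df$denominator <- as.integer(totals[df$ref])
  } else {
    df <- df[df$strand != "none", , drop = FALSE]
    strat <- composition %>% rename(comp_count = "count")
    df <- df %>%
      left_join(strat, by = c("strand" = "strand", "ref" = "base")) %>%
      rename(denominator = "comp_count")
    flip <- df$strand == "+"
    newref <- ifelse(flip, complement_base(df$ref), df$ref)
    newalt <- ifelse(flip, complement_base(df$alt), df$alt)
    df$ref <- newref
    df$alt <- newalt
  }
  df$undefined <- df$denominator == 0
  df$rate <- ifelse(df$undefined, NA_real_, df$n / df$denominator)
  structure(df,
    frame = frame,
    class = c("normalized_counts", class(tibble())))
}
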