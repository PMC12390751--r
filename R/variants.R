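#' Read biallelic SNVs from a VCF
#'
#' Ingests VCF 4.x, excluding indels and multiallelic records, and emits one
#' row per (record, carrier sample): samples whose genotype contains the
#' alternative allele. `FILTER`, `QUAL` and genotype class are preserved.
#' Sample roles (`"tumour"`, `"normal"`, `"germline"`) come from `role_map`;
#' a carrier sample without a role is skipped with a warning. VCFs without
#' genotype columns yield one row per record with `sample = NA` and role
#' `"unknown"`.
#'
#' @param vcf Path to a (plain-text or bgzipped) VCF file.
#' @param role_map Named character vector, sample name -> role; `NULL` maps
#'   every sample to `"unknown"`.
#' @return A tibble of SNV records: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `filter`, `qual`, `sample`, `role`, `genotype`
#'   (`"het"`/`"hom"`/`"unknown"`).
#' @export
read_biallelic_snvs <- function(vcf, role_map = NULL) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), filter = character(), qual = double(),
                  sample = character(), role = character(),
                  genotype = character()))
  }
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% .BASES & fix$ALT %in% .BASES
  fix <- fix[keep, , drop = FALSE]
  base <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  has_gt <- ncol(v@gt) > 1
  if (!has_gt) {
    base$sample <- NA_character_
    base$role <- "unknown"
    base$genotype <- "unknown"
    return(base)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  out <- vector("list", length(samples))
  skipped <- character(0)
  for (j in seq_along(samples)) {
    g <- gt[, j]
    alleles <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    n_alt <- vapply(alleles, function(a) sum(a == "1"), 0L)
    n_called <- vapply(alleles, function(a) sum(a %in% c("0", "1")), 0L)
    carrier <- n_alt > 0
    if (!any(carrier)) next
    role <- if (!is.null(role_map)) unname(role_map[samples[j]]) else "unknown"
    if (is.null(role) || is.na(role)) {
      skipped <- c(skipped, samples[j])
      next
    }
    rec <- base[carrier, , drop = FALSE]
    rec$sample <- samples[j]
    rec$role <- role
    rec$genotype <- dplyr::case_when(
      n_alt[carrier] > 0 & n_alt[carrier] == n_called[carrier] ~ "hom",
      n_alt[carrier] > 0 & n_called[carrier] > n_alt[carrier] ~ "het",
      TRUE ~ "unknown"
    )
    out[[j]] <- rec
  }
  if (length(skipped) > 0) {
    warn(paste0("no role for carrier sample(s), skipped: ",
                paste(unique(skipped), collapse = ", ")))
  }
  bind_rows(out)
}

#' Remove records at user-supplied common-variant sites
#'
#' Drops records whose exact (`chrom`, `pos`, `ref`, `alt`) tuple appears in
#' an exclusion list (e.g. common SNPs from a population database). Same
#' position with a different alt is kept.
#'
#' @param records SNV record tibble from [read_biallelic_snvs()].
#' @param exclude_sites Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return The filtered record tibble.
#' @export
filter_common_sites <- function(records, exclude_sites) {
  if (is.null(exclude_sites) || nrow(exclude_sites) == 0) return(records)
  anti_join(records, as_tibble(exclude_sites)[, c("chrom", "pos", "ref", "alt")],
            by = c("chrom", "pos", "ref", "alt"))
}

#' Construct a variant count table
#'
#' @param df Data frame with columns `ref`, `alt`, `strand`, `filter_class`,
#'   `n`; missing grid cells are filled with zero.
#' @return A `variant_counts` tibble over the full
#'   12 types x 3 strands x \{all, pass\} grid.
#' @export
variant_count_table <- function(df) {
  grid <- tidyr::expand_grid(
    type = mismatch_types(), strand = c("+", "-", "none"),
    filter_class = c("all", "pass")
  )
  grid$ref <- substr(grid$type, 1, 1)
  grid$alt <- substr(grid$type, 3, 3)
  grid <- grid[, c("ref", "alt", "strand", "filter_class")]
  df <- as_tibble(df) %>%
    group_by(.data$ref, .data$alt, .data$strand, .data$filter_class) %>%
    summarise(n = sum(.data$n), .groups = "drop")
  out <- grid %>%
    left_join(df, by = c("ref", "alt", "strand", "filter_class")) %>%
    mutate(n = as.integer(dplyr::coalesce(.data$n, 0L)))
  structure(out, class = c("variant_counts", class(tibble())))
}

#' Tally variant calls by coding strand and filter status
#'
#' Each record inside the captured regions is counted under
#' (`type`, coding strand, `"all"`), and additionally under `"pass"` when its
#' FILTER is exactly `"PASS"`. Loci with conflicting or absent strand
#' annotation count under `strand = "none"`; records outside all regions are
#' ignored. `pass <= all` holds componentwise by construction.
#'
#' @param records SNV record tibble.
#' @param regions A [capture_regions] object.
#' @return A `variant_counts` tibble.
#' @export
tally_variants <- function(records, regions) {
  stopifnot(inherits(regions, "capture_regions"))
  if (nrow(records) == 0) return(variant_count_table(tibble(
    ref = character(), alt = character(), strand = character(),
    filter_class = character(), n = integer())))
  st <- strand_at(regions, records$chrom, records$pos - 1L)
  inside <- st != "outside"
  rec <- records[inside, , drop = FALSE]
  stratum <- ifelse(st[inside] %in% c("+", "-"), st[inside], "none")
  all_rows <- tibble(ref = rec$ref, alt = rec$alt, strand = stratum,
                     filter_class = "all")
  pass <- rec$filter == "PASS"
  pass_rows <- tibble(ref = rec$ref[pass], alt = rec$alt[pass],
                      strand = stratum[pass], filter_class = "pass")
  variant_count_table(bind_rows(all_rows, pass_rows) %>%
    count(.data$ref, .data$alt, .data$strand, .data$filter_class, name = "n"))
}

#' Aggregate unique SNV sites across a cohort
#'
#' Collapses per-sample records so that a (chrom, pos, ref, alt) tuple shared
#' by many samples (for example a recurrent driver mutation) is counted once,
#' recording in how many samples it was seen.
#'
#' @param records SNV record tibble with a `sample` column (rows from several
#'   samples concatenated).
#' @return A tibble of unique sites with `n_samples`, carrying attribute
#'   `type_totals`: a tibble of unique-site counts per mismatch type.
#' @export
unique_sites <- function(records) {
  sites <- records %>%
    count(.data$chrom, .data$pos, .data$ref, .data$alt, name = "n_samples")
  totals <- sites %>%
    count(.data$ref, .data$alt, name = "n_sites")
  structure(sites, type_totals = totals,
            class = c("unique_sites", class(tibble())))
}

#' Exact binomial departure from composition-expected asymmetry
#'
#' Tests whether the observed split between a mismatch type and its
#' complement departs from the split expected under the nucleotide
#' composition of the captured regions. The expected probability of the type
#' is `q = n(ref base of type) / (n(ref base of type) + n(ref base of
#' complement))` from forward-sense composition; the p-value is the exact
#' two-sided binomial probability (minimum-likelihood convention: the sum of
#' all outcome probabilities no larger than that of the observation), as
#' computed by [stats::binom.test()].
#'
#' @param n_type Observed count of the type.
#' @param n_complement Observed count of the complement.
#' @param composition A `nucleotide_composition` from
#'   [composition_of_regions()].
#' @param type Mismatch type, e.g. `"G>T"`.
#' @return One-row tibble: `type`, `complement`, `n_type`, `n_complement`,
#'   `expected_prop`, `observed_prop`, `p_value`.
#' @examples
#' rg <- capture_regions(data.frame(chrom = "s", start = 0, end = 8, strand = "+"))
#' comp <- composition_of_regions(rg, c(s = "GGGGCCCC"))
#' binomial_departure(8, 2, comp, "G>T")
#' @export
binomial_departure <- function(n_type, n_complement, composition, type) {
  if (n_type + n_complement <= 0) abort("both counts are zero: nothing to test")
  comp_type <- complement_of(type)
  totals <- composition_totals(composition)
  a <- totals[substr(type, 1, 1)]
  b <- totals[substr(comp_type, 1, 1)]
  if (a + b == 0) abort("composition has no copies of either reference base")
  q <- unname(a / (a + b))
  p <- binom.test(n_type, n_type + n_complement, p = q)$p.value
  tibble(
    type = type, complement = comp_type,
    n_type = as.integer(n_type), n_complement = as.integer(n_complement),
    expected_prop = q,
    observed_prop = n_type / (n_type + n_complement),
    p_value = p
  )
}

#' Trinucleotide context table of mismatch sites
#'
#' Looks up the forward-sense reference 3-mer centred on each site
#' (positions pos-1, pos, pos+1). Sites at chromosome edges are skipped and
#' counted. Fractions are relative to the number of sites with a context.
#' Optionally re-keys contexts to the strand whose central base is a
#' pyrimidine.
#'
#' @param sites Data frame with `chrom` and `pos` (1-based) columns.
#' @param reference FASTA path, named character vector, or `DNAStringSet`.
#' @param frame `"forward"` (default) or `"pyrimidine"` context keying.
#' @return A `context_table` tibble (`context`, `n`, `fraction`) sorted by
#'   decreasing count, with attributes `n_sites` and `n_skipped`. The first
#'   row is the modal context.
#' @examples
#' trinucleotide_context_table(data.frame(chrom = "s", pos = 3), c(s = "AGGCA"))
#' @export
trinucleotide_context_table <- function(sites, reference,
                                        frame = c("forward", "pyrimidine")) {
  frame <- match.arg(frame)
  ref <- .load_reference(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  chrom <- as.character(sites$chrom)
  pos <- as.integer(sites$pos)
  missing_chrom <- setdiff(unique(chrom), names(ref))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from reference: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  len <- setNames(Biostrings::width(ref), names(ref))
  ok <- pos > 1L & pos < len[chrom]
  if (any(!ok)) inform(paste0(sum(!ok), " site(s) at chromosome edges skipped"))
  ctx <- unname(vapply(which(ok), function(i) {
    as.character(Biostrings::subseq(ref[[chrom[i]]], pos[i] - 1L, pos[i] + 1L))
  }, ""))
  if (frame == "pyrimidine" && length(ctx) > 0) {
    centre <- substr(ctx, 2, 2)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx)))
    ctx <- ifelse(centre %in% c("A", "G"), rc, ctx)
  }
  out <- tibble(context = ctx) %>%
    count(.data$context, name = "n") %>%
    arrange(dplyr::desc(.data$n), .data$context) %>%
    mutate(fraction = .data$n / sum(.data$n))
  structure(out, n_sites = length(ctx), n_skipped = sum(!ok),
            class = c("context_table", class(tibble())))
}

#' Fraction of alternative-allele reads in F1R2 orientation
#'
#' The per-site orientation-bias statistic: among reads supporting the
#' alternative allele, the fraction in the F1R2 read-pair orientation class.
#' Balanced true variants sit near 0.5; strand-specific oxidative artefacts
#' approach 0 or 1.
#'
#' @param x Either an integer vector of F1R2 counts (with `n_f2r1` supplied),
#'   or a character vector of per-read orientations (`"F1R2"`/`"F2R1"`).
#' @param n_f2r1 Integer vector of F2R1 counts when `x` is numeric.
#' @return Numeric vector of fractions in `[0, 1]`; `NA` (undefined) when a
#'   record has no orientation-tagged alt reads.
#' @examples
#' orientation_fraction(c("F1R2", "F1R2", "F2R1", "F1R2"))
#' orientation_fraction(3, 1)
#' @export
orientation_fraction <- function(x, n_f2r1 = NULL) {
  if (is.character(x)) {
    if (!all(x %in% c("F1R2", "F2R1"))) {
      abort("orientations must be 'F1R2' or 'F2R1'")
    }
    if (length(x) == 0) return(NA_real_)
    return(mean(x == "F1R2"))
  }
  stopifnot(is.numeric(x), is.numeric(n_f2r1))
  total <- x + n_f2r1
  ifelse(total > 0, x / total, NA_real_)
}

#' Quality-ordered rebalancing filter for excess G>T calls
#'
#' Removes G>T calls beginning with those of lowest quality (ties broken by
#' genomic coordinate order) until the retained count does not exceed the
#' complementary C>A count — eliminating the call asymmetry attributed to
#' oxidative artefacts while preferentially retaining well-supported calls.
#'
#' @param gt_calls Tibble of G>T calls with a quality column (`qual` is used
#'   when present and non-missing, else `alt_reads`) and `chrom`, `pos`.
#' @param ca_count Number of complementary C>A calls (the target ceiling).
#' @return A list with `retained` and `removed` tibbles; `nrow(retained) <=
#'   max(ca_count, 0)` unless no removal was needed.
#' @examples
#' calls <- data.frame(chrom = "1", pos = 1:3, qual = c(10, 20, 30))
#' rebalance_filter(calls, ca_count = 1)
#' @export
rebalance_filter <- function(gt_calls, ca_count) {
  df <- as_tibble(gt_calls)
  qual <- if ("qual" %in% names(df) && !all(is.na(df$qual))) {
    df$qual
  } else if ("alt_reads" %in% names(df)) {
    df$alt_reads
  } else {
    abort("gt_calls needs a 'qual' or 'alt_reads' column to order by quality")
  }
  qual[is.na(qual)] <- -Inf
  n_remove <- max(0L, nrow(df) - max(as.integer(ca_count), 0L))
  if (n_remove == 0L) {
    return(list(retained = df, removed = df[0, , drop = FALSE]))
  }
  ord <- order(qual, df$chrom, df$pos)
  drop_idx <- ord[seq_len(n_remove)]
  list(retained = df[-drop_idx, , drop = FALSE],
       removed = df[drop_idx, , drop = FALSE])
}
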