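#' Capture-kit target regions with coding-strand annotation
#'
#' A `capture_regions` object is a tibble of target intervals (BED-style,
#' 0-based half-open) whose `strand` column records the coding direction of
#' the overlapping gene as annotated in the capture-kit BED: `"+"`, `"-"`, or
#' `"."` for unannotated. Positions covered by two regions with *conflicting*
#' annotated strands are recorded as ambiguous and excluded from
#' transcription-strand statistics (they still contribute to reference-strand
#' statistics).
#'
#' @param regions A data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand` (defaults `"."`).
#' @return A tibble of class `capture_regions` with attribute `ambiguous`, a
#'   tibble of 0-based half-open intervals covered by conflicting strands.
#' @examples
#' capture_regions(data.frame(
#'   chrom = "chr1", start = c(100, 150), end = c(200, 250),
#'   strand = c("+", "-")
#' ))
#' @export
capture_regions <- function(regions) {
  df <- as_tibble(regions)
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    abort("regions must have columns chrom, start, end")
  }
  if (!"name" %in% names(df)) df$name <- paste0("region", seq_len(nrow(df)))
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end
  if (any(bad)) {
    abort(paste0("invalid interval(s) at row(s): ",
                 paste(which(bad), collapse = ", ")))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  structure(df,
    ambiguous = .conflicting_overlaps(df),
    class = c("capture_regions", class(tibble())))
}

# intervals (0-based half-open) covered by >=2 regions with differing
# non-"." strands
.conflicting_overlaps <- function(df) {
  gp <- .regions_granges(df[df$strand == "+", ])
  gm <- .regions_granges(df[df$strand == "-", ])
  amb <- GenomicRanges::intersect(GenomicRanges::reduce(gp),
                                  GenomicRanges::reduce(gm))
  .granges_to_bed(amb)
}

.regions_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.granges_to_bed <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read capture-kit target regions from a BED file
#'
#' Parses BED (tab-separated, >= 3 columns; strand in column 6 when present)
#' into a [capture_regions] object. Coordinates are kept 0-based half-open.
#' `track`, `browser` and `#` comment lines are skipped. Overlapping
#' opposite-strand regions are retained and their overlap recorded as
#' ambiguous loci.
#'
#' @param path Path to a BED file.
#' @param require_strand If `TRUE`, error when column 6 is absent.
#' @return A [capture_regions] tibble.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tgeneA\t0\t+", bed)
#' read_capture_bed(bed)
#' @export
read_capture_bed <- function(path, require_strand = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(fields) == 0) abort("BED file contains no region lines")
  if (any(nf < 3)) {
    abort(paste0("line ", lineno[which(nf < 3)[1]], ": fewer than 3 columns"))
  }
  if (require_strand && any(nf < 6)) {
    abort(paste0("line ", lineno[which(nf < 6)[1]],
                 ": strand column (6) required but absent"))
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    abort(paste0("line ", lineno[which(bad)[1]], ": non-integer coordinates"))
  }
  bad <- start < 0 | start >= end
  if (any(bad)) {
    abort(paste0("line ", lineno[which(bad)[1]],
                 ": invalid interval (start >= end or start < 0)"))
  }
  strand <- col(6, ".")
  strand[is.na(strand)] <- "."
  if (!all(strand %in% c("+", "-", "."))) {
    abort(paste0("line ", lineno[which(!strand %in% c("+", "-", "."))[1]],
                 ": strand must be '+', '-' or '.'"))
  }
  name <- col(4)
  name[is.na(name)] <- paste0("region", which(is.na(name)))
  score <- suppressWarnings(as.numeric(col(5, "0")))
  score[is.na(score)] <- 0
  capture_regions(tibble(
    chrom = col(1), start = start, end = end,
    name = name, score = score, strand = strand
  ))
}

#' Write capture regions to BED 6
#' @param regions A [capture_regions] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_capture_bed <- function(regions, path) {
  df <- as.data.frame(regions)[, c("chrom", "start", "end", "name", "score", "strand")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# partition of covered positions into effective strand classes:
# list of GRanges: plus, minus, none (= ambiguous + unknown-only), ambiguous
.strand_partition <- function(regions) {
  gp <- GenomicRanges::reduce(.regions_granges(regions[regions$strand == "+", ]))
  gm <- GenomicRanges::reduce(.regions_granges(regions[regions$strand == "-", ]))
  gu <- GenomicRanges::reduce(.regions_granges(regions[regions$strand == ".", ]))
  amb <- GenomicRanges::intersect(gp, gm)
  plus <- GenomicRanges::setdiff(gp, gm)
  minus <- GenomicRanges::setdiff(gm, gp)
  unknown <- GenomicRanges::setdiff(gu, GenomicRanges::union(gp, gm))
  none <- GenomicRanges::reduce(GenomicRanges::union(amb, unknown))
  list(plus = plus, minus = minus, none = none, ambiguous = amb,
       unknown = unknown)
}

#' Coding strand at genomic positions
#'
#' Resolves the coding-strand annotation of each query position against a
#' region set: `"+"` or `"-"` where a single annotated direction covers the
#' position, `"ambiguous"` where regions with conflicting annotated strands
#' overlap, `"unknown"` where only strand-unannotated regions cover it, and
#' `"outside"` where no region covers it. A position covered by both an
#' annotated and an unannotated region takes the annotated direction.
#'
#' @param regions A [capture_regions] object.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions (recycled with `chrom`).
#' @return Character vector in `{"+", "-", "ambiguous", "unknown", "outside"}`.
#' @examples
#' rg <- capture_regions(data.frame(chrom = "chr1", start = 100, end = 200,
#'                                  strand = "+"))
#' strand_at(rg, "chr1", c(150, 500))
#' @export
strand_at <- function(regions, chrom, pos) {
  stopifnot(inherits(regions, "capture_regions"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  part <- .strand_partition(regions)
  # queries on chromosomes absent from the region set are simply "outside";
  # silence the disjoint-seqlevels note GenomicRanges emits for them
  hit <- function(gr) suppressWarnings(IRanges::overlapsAny(q, gr))
  out <- rep("outside", n)
  out[hit(part$unknown)] <- "unknown"
  out[hit(part$plus)] <- "+"
  out[hit(part$minus)] <- "-"
  out[hit(part$ambiguous)] <- "ambiguous"
  out
}

.load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  if (is.character(reference)) {
    return(Biostrings::DNAStringSet(reference))
  }
  if (methods::is(reference, "DNAStringSet")) return(reference)
  abort("reference must be a FASTA path, a named character vector, or a DNAStringSet")
}

#' Nucleotide composition of captured regions
#'
#' Tallies A/C/G/T (forward reference sense, N excluded) once per captured
#' position, stratified by effective coding-strand class: `"+"`, `"-"`, and
#' `"none"` (ambiguous or strand-unannotated coverage). Overlapping
#' same-strand regions are deduplicated by position. The forward-sense total
#' used for reference-frame normalization is the sum over classes.
#'
#' @param regions A [capture_regions] object.
#' @param reference Reference sequence: FASTA path, named character vector of
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @return A tibble of class `nucleotide_composition` with columns `strand`,
#'   `base`, `count`.
#' @examples
#' rg <- capture_regions(data.frame(chrom = "s", start = 0, end = 4, strand = "+"))
#' composition_of_regions(rg, c(s = "ACGT"))
#' @export
composition_of_regions <- function(regions, reference) {
  stopifnot(inherits(regions, "capture_regions"))
  ref <- .load_reference(reference)
  # FASTA headers may carry descriptions after the name
  names(ref) <- sub("\\s.*$", "", names(ref))
  part <- .strand_partition(regions)
  missing_chrom <- setdiff(unique(as.character(regions$chrom)), names(ref))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from reference: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  count_class <- function(gr) {
    counts <- setNames(rep(0L, 4), .BASES)
    if (length(gr) == 0) return(counts)
    bed <- .granges_to_bed(gr)
    for (i in seq_len(nrow(bed))) {
      s <- Biostrings::subseq(ref[[bed$chrom[i]]], bed$start[i] + 1L, bed$end[i])
      counts <- counts + Biostrings::letterFrequency(s, .BASES)
    }
    counts
  }
  res <- purrr::map(list(`+` = part$plus, `-` = part$minus, none = part$none),
                    count_class)
  out <- purrr::imap(res, function(counts, strand) {
    tibble(strand = strand, base = .BASES, count = as.integer(counts))
  }) %>% bind_rows()
  structure(out, class = c("nucleotide_composition", class(tibble())))
}

#' Forward-sense base totals of a composition
#' @param composition A `nucleotide_composition` tibble.
#' @return Named integer vector over A, C, G, T.
#' @export
composition_totals <- function(composition) {
  tot <- composition %>% group_by(.data$base) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  setNames(as.integer(tot$count), tot$base)[.BASES]
}

#' @export
print.capture_regions <- function(x, ...) {
  amb <- attr(x, "ambiguous")
  amb_bp <- if (is.null(amb) || nrow(amb) == 0) 0L else sum(amb$end - amb$start)
  cat(sprintf("<capture_regions> %d regions, %d bp ambiguous (conflicting strands)\n",
              nrow(x), amb_bp))
  NextMethod()
}
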