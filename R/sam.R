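.SAM_FLAGS <- c(
  paired = 1L, unmapped = 4L, mate_unmapped = 8L, reverse = 16L,
  secondary = 256L, qcfail = 512L, duplicate = 1024L, supplementary = 2048L
)

#' Read minimal SAM alignment records from text
#'
#' Parses the eleven mandatory SAM columns from a text SAM file (headers
#' skipped). Only the fields the quality filters need are typed.
#'
#' @param x Path to a SAM file or character vector of SAM lines.
#' @return Tibble with columns `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`.
#' @export
read_sam <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(qname = character(), flag = integer(), chrom = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character(), qual = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    abort(paste0("SAM record ", which(lengths(fields) < 11)[1],
                 ": fewer than 11 columns"))
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  tibble(
    qname = f(1), flag = as.integer(f(2)), chrom = f(3),
    pos = as.integer(f(4)), mapq = suppressWarnings(as.integer(f(5))),
    cigar = f(6), seq = f(10), qual = f(11)
  )
}

#' Alignment-level quality filter
#'
#' Keeps only primary, mapped, non-duplicate alignments that passed vendor
#' quality control, whose mate (if paired) is mapped, and whose mapping
#' quality is at least `min_mapq`. Records without a usable MAPQ (missing or
#' the SAM sentinel 255) are treated as MAPQ 0 and a note is emitted.
#' The filter is idempotent.
#'
#' @param records Tibble from [read_sam()] (needs `flag`, `mapq`).
#' @param min_mapq Minimum mapping quality (default 60).
#' @return The filtered record tibble.
#' @export
filter_alignments <- function(records, min_mapq = 60) {
  flag <- records$flag
  has <- function(bit) bitwAnd(flag, .SAM_FLAGS[[bit]]) != 0L
  mapq <- records$mapq
  missing_mapq <- is.na(mapq) | mapq == 255L
  if (any(missing_mapq)) {
    inform(paste0(sum(missing_mapq), " record(s) without mapping quality treated as MAPQ 0"))
    mapq[missing_mapq] <- 0L
  }
  keep <- !has("secondary") & !has("supplementary") & !has("duplicate") &
    !has("unmapped") & !(has("paired") & has("mate_unmapped")) &
    !has("qcfail") & mapq >= min_mapq
  records[keep, , drop = FALSE]
}
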