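#' Expected fraction of alignment mismatches that are true somatic mutations
#'
#' Converts a per-cell somatic substitution load into the fraction of
#' observed alignment mismatches attributable to genuine somatic mutations:
#'
#' \deqn{\frac{\mathrm{somatic\ mutations}}{\mathrm{mismatch}} =
#'   \frac{(\mathrm{somatic\ mutations\ per\ cell} / \mathrm{genome\ size})
#'   \times \mathrm{reads} \times \mathrm{read\ length}}{\mathrm{mismatches}}}
#'
#' The result is linear in the somatic load and in sequenced bases, and
#' inverse-linear in the mismatch count and genome size. A small value means
#' that observed mismatch asymmetry cannot be explained by genuine somatic
#' mutation.
#'
#' @param somatic_mutations_per_cell Somatic substitutions per cell (>= 0).
#' @param genome_size Diploid genome size in bp (> 0).
#' @param n_reads Number of sequenced reads after filtering (> 0).
#' @param read_length Read length in bp (> 0).
#' @param n_mismatches Alignment mismatches per sample after filtering (> 0).
#' @return The expected somatic-mutations-per-mismatch proportion.
#' @examples
#' estimate_somatic_fraction(2101, 6185543820, 44487029, 50, 173327)
#' @export
estimate_somatic_fraction <- function(somatic_mutations_per_cell, genome_size,
                                      n_reads, read_length, n_mismatches) {
  if (any(somatic_mutations_per_cell < 0)) {
    abort("somatic_mutations_per_cell must be >= 0")
  }
  if (any(genome_size <= 0) || any(n_mismatches <= 0)) {
    abort("genome_size and n_mismatches must be > 0")
  }
  if (any(n_reads <= 0) || any(read_length <= 0)) {
    abort("n_reads and read_length must be > 0")
  }
  (somatic_mutations_per_cell / genome_size) * (n_reads * read_length) /
    n_mismatches
}
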