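#' The twelve directed single-base mismatch types
#'
#' A directed mismatch type is an ordered pair of distinct bases, written
#' `"G>T"`: the reference base and the observed base, both expressed on the
#' forward sense of the reference genome. The twelve types fall into six
#' complement pairs (e.g. G>T / C>A): a substitution seen as `G>T` on one
#' strand is `C>A` on the other.
#'
#' @return A character vector of the twelve types in a fixed order.
#' @examples
#' mismatch_types()
#' @export
mismatch_types <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (r in bases) for (a in bases) if (r != a) out <- c(out, paste0(r, ">", a))
  out
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement a base vector
#' @param base Character vector of bases (A/C/G/T/N).
#' @return Complemented bases.
#' @keywords internal
complement_base <- function(base) {
  unname(.COMP[base])
}

#' Reverse-complement mismatch type
#'
#' Maps each directed mismatch type to its complement: the same substitution
#' read off the opposite strand (`G>T` -> `C>A`, `T>C` -> `A>G`, ...). The
#' mapping is an involution and partitions the twelve types into six pairs.
#'
#' @param type Character vector of mismatch types, e.g. `"G>T"`.
#' @return Character vector of complementary types.
#' @examples
#' complement_of("G>T")
#' complement_of(mismatch_types())
#' @export
complement_of <- function(type) {
  stopifnot(is.character(type))
  ref <- substr(type, 1, 1)
  alt <- substr(type, 3, 3)
  bad <- !(ref %in% .BASES) | !(alt %in% .BASES) | substr(type, 2, 2) != ">" |
    nchar(type) != 3 | ref == alt
  if (any(bad)) {
    abort(paste0("invalid mismatch type: ", paste(unique(type[bad]), collapse = ", ")))
  }
  paste0(complement_base(ref), ">", complement_base(alt))
}

#' Canonical label for a mismatch/complement pair
#'
#' @param type Character vector of mismatch types.
#' @return Pair labels such as `"G>T/C>A"`; the member whose reference base is
#'   a pyrimidine-partner purine (C or T first alphabetically by convention
#'   here: the lexicographically smaller type) leads, so both members of a
#'   pair map to the same label.
#' @examples
#' pair_label(c("G>T", "C>A"))
#' @export
pair_label <- function(type) {
  comp <- complement_of(type)
  first <- ifelse(type <= comp, type, comp)
  second <- complement_of(first)
  paste0(first, "/", second)
}
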