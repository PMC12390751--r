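#' Parse samtools-style pileup text into a per-call table
#'
#' Reads the six-column mpileup dialect (chrom, 1-based position, reference
#' base, depth, base string, Phred+33 quality string) into a long tibble with
#' one row per base call. The base string conventions are honoured: `.`/`,`
#' are matches on forward/reverse alignments, `ACGTN`/`acgtn` are mismatches
#' by alignment direction, `^X` (start + mapping quality), `$` (end),
#' `+N<seq>`/`-N<seq>` (indels), `*` (deletion placeholder) and `>`/`<`
#' (reference skips) are consumed; indels and deletion/skip placeholders do
#' not become base calls.
#'
#' @param x Path to a pileup file, or a character vector of pileup lines.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `base`
#'   (forward sense), `qual` (numeric Phred), `direction`
#'   (`"forward"`/`"reverse"`).
#' @examples
#' parse_pileup("sim1\t5\tG\t4\t..,T\tIIII")
#' @export
parse_pileup <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  base = character(), qual = numeric(), direction = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(paste0("pileup line ", which(nf < 6)[1], ": fewer than 6 columns"))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  pos <- as.integer(vapply(fields, `[[`, "", 2))
  ref <- toupper(vapply(fields, `[[`, "", 3))
  bases <- vapply(fields, `[[`, "", 5)
  quals <- vapply(fields, `[[`, "", 6)

  simple <- !grepl("[\\^$+*><-]", bases)
  res <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (simple[i]) {
      sym <- strsplit(bases[i], "", fixed = TRUE)[[1]]
      q <- utf8ToInt(quals[i]) - 33
    } else {
      parsed <- .walk_pileup_string(bases[i], quals[i], i)
      sym <- parsed$sym
      q <- parsed$qual
    }
    if (length(sym) != length(q)) {
      abort(paste0("pileup line ", i, ": base and quality strings disagree"))
    }
    res[[i]] <- list(sym = sym, q = q, n = length(sym))
  }
  nper <- vapply(res, `[[`, 0L, "n")
  sym <- unlist(lapply(res, `[[`, "sym"), use.names = FALSE)
  qual <- unlist(lapply(res, `[[`, "q"), use.names = FALSE)
  out <- tibble(
    chrom = rep(chrom, nper),
    pos = rep(pos, nper),
    ref = rep(ref, nper),
    sym = sym,
    qual = as.numeric(qual)
  )
  is_fwd_match <- out$sym == "."
  is_rev_match <- out$sym == ","
  out$direction <- ifelse(is_fwd_match | out$sym %in% c("A", "C", "G", "T", "N"),
                          "forward", "reverse")
  out$base <- ifelse(is_fwd_match | is_rev_match, out$ref, toupper(out$sym))
  out$sym <- NULL
  out[, c("chrom", "pos", "ref", "base", "qual", "direction")]
}

# character-walk for base strings containing structural markers
.walk_pileup_string <- function(bstr, qstr, lineno) {
  chars <- strsplit(bstr, "", fixed = TRUE)[[1]]
  qual_all <- utf8ToInt(qstr) - 33
  sym <- character(0)
  qual <- numeric(0)
  i <- 1L
  qi <- 1L
  nc <- length(chars)
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L  # skip the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= nc && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch %in% c("*", ">", "<")) {
      qi <- qi + 1L  # placeholder consumes a quality but is not a base call
      i <- i + 1L
    } else if (ch %in% c(".", ",") || grepl("[ACGTNacgtn]", ch)) {
      if (qi > length(qual_all)) {
        abort(paste0("pileup line ", lineno, ": quality string too short"))
      }
      sym <- c(sym, ch)
      qual <- c(qual, qual_all[qi])
      qi <- qi + 1L
      i <- i + 1L
    } else {
      abort(paste0("pileup line ", lineno, ": unexpected character '", ch, "'"))
    }
  }
  list(sym = sym, qual = qual)
}

#' Base-quality filter for pileup calls
#'
#' Drops calls below a base-quality threshold. The default (37) restricts
#' analysis to high-confidence calls; `min_bq = 0` is the identity.
#'
#' @param calls A per-call tibble from [parse_pileup()].
#' @param min_bq Minimum Phred base quality to retain (default 37).
#' @return The filtered call tibble.
#' @export
filter_pileup_bases <- function(calls, min_bq = 37) {
  calls[calls$qual >= min_bq, , drop = FALSE]
}

#' Classify singleton-mismatch sites
#'
#' Applies the singleton rule: a site contributes a mismatch only when exactly
#' one retained call differs from the reference base. Sites with two or more
#' mismatching calls are excluded (they are the signature of true biological
#' variation); sites with reference base outside A/C/G/T are ignored. `N`
#' calls neither match nor count as mismatches.
#'
#' @param calls A per-call tibble (already base-quality filtered).
#' @param multiple_alleles If `TRUE`, the singleton rule is relaxed to "one
#'   distinct mismatching allele" instead of "one mismatching read".
#' @return A tibble with one row per singleton site: `chrom`, `pos`, `ref`,
#'   `alt`, `direction`, plus attributes `sites_considered` (sites with >= 1
#'   retained call) and `sites_excluded_multi`.
#' @export
classify_singleton_sites <- function(calls, multiple_alleles = FALSE) {
  calls <- calls[calls$ref %in% .BASES, , drop = FALSE]
  if (nrow(calls) == 0) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), direction = character())
    attr(out, "sites_considered") <- 0L
    attr(out, "sites_excluded_multi") <- 0L
    return(out)
  }
  is_mis <- calls$base != calls$ref & calls$base != "N"
  key <- factor(paste(calls$chrom, calls$pos, sep = "\r"))
  nm <- rowsum(as.integer(is_mis), key)
  n_mis <- setNames(as.integer(nm), rownames(nm))[levels(key)]
  mis_idx <- which(is_mis)
  mis_key <- key[mis_idx]
  first <- !duplicated(mis_key)
  first_idx <- mis_idx[first]
  first_alt <- setNames(calls$base[first_idx], as.character(mis_key[first]))
  first_dir <- setNames(calls$direction[first_idx], as.character(mis_key[first]))
  n_alleles <- rep(0L, nlevels(key))
  names(n_alleles) <- levels(key)
  if (length(mis_idx) > 0) {
    distinct_pairs <- !duplicated(paste(mis_key, calls$base[mis_idx], sep = "\r"))
    tab <- table(mis_key[distinct_pairs])
    n_alleles[names(tab)] <- as.integer(tab)
  }
  if (multiple_alleles) {
    singleton_lv <- n_mis >= 1L & n_alleles == 1L
    multi_lv <- n_alleles > 1L
  } else {
    singleton_lv <- n_mis == 1L
    multi_lv <- n_mis > 1L
  }
  keep_levels <- levels(key)[singleton_lv]
  site_first <- !duplicated(key)
  site_key <- as.character(key[site_first])
  sel <- site_key %in% keep_levels
  out <- tibble(
    chrom = calls$chrom[site_first][sel],
    pos = calls$pos[site_first][sel],
    ref = calls$ref[site_first][sel],
    alt = unname(first_alt[site_key[sel]]),
    direction = unname(first_dir[site_key[sel]])
  )
  attr(out, "sites_considered") <- nlevels(key)
  attr(out, "sites_excluded_multi") <- sum(multi_lv)
  out
}
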