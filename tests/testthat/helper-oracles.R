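# Independent oracles and fixture builders used across test files.
# These deliberately avoid the package's own code paths wherever they serve
# as cross-checks.

# brute-force singleton-mismatch tally: per-site loops over a parsed pileup,
# with its own region lookup. Fixture pileups use only simple base-string
# symbols (no indel/start/end markers).
naive_tally <- function(pileup_lines, regions_df, min_bq = 37) {
  counts <- list()
  bump <- function(key) {
    counts[[key]] <<- (counts[[key]] %||% 0L) + 1L
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (line in pileup_lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    chrom <- f[1]; pos <- as.integer(f[2]); ref <- toupper(f[3])
    syms <- strsplit(f[5], "")[[1]]
    quals <- utf8ToInt(f[6]) - 33
    if (!ref %in% c("A", "C", "G", "T")) next
    # region lookup by full scan
    cov <- regions_df$chrom == chrom & regions_df$start <= (pos - 1) &
      (pos - 1) < regions_df$end
    if (!any(cov)) next
    st <- unique(regions_df$strand[cov])
    st_known <- setdiff(st, ".")
    stratum <- if (length(st_known) == 1) st_known else "none"
    keep <- quals >= min_bq
    syms <- syms[keep]
    bases <- ifelse(syms %in% c(".", ","), ref, toupper(syms))
    dirs <- ifelse(syms == "." | syms %in% c("A", "C", "G", "T", "N"),
                   "forward", "reverse")
    mis <- which(bases != ref & bases != "N")
    if (length(mis) != 1) next
    bump(paste(ref, bases[mis], stratum, dirs[mis], sep = "|"))
  }
  if (length(counts) == 0) {
    return(tibble::tibble(ref = character(), alt = character(),
                          strand = character(), direction = character(),
                          n = integer()))
  }
  parts <- strsplit(names(counts), "|", fixed = TRUE)
  tibble::tibble(
    ref = vapply(parts, `[[`, "", 1),
    alt = vapply(parts, `[[`, "", 2),
    strand = vapply(parts, `[[`, "", 3),
    direction = vapply(parts, `[[`, "", 4),
    n = as.integer(unlist(counts))
  )
}

# direct pmf-summation two-sided exact binomial p-value
# (minimum-likelihood convention with the standard numerical tie guard)
pmf_pvalue <- function(x, n, q) {
  d <- stats::dbinom(0:n, n, q)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# reverse-complement relabeling of a simulated dataset's calls and regions:
# mirrors the genome, complements every base, flips strands and alignment
# directions. Tallies of the relabeled data must equal the complement-swapped
# originals.
revcomp_relabel <- function(ds) {
  L <- ds$config$genome_length
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  calls <- ds$calls
  calls$pos <- L + 1L - calls$pos
  calls$ref <- unname(comp[calls$ref])
  calls$base <- unname(comp[calls$base])
  calls$direction <- ifelse(calls$direction == "forward", "reverse", "forward")
  regions <- tibble::tibble(
    chrom = ds$regions$chrom,
    start = L - ds$regions$end,
    end = L - ds$regions$start,
    name = ds$regions$name,
    score = ds$regions$score,
    strand = ifelse(ds$regions$strand == "+", "-",
                    ifelse(ds$regions$strand == "-", "+", "."))
  )
  list(calls = calls, regions = oxoasym::capture_regions(regions))
}

# random simple-dialect pileup fixture with mixed qualities and directions
make_random_pileup <- function(n_sites, seed, mismatch_prob = 0.3,
                               max_depth = 6) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    lines <- character(n_sites)
    for (i in seq_len(n_sites)) {
      chrom <- sample(c("cA", "cB"), 1)
      pos <- i + 10L
      ref <- sample(bases, 1)
      depth <- sample.int(max_depth, 1)
      sym <- character(depth)
      for (k in seq_len(depth)) {
        fwd <- runif(1) < 0.5
        if (runif(1) < mismatch_prob) {
          b <- sample(setdiff(bases, ref), 1)
          sym[k] <- if (fwd) b else tolower(b)
        } else {
          sym[k] <- if (fwd) "." else ","
        }
      }
      quals <- sample(30:45, depth, replace = TRUE)
      lines[i] <- paste(chrom, pos, ref, depth,
                        paste0(sym, collapse = ""),
                        intToUtf8(quals + 33, multiple = FALSE),
                        sep = "\t")
    }
    lines
  })
}

# regions covering the random pileup fixture, with a strand conflict and an
# unannotated region
random_pileup_regions <- function() {
  oxoasym::capture_regions(tibble::tibble(
    chrom = c("cA", "cA", "cA", "cB", "cB"),
    start = c(0, 40, 55, 0, 80),
    end = c(50, 60, 70, 60, 120),
    strand = c("+", "-", ".", "-", ".")
  ))
}

# reference + site list whose trinucleotide contexts realize the given
# named counts (contexts are 3-mers with a central G)
make_context_sites <- function(context_counts, chrom = "ctx1") {
  ctx <- rep(names(context_counts), context_counts)
  blocks <- paste0(ctx, "TT")
  seq <- paste0(blocks, collapse = "")
  pos <- (seq_along(ctx) - 1L) * 5L + 2L
  list(
    reference = stats::setNames(seq, chrom),
    sites = tibble::tibble(chrom = chrom, pos = pos)
  )
}
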