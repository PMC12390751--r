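#' Configuration for the capture-and-oxidation simulator
#'
#' Defines a generative model of guanine oxidation under single-stranded
#' exome capture. A pseudo-chromosome (`"sim1"`) carries `n_genes` target
#' regions of `read_length` bp each; every region is sequenced by `depth`
#' single-end reads (one read per captured molecule, spanning the region).
#'
#' The damage mechanism has two arms. *Pre-capture* oxidation strikes both
#' strands of the original double-stranded DNA: descendants of either strand
#' are captured equiprobably, so each forward-sense G is read as T with
#' probability `lambda_pre * p_mispair / 2` and each forward-sense C as A
#' with the same probability, symmetrically, whatever strand is captured.
#' *Post-capture* oxidation strikes only guanines on the captured
#' single strand: with probability `lambda_post` a captured-strand G carries
#' a lesion, read as T with probability `p_mispair` — this is the arm that
#' creates strand asymmetry. Uniform sequencing error `seq_error` (split
#' evenly across the three alternatives), germline heterozygotes (allele
#' fraction 1/2) and somatic variants (allele fraction `somatic_vaf`)
#' complete the model.
#'
#' @param genome_length Pseudo-chromosome length in bp (>= `n_genes * 2 *
#'   read_length`).
#' @param gc_fraction GC content of the simulated reference.
#' @param n_genes Number of target regions (genes).
#' @param gene_strand_scheme `"alternating"`, `"random_balanced"`, or
#'   `"all_plus"` coding-strand assignment.
#' @param capture_design Which strand the capture probes enrich at each
#'   locus: `"forward_reference"` (forward strand always, the behaviour
#'   attributed to reference-strand-designed kits), `"template_strand"`
#'   (the transcription template, the behaviour attributed to
#'   coding-sequence-designed kits), `"coding_strand"`, or
#'   `"double_stranded"` (either strand with probability 1/2 per molecule).
#' @param depth Captured molecules (= reads) per region.
#' @param read_length Read and region length in bp.
#' @param lambda_pre Per-G pre-capture lesion probability per strand.
#' @param lambda_post Per-G post-capture lesion probability on the captured
#'   strand.
#' @param p_mispair Probability a lesion-bearing G is read as T (adenine
#'   mispairing followed by replication).
#' @param seq_error Per-base uniform sequencing error rate.
#' @param het_rate Per-site germline heterozygote probability.
#' @param somatic_rate Per-site true somatic variant probability.
#' @param somatic_vaf Allele fraction of somatic variants.
#' @param base_quality Uniform Phred base quality of simulated calls.
#' @param n_duplicate_reads,n_secondary_reads,n_qcfail_reads,n_lowmapq_reads
#'   Numbers of flagged/low-quality SAM records to inject (to exercise
#'   alignment filters); 0 by default.
#' @param chrom Pseudo-chromosome name.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @examples
#' sim_config(n_genes = 4, depth = 10)
#' @export
sim_config <- function(genome_length = 4000, gc_fraction = 0.45,
                       n_genes = 20, gene_strand_scheme = "alternating",
                       capture_design = "forward_reference",
                       depth = 40, read_length = 50,
                       lambda_pre = 0, lambda_post = 0.003,
                       p_mispair = 1 / 3, seq_error = 0.0015,
                       het_rate = 0.001, somatic_rate = 1e-4,
                       somatic_vaf = 0.2, base_quality = 40,
                       n_duplicate_reads = 0, n_secondary_reads = 0,
                       n_qcfail_reads = 0, n_lowmapq_reads = 0,
                       chrom = "sim1", seed = 1) {
  cfg <- list(
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes),
    gene_strand_scheme = match.arg(gene_strand_scheme,
                                   c("alternating", "random_balanced", "all_plus")),
    capture_design = match.arg(capture_design,
                               c("forward_reference", "template_strand",
                                 "coding_strand", "double_stranded")),
    depth = as.integer(depth), read_length = as.integer(read_length),
    lambda_pre = lambda_pre, lambda_post = lambda_post,
    p_mispair = p_mispair, seq_error = seq_error,
    het_rate = het_rate, somatic_rate = somatic_rate,
    somatic_vaf = somatic_vaf, base_quality = as.integer(base_quality),
    n_duplicate_reads = as.integer(n_duplicate_reads),
    n_secondary_reads = as.integer(n_secondary_reads),
    n_qcfail_reads = as.integer(n_qcfail_reads),
    n_lowmapq_reads = as.integer(n_lowmapq_reads),
    chrom = chrom, seed = as.integer(seed)
  )
  probs <- c("gc_fraction", "lambda_pre", "lambda_post", "p_mispair",
             "seq_error", "het_rate", "somatic_rate", "somatic_vaf")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("config error: ", p, " must be a probability in [0, 1]"))
    }
  }
  # the damage/error arms are drawn as mutually exclusive events per call
  if (cfg$lambda_pre * cfg$p_mispair + cfg$lambda_post * cfg$p_mispair +
      cfg$seq_error >= 1) {
    abort("config error: combined per-call event probability must be < 1")
  }
  if (cfg$genome_length < cfg$n_genes * 2L * cfg$read_length) {
    abort("config error: genome_length must be >= n_genes * 2 * read_length")
  }
  if (cfg$depth < 1L || cfg$n_genes < 1L || cfg$read_length < 1L) {
    abort("config error: depth, n_genes and read_length must be >= 1")
  }
  structure(cfg, class = "sim_config")
}

.ALT_LOOKUP <- rbind(
  A = c("C", "G", "T"), C = c("A", "G", "T"),
  G = c("A", "C", "T"), T = c("A", "C", "G")
)

#' Simulate an exome-capture dataset with oxidative-damage artefacts
#'
#' Runs the generative model described in [sim_config()] and returns the
#' reference, the strand-annotated target regions, the per-call table, pileup
#' and SAM renderings, and a ground-truth event table in which every
#' non-reference call is attributed to exactly one event (`lesion_pre_fwd`,
#' `lesion_pre_rev`, `lesion_post`, `germline`, `somatic`, or `error`).
#'
#' Alignment direction and F1R2/F2R1 orientation class are assigned per
#' molecule: a lesion-bearing molecule takes them deterministically from the
#' lesion strand (forward-strand lesion -> forward alignment, F1R2); all
#' other molecules draw both uniformly at random.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `oxo_sim` with elements `config`, `reference`
#'   (named character), `regions` ([capture_regions]), `calls` (per-call
#'   tibble), `pileup` (text lines), `sam` (text lines), `truth` (tibble).
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 2, depth = 5, seed = 7))
#' head(ds$truth)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  L <- cfg$read_length
  gc <- cfg$gc_fraction
  genome <- sample(.BASES, cfg$genome_length, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  slot <- cfg$genome_length %/% cfg$n_genes
  gene_start <- (seq_len(cfg$n_genes) - 1L) * slot + (slot - L) %/% 2L
  gene_strand <- switch(cfg$gene_strand_scheme,
    alternating = rep_len(c("+", "-"), cfg$n_genes),
    random_balanced = sample(rep_len(c("+", "-"), cfg$n_genes)),
    all_plus = rep("+", cfg$n_genes)
  )
  regions <- capture_regions(tibble(
    chrom = cfg$chrom, start = gene_start, end = gene_start + L,
    name = paste0("gene", seq_len(cfg$n_genes)), score = 0,
    strand = gene_strand
  ))

  # site table: one row per captured position
  n_sites <- cfg$n_genes * L
  site_gene <- rep(seq_len(cfg$n_genes), each = L)
  site_pos0 <- rep(gene_start, each = L) + rep_len(seq_len(L) - 1L, n_sites)
  site_ref <- genome[site_pos0 + 1L]
  u <- runif(n_sites)
  site_variant <- ifelse(u < cfg$het_rate, "germline",
                  ifelse(u < cfg$het_rate + cfg$somatic_rate, "somatic", "none"))
  alt_pick <- sample.int(3L, n_sites, replace = TRUE)
  site_alt <- .ALT_LOOKUP[cbind(match(site_ref, .BASES), alt_pick)]
  site_alt[site_variant == "none"] <- NA_character_

  # molecule table: depth captured molecules per gene
  n_mol <- cfg$n_genes * cfg$depth
  mol_gene <- rep(seq_len(cfg$n_genes), each = cfg$depth)
  mol_coding <- gene_strand[mol_gene]
  mol_capt <- switch(cfg$capture_design,
    forward_reference = rep("+", n_mol),
    coding_strand = mol_coding,
    template_strand = ifelse(mol_coding == "+", "-", "+"),
    double_stranded = sample(c("+", "-"), n_mol, replace = TRUE)
  )

  # one row per (molecule, site): the molecule covers its whole gene
  n <- n_mol * L
  row_mol <- rep(seq_len(n_mol), each = L)
  row_site <- (rep(mol_gene, each = L) - 1L) * L + rep_len(seq_len(L), n)
  refb <- site_ref[row_site]
  capt <- mol_capt[row_mol]

  # variant carriage first, then a mutually exclusive damage/error draw
  vclass <- site_variant[row_site]
  vaf <- ifelse(vclass == "germline", 0.5,
         ifelse(vclass == "somatic", cfg$somatic_vaf, 0))
  carrier <- runif(n) < vaf

  p_pre <- ifelse(refb %in% c("G", "C"), cfg$lambda_pre * cfg$p_mispair / 2, 0)
  p_post <- ifelse((capt == "+" & refb == "G") | (capt == "-" & refb == "C"),
                   cfg$lambda_post * cfg$p_mispair, 0)
  p_err <- cfg$seq_error / 3
  u <- runif(n)
  event <- rep("match", n)
  call <- refb
  lesion_strand <- rep(NA_character_, n)

  sel <- !carrier & u < p_pre
  event[sel] <- ifelse(refb[sel] == "G", "lesion_pre_fwd", "lesion_pre_rev")
  call[sel] <- ifelse(refb[sel] == "G", "T", "A")
  lesion_strand[sel] <- ifelse(refb[sel] == "G", "+", "-")

  sel <- !carrier & u >= p_pre & u < p_pre + p_post
  event[sel] <- "lesion_post"
  call[sel] <- ifelse(refb[sel] == "G", "T", "A")
  lesion_strand[sel] <- capt[sel]

  for (k in 1:3) {
    lo <- p_pre + p_post + (k - 1) * p_err
    sel <- !carrier & u >= lo & u < lo + p_err
    event[sel] <- "error"
    call[sel] <- .ALT_LOOKUP[cbind(match(refb[sel], .BASES), k)]
  }

  event[carrier] <- vclass[carrier]
  call[carrier] <- site_alt[row_site][carrier]

  # per-molecule direction/orientation: deterministic from the lesion strand
  # for lesion-bearing molecules, uniform otherwise
  mol_lesion <- rep(NA_character_, n_mol)
  idx <- which(!is.na(lesion_strand))
  if (length(idx) > 0) {
    mol_lesion[row_mol[rev(idx)]] <- lesion_strand[rev(idx)]  # first lesion wins
  }
  coin <- sample(c("+", "-"), n_mol, replace = TRUE)
  mol_strand <- ifelse(is.na(mol_lesion), coin, mol_lesion)
  mol_dir <- ifelse(mol_strand == "+", "forward", "reverse")
  mol_orient <- ifelse(mol_strand == "+", "F1R2", "F2R1")

  calls <- tibble(
    chrom = cfg$chrom,
    pos = site_pos0[row_site] + 1L,
    ref = refb,
    base = call,
    qual = as.numeric(cfg$base_quality),
    direction = mol_dir[row_mol],
    molecule = row_mol,
    gene = mol_gene[row_mol],
    coding_strand = mol_coding[row_mol],
    captured_strand = capt,
    event = event,
    lesion_strand = lesion_strand,
    orientation = mol_orient[row_mol]
  )

  truth <- calls %>%
    filter(.data$event != "match") %>%
    select("chrom", "pos", "molecule", "event", strand = "lesion_strand",
           orientation_class = "orientation", "ref", alt = "base")

  reference <- setNames(paste(genome, collapse = ""), cfg$chrom)
  pileup <- render_pileup(calls)
  sam <- .render_sam(cfg, regions, mol_gene, mol_dir, call, L, n_mol)

  structure(list(config = cfg, reference = reference, regions = regions,
                 calls = calls, pileup = pileup, sam = sam, truth = truth),
            class = "oxo_sim")
}

.render_sam <- function(cfg, regions, mol_gene, mol_dir, call, L, n_mol) {
  seqs <- do.call(paste0, as.data.frame(matrix(call, ncol = L, byrow = TRUE),
                                        stringsAsFactors = FALSE))
  qstr <- strrep(intToUtf8(cfg$base_quality + 33), L)
  flag <- ifelse(mol_dir == "reverse", 16L, 0L)
  pos1 <- regions$start[mol_gene] + 1L
  rec <- function(qname, flag, pos, mapq, seq) {
    paste(qname, flag, cfg$chrom, pos, mapq, paste0(L, "M"),
          "*", 0, 0, seq, qstr, sep = "\t")
  }
  body <- rec(paste0("mol", seq_len(n_mol)), flag, pos1, 60L, seqs)
  junk <- character(0)
  inject <- function(n_inj, extra_flag, mapq) {
    if (n_inj <= 0) return(character(0))
    rec(paste0("junk", extra_flag, "_", seq_len(n_inj)),
        bitwOr(flag[1], extra_flag), pos1[1], mapq, seqs[1])
  }
  junk <- c(
    inject(cfg$n_duplicate_reads, 1024L, 60L),
    inject(cfg$n_secondary_reads, 256L, 60L),
    inject(cfg$n_qcfail_reads, 512L, 60L),
    if (cfg$n_lowmapq_reads > 0) {
      rec(paste0("lowmq_", seq_len(cfg$n_lowmapq_reads)), flag[1], pos1[1],
          10L, seqs[1])
    } else character(0)
  )
  c(paste0("@HD\tVN:1.6\tSO:unsorted"),
    paste0("@SQ\tSN:", cfg$chrom, "\tLN:", cfg$genome_length),
    body, junk)
}

#' Closed-form expected per-read mismatch probabilities
#'
#' The analytic counterpart of the simulator: per captured molecule, at a
#' non-variant site, the probability of each directed mismatch type. With the
#' forward strand captured, `P(G>T) = lambda_pre*p_mispair/2 +
#' lambda_post*p_mispair + seq_error/3`, `P(C>A) = lambda_pre*p_mispair/2 +
#' seq_error/3`, and every other type is `seq_error/3`; with the reverse
#' strand captured G>T and C>A exchange roles; `"double"` averages the two.
#'
#' @param config A [sim_config()] object.
#' @param locus_class Captured-strand class: `"forward"`, `"reverse"`, or
#'   `"double"`.
#' @return A tibble with columns `ref`, `alt`, `type`, `rate`.
#' @examples
#' cfg <- sim_config(lambda_pre = 0, lambda_post = 0.003, p_mispair = 1/3,
#'                   seq_error = 0.0015)
#' expected_mismatch_rates(cfg, "forward")
#' @export
expected_mismatch_rates <- function(config,
                                    locus_class = c("forward", "reverse",
                                                    "double")) {
  stopifnot(inherits(config, "sim_config"))
  locus_class <- match.arg(locus_class)
  one <- function(capt) {
    pre <- config$lambda_pre * config$p_mispair / 2
    post <- config$lambda_post * config$p_mispair
    err <- config$seq_error / 3
    types <- mismatch_types()
    rate <- rep(err, length(types))
    names(rate) <- types
    rate["G>T"] <- rate["G>T"] + pre + if (capt == "forward") post else 0
    rate["C>A"] <- rate["C>A"] + pre + if (capt == "reverse") post else 0
    rate
  }
  rate <- switch(locus_class,
    forward = one("forward"),
    reverse = one("reverse"),
    double = (one("forward") + one("reverse")) / 2
  )
  tibble(
    ref = substr(names(rate), 1, 1),
    alt = substr(names(rate), 3, 3),
    type = names(rate),
    rate = unname(rate)
  )
}

#' Render per-call data as pileup text
#'
#' Emits the six-column mpileup dialect: `.`/`,` for matches on
#' forward/reverse alignments, `ACGT`/`acgt` for mismatches by alignment
#' direction, qualities as Phred+33. Zero-depth sites are omitted (they never
#' arise in the per-call representation). Round-trips through
#' [parse_pileup()].
#'
#' @param x An `oxo_sim` dataset or a per-call tibble with columns `chrom`,
#'   `pos`, `ref`, `base`, `qual`, `direction`.
#' @return Character vector of pileup lines ordered by position.
#' @export
render_pileup <- function(x) {
  calls <- if (inherits(x, "oxo_sim")) x$calls else x
  if (nrow(calls) == 0) return(character(0))
  ord <- order(calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  is_match <- calls$base == calls$ref
  fwd <- calls$direction == "forward"
  sym <- ifelse(is_match, ifelse(fwd, ".", ","),
                ifelse(fwd, calls$base, tolower(calls$base)))
  qch <- intToUtf8(as.integer(calls$qual) + 33L, multiple = TRUE)
  key <- factor(paste(calls$chrom, calls$pos),
                levels = unique(paste(calls$chrom, calls$pos)))
  bases <- vapply(split(sym, key), paste0, "", collapse = "")
  quals <- vapply(split(qch, key), paste0, "", collapse = "")
  first <- !duplicated(key)
  paste(calls$chrom[first], calls$pos[first], calls$ref[first],
        as.integer(table(key)), bases, quals, sep = "\t")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `reference.fa`, `regions.bed`, `reads.sam`, `pileup.txt`, and
#' `truth.tsv` into a directory.
#'
#' @param dataset An `oxo_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "oxo_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference = file.path(dir, "reference.fa"),
    regions = file.path(dir, "regions.bed"),
    sam = file.path(dir, "reads.sam"),
    pileup = file.path(dir, "pileup.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  seq <- dataset$reference
  wrapped <- gsub("(.{60})", "\\1\n", seq)
  writeLines(paste0(">", names(seq), "\n", sub("\n$", "", wrapped)),
             paths["reference"])
  write_capture_bed(dataset$regions, paths["regions"])
  writeLines(dataset$sam, paths["sam"])
  writeLines(dataset$pileup, paths["pileup"])
  write.table(dataset$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' @export
print.oxo_sim <- function(x, ...) {
  cat(sprintf(
    "<oxo_sim> %d genes x %d bp, depth %d (%s capture): %d calls, %d truth events\n",
    x$config$n_genes, x$config$read_length, x$config$depth,
    x$config$capture_design, nrow(x$calls), nrow(x$truth)))
  invisible(x)
}
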