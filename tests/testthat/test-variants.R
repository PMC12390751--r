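write_test_vcf <- function(body, samples = c("s1", "s2")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

test_that("VCF ingestion keeps biallelic SNVs and drops indels/multiallelics", {
  vcf <- write_test_vcf(c(
    "chr1\t10\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t20\t.\tA\tAT\t30\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t25\t.\tAT\tA\t30\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t30\t.\tA\tC,G\t30\tPASS\t.\tGT\t1/2\t0/0",
    "chr1\t40\t.\tG\tT\t12\tartifact\t.\tGT\t1/1\t0|1"
  ))
  rec <- read_biallelic_snvs(vcf, c(s1 = "tumour", s2 = "normal"))
  expect_equal(sort(unique(rec$pos)), c(10L, 40L))
  r10 <- rec[rec$pos == 10, ]
  expect_equal(r10$genotype, "het")
  expect_equal(r10$filter, "PASS")
  expect_equal(r10$role, "tumour")
  r40 <- rec[rec$pos == 40, ]
  expect_equal(nrow(r40), 2)
  expect_equal(sort(r40$genotype), c("het", "hom"))
  expect_equal(r40$filter, rep("artifact", 2))
})

test_that("carrier samples without a role are skipped with a warning", {
  vcf <- write_test_vcf("chr1\t10\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t0/1")
  expect_warning(rec <- read_biallelic_snvs(vcf, c(s1 = "tumour")), "s2")
  expect_equal(unique(rec$sample), "s1")
})

test_that("common-site exclusion removes exact tuples only", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 10L, 20L), ref = "G", alt = c("T", "A", "T"),
    filter = "PASS", qual = 10, sample = "s1", role = "tumour",
    genotype = "het"
  )
  excl <- data.frame(chrom = "chr1", pos = 10L, ref = "G", alt = "T")
  out <- filter_common_sites(rec, excl)
  expect_equal(nrow(out), 2)
  expect_false(any(out$pos == 10 & out$alt == "T"))
  expect_equal(filter_common_sites(rec, excl[0, ]), rec)
})

test_that("variant tallies stratify by strand and filter status", {
  rg <- capture_regions(data.frame(chrom = "chr1", start = c(0, 100),
                                   end = c(50, 150), strand = c("+", "-")))
  rec <- tibble::tibble(
    chrom = "chr1",
    pos = c(10L, 110L, 120L, 900L),
    ref = c("G", "C", "G", "G"),
    alt = c("T", "A", "T", "T"),
    filter = c("PASS", "clustered_events", "PASS", "PASS"),
    qual = 1, sample = "s1", role = "tumour", genotype = "het"
  )
  vt <- tally_variants(rec, rg)
  df <- as.data.frame(vt)
  get <- function(r, a, s, fc) df$n[df$ref == r & df$alt == a &
                                      df$strand == s & df$filter_class == fc]
  expect_equal(get("G", "T", "+", "all"), 1L)
  expect_equal(get("G", "T", "+", "pass"), 1L)
  expect_equal(get("C", "A", "-", "all"), 1L)
  expect_equal(get("C", "A", "-", "pass"), 0L)
  expect_equal(get("G", "T", "-", "pass"), 1L)
  # the record outside all regions is ignored
  expect_equal(sum(df$n[df$filter_class == "all"]), 3L)
  # pass <= all componentwise
  wide <- merge(df[df$filter_class == "all", c("ref", "alt", "strand", "n")],
                df[df$filter_class == "pass", c("ref", "alt", "strand", "n")],
                by = c("ref", "alt", "strand"), suffixes = c("_all", "_pass"))
  expect_true(all(wide$n_pass <= wide$n_all))
})

test_that("ratio functions accept variant tables with a filter_class choice", {
  rg <- capture_regions(data.frame(chrom = "chr1", start = 0, end = 1000,
                                   strand = "+"))
  rec <- tibble::tibble(
    chrom = "chr1", pos = c(1:9, 10:12) * 10L,
    ref = c(rep("G", 9), rep("C", 3)),
    alt = c(rep("T", 9), rep("A", 3)),
    filter = c(rep("PASS", 4), rep("oxog", 5), rep("PASS", 3)),
    qual = 1, sample = "s1", role = "tumour", genotype = "het"
  )
  vt <- tally_variants(rec, rg)
  expect_equal(reference_strand_ratio(vt, "G>T")$ratio, 3)  # all: 9 vs 3
  expect_equal(reference_strand_ratio(vt, "G>T", filter_class = "pass")$ratio,
               4 / 3)
})

test_that("unique-site aggregation collapses recurrent sites", {
  rec <- tibble::tibble(
    chrom = "chr1",
    pos = c(rep(10L, 5), 20L, 30L, 30L),
    ref = "G", alt = c(rep("T", 5), "T", "T", "A"),
    sample = c(paste0("s", 1:5), "s1", "s1", "s2")
  )
  us <- unique_sites(rec)
  expect_equal(nrow(us), 4)  # 10/T, 20/T, 30/T, 30/A
  expect_equal(us$n_samples[us$pos == 10], 5L)
  totals <- attr(us, "type_totals")
  expect_equal(totals$n_sites[totals$alt == "T"], 3L)
  expect_equal(totals$n_sites[totals$alt == "A"], 1L)
})

test_that("binomial departure reproduces exact two-sided tail sums", {
  rg <- capture_regions(data.frame(chrom = "s", start = 0, end = 8, strand = "+"))
  comp_eq <- composition_of_regions(rg, c(s = "GGGGCCCC"))  # q = 0.5

  expect_equal(binomial_departure(5, 5, comp_eq, "G>T")$p_value, 1.0)
  expect_equal(binomial_departure(8, 2, comp_eq, "G>T")$p_value, 0.109375,
               tolerance = 1e-12)
  expect_lt(binomial_departure(403, 195, comp_eq, "G>T")$p_value, 1e-15)
  expect_error(binomial_departure(0, 0, comp_eq, "G>T"), "zero")

  # expected proportion comes from the composition
  rg2 <- capture_regions(data.frame(chrom = "s", start = 0, end = 10, strand = "+"))
  comp_uneq <- composition_of_regions(rg2, c(s = "GGGGGGGCCC"))
  b <- binomial_departure(7, 3, comp_uneq, "G>T")
  expect_equal(b$expected_prop, 0.7)
  expect_equal(b$p_value, 1.0)
})

test_that("binomial departure matches pmf summation to 1e-12 for n <= 500", {
  rg <- capture_regions(data.frame(chrom = "s", start = 0, end = 10, strand = "+"))
  comp <- composition_of_regions(rg, c(s = "GGGGGGCCCC"))  # q = 0.6
  q <- 0.6
  withr::with_seed(11, {
    cases <- rbind(
      data.frame(n = c(1, 2, 10, 77, 500), x = c(0, 2, 5, 40, 500)),
      data.frame(n = sample(3:500, 40),
                 x = NA)
    )
    cases$x[is.na(cases$x)] <- vapply(cases$n[is.na(cases$x)],
                                      function(n) sample(0:n, 1), 0)
  })
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; x <- cases$x[i]
    got <- binomial_departure(x, n - x, comp, "G>T")$p_value
    expect_equal(got, pmf_pvalue(x, n, q), tolerance = 1e-12)
  }
})

test_that("trinucleotide contexts are read off the forward reference", {
  tab <- trinucleotide_context_table(data.frame(chrom = "s", pos = 3),
                                     c(s = "AGGCA"))
  expect_equal(tab$context, "GGC")
  expect_equal(tab$fraction, 1)

  # chromosome-edge sites are skipped with a note
  expect_message(
    tab2 <- trinucleotide_context_table(
      data.frame(chrom = "s", pos = c(1, 3, 5)), c(s = "AGGCA")),
    "skipped")
  expect_equal(attr(tab2, "n_skipped"), 2L)
  expect_equal(attr(tab2, "n_sites"), 1L)

  # pyrimidine re-keying maps G-centred contexts to their reverse complement
  tab3 <- trinucleotide_context_table(data.frame(chrom = "s", pos = 3),
                                      c(s = "AGGCA"), frame = "pyrimidine")
  expect_equal(tab3$context, "GCC")
})

test_that("orientation fractions handle both input forms and edge cases", {
  expect_equal(orientation_fraction(c("F1R2", "F1R2", "F2R1", "F1R2")), 0.75)
  expect_equal(orientation_fraction(c("F1R2", "F1R2")), 1.0)
  expect_true(is.na(orientation_fraction(character(0))))
  expect_equal(orientation_fraction(3, 1), 0.75)
  expect_equal(orientation_fraction(c(3, 0), c(1, 0)), c(0.75, NA))
  expect_error(orientation_fraction("FWD"), "orientations")
})

test_that("simulated variants are orientation-balanced, lesions are not", {
  cfg <- sim_config(n_genes = 60, depth = 30, genome_length = 6000,
                    lambda_pre = 0, lambda_post = 0.01, seq_error = 0,
                    het_rate = 0.02, somatic_rate = 0, seed = 23)
  ds <- simulate_dataset(cfg)
  germ <- ds$truth[ds$truth$event == "germline", ]
  frac_germ <- orientation_fraction(germ$orientation_class)
  se <- sqrt(0.25 / nrow(germ))
  expect_lt(abs(frac_germ - 0.5), 3 * se)
  les <- ds$truth[ds$truth$event == "lesion_post", ]
  expect_equal(orientation_fraction(les$orientation_class), 1.0)
})

test_that("rebalance filter removes lowest-quality calls first", {
  calls <- data.frame(chrom = "1", pos = 1:3, qual = c(10, 20, 30))
  out <- rebalance_filter(calls, ca_count = 1)
  expect_equal(out$retained$qual, 30)
  expect_equal(out$removed$qual, c(10, 20))

  # already balanced: identity
  out2 <- rebalance_filter(calls, ca_count = 5)
  expect_equal(nrow(out2$retained), 3)
  expect_equal(nrow(out2$removed), 0)

  # ca_count = 0 removes everything
  expect_equal(nrow(rebalance_filter(calls, 0)$retained), 0)

  # quality ties broken by coordinate order
  tied <- data.frame(chrom = "1", pos = c(30L, 10L, 20L), qual = 5)
  out3 <- rebalance_filter(tied, ca_count = 1)
  expect_equal(out3$removed$pos, c(10L, 20L))
  expect_equal(out3$retained$pos, 30L)

  # falls back to alt_reads when qual is absent
  ar <- data.frame(chrom = "1", pos = 1:2, alt_reads = c(9, 2))
  expect_equal(rebalance_filter(ar, 1)$retained$alt_reads, 9)
  expect_error(rebalance_filter(data.frame(chrom = "1", pos = 1), 0), "qual")
})

test_that("true somatic calls survive rebalancing preferentially", {
  cfg <- sim_config(n_genes = 80, depth = 30, genome_length = 8000,
                    lambda_pre = 0, lambda_post = 0.012, p_mispair = 1 / 2,
                    seq_error = 0, het_rate = 0, somatic_rate = 0.02,
                    somatic_vaf = 0.35, seed = 37)
  ds <- simulate_dataset(cfg)
  gt <- ds$truth[ds$truth$ref == "G" & ds$truth$alt == "T", ]
  per_site <- stats::aggregate(molecule ~ chrom + pos, gt, length)
  names(per_site)[3] <- "alt_reads"
  ev <- stats::aggregate(event ~ chrom + pos, gt,
                         function(e) if (any(e == "somatic")) "somatic" else "artefact")
  sites <- merge(per_site, ev)
  ca_sites <- sum(ds$truth$ref == "C" & ds$truth$alt == "A")
  out <- rebalance_filter(sites, ca_count = nrow(sites[sites$event == "somatic", ]))
  frac_somatic <- function(df) mean(df$event == "somatic")
  expect_gt(frac_somatic(out$retained), frac_somatic(sites))
  expect_lt(frac_somatic(out$removed), frac_somatic(sites))
})
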