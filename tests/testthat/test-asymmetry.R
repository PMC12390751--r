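count_table <- function(...) {
  # build a mismatch_counts table from (type, strand, direction, n) triples
  entries <- list(...)
  grid <- as.data.frame(tally_mismatches(character(0),
    capture_regions(data.frame(chrom = "s", start = 0, end = 1, strand = "+"))))
  for (e in entries) {
    sel <- grid$ref == substr(e[[1]], 1, 1) & grid$alt == substr(e[[1]], 3, 3) &
      grid$strand == e[[2]] & grid$direction == e[[3]]
    grid$n[sel] <- grid$n[sel] + as.integer(e[[4]])
  }
  structure(tibble::as_tibble(grid),
            class = c("mismatch_counts", class(tibble::tibble())))
}

test_that("complement pairing is the reverse-complement involution", {
  expect_equal(complement_of("G>T"), "C>A")
  expect_equal(complement_of("T>C"), "A>G")
  expect_equal(complement_of("C>G"), "G>C")
  for (t in mismatch_types()) {
    expect_equal(complement_of(complement_of(t)), t)
  }
  # six pairs exactly
  expect_equal(length(unique(pair_label(mismatch_types()))), 6)
  expect_error(complement_of("G>G"), "invalid")
  expect_error(complement_of("GT"), "invalid")
})

test_that("reference-strand ratio divides type by complement over all strata", {
  ct <- count_table(list("G>T", "+", "forward", 60), list("G>T", "-", "reverse", 40),
                    list("C>A", "+", "forward", 30), list("C>A", "none", "reverse", 20))
  r <- reference_strand_ratio(ct, "G>T")
  expect_equal(r$numerator, 100)
  expect_equal(r$denominator, 50)
  expect_equal(r$ratio, 2)
  expect_equal(r$log2_ratio, 1)
  expect_true(r$defined)

  # the printed PASS-call counts: over twice as many G>T as C>A
  ct2 <- count_table(list("G>T", "+", "forward", 403), list("C>A", "+", "forward", 195))
  r2 <- reference_strand_ratio(ct2, "G>T")
  expect_equal(r2$ratio, 403 / 195, tolerance = 1e-12)
  expect_gte(r2$ratio, 2)

  # equal counts
  ct3 <- count_table(list("G>T", "+", "forward", 7), list("C>A", "+", "forward", 7))
  expect_equal(reference_strand_ratio(ct3, "G>T")$log2_ratio, 0)

  # zero denominator: flagged undefined unless pseudocounts requested
  ct4 <- count_table(list("G>T", "+", "forward", 5))
  r4 <- reference_strand_ratio(ct4, "G>T")
  expect_false(r4$defined)
  expect_true(is.na(r4$ratio))
  r5 <- reference_strand_ratio(ct4, "G>T", pseudocount = 0.5)
  expect_equal(r5$ratio, 5.5 / 0.5)
})

test_that("transcription-strand ratio re-expresses counts on the template", {
  # all signal on the template strand: coding-frame count is zero
  ct <- count_table(list("G>T", "-", "forward", 10), list("C>A", "+", "forward", 5))
  r <- transcription_strand_ratio(ct, "G>T")
  expect_equal(r$numerator, 15)
  expect_equal(r$denominator, 0)
  expect_false(r$defined)

  # symmetric input
  ct2 <- count_table(list("G>T", "-", "forward", 10), list("G>T", "+", "forward", 10),
                     list("C>A", "+", "forward", 10), list("C>A", "-", "forward", 10))
  expect_equal(transcription_strand_ratio(ct2, "G>T")$ratio, 1)

  # the none stratum is excluded from transcription-strand statistics
  ct3 <- count_table(list("G>T", "-", "forward", 10), list("G>T", "none", "forward", 99),
                     list("G>T", "+", "forward", 5))
  r3 <- transcription_strand_ratio(ct3, "G>T")
  expect_equal(r3$numerator, 10)
  expect_equal(r3$denominator, 5)
})

test_that("alignment-direction ratio compares forward to reverse alignments", {
  ct <- count_table(list("G>T", "+", "forward", 30), list("G>T", "-", "reverse", 10))
  r <- alignment_direction_ratio(ct, "G>T")
  expect_equal(r$ratio, 3)
  ct2 <- count_table(list("G>T", "+", "forward", 8), list("G>T", "+", "reverse", 8))
  expect_equal(alignment_direction_ratio(ct2, "G>T")$ratio, 1)
})

test_that("orientation-tagged post-capture lesions skew alignment direction", {
  cfg <- sim_config(n_genes = 40, depth = 20, genome_length = 4000,
                    lambda_pre = 0, lambda_post = 0.02, p_mispair = 1 / 2,
                    seq_error = 0, het_rate = 0, somatic_rate = 0, seed = 99)
  ds <- simulate_dataset(cfg)
  ct <- tally_mismatches(ds$calls, ds$regions)
  r <- alignment_direction_ratio(ct, "G>T")
  # forward-strand lesions ride forward-aligned molecules
  expect_true(r$defined == FALSE || r$ratio > 1)
  expect_gt(r$numerator, r$denominator)
})

test_that("reciprocity: ratio of complement is the reciprocal", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      entries <- lapply(sample(mismatch_types(), 8), function(t) {
        list(t, sample(c("+", "-", "none"), 1),
             sample(c("forward", "reverse"), 1), sample(1:50, 1))
      })
      ct <- do.call(count_table, entries)
      for (t in c("G>T", "C>T", "T>A")) {
        a <- reference_strand_ratio(ct, t)
        b <- reference_strand_ratio(ct, complement_of(t))
        if (a$defined && b$defined && a$numerator > 0) {
          expect_equal(a$ratio * b$ratio, 1, tolerance = 1e-12)
        }
        ta <- transcription_strand_ratio(ct, t)
        tb <- transcription_strand_ratio(ct, complement_of(t))
        if (ta$defined && tb$defined && ta$numerator > 0) {
          expect_equal(ta$ratio * tb$ratio, 1, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("reverse-complement relabeling maps each ratio to its reciprocal", {
  cfg <- sim_config(n_genes = 20, depth = 25, genome_length = 2000,
                    lambda_pre = 0.001, lambda_post = 0.01, seed = 17)
  ds <- simulate_dataset(cfg)
  rc <- revcomp_relabel(ds)
  a <- tally_mismatches(ds$calls, ds$regions)
  b <- tally_mismatches(rc$calls, rc$regions)
  for (t in c("G>T", "C>T")) {
    ra <- reference_strand_ratio(a, t)
    rb <- reference_strand_ratio(b, t)
    if (ra$defined && rb$defined && ra$numerator > 0) {
      expect_equal(ra$ratio, 1 / rb$ratio, tolerance = 1e-12)
    }
  }
})

test_that("asymmetry_ratios reports every type in a mode", {
  ct <- count_table(list("G>T", "+", "forward", 10), list("C>A", "-", "reverse", 5))
  out <- asymmetry_ratios(ct, "reference")
  expect_equal(nrow(out), 12)
  expect_true(all(out$mode == "reference"))
  expect_equal(out$ratio[out$type == "G>T"], 2)
})

test_that("batch summaries compute medians, outliers and top-decile flags", {
  one <- batch_summary(data.frame(sample = c("a", "b", "c"),
                                  ratio = c(1, 2, 3), batch = "fc1"))
  expect_equal(one$median_ratio, 2)
  expect_false(is.na(one$sd_ratio))

  # ten batches with medians 1..10: only the highest flagged at 0.1
  df <- data.frame(
    sample = paste0("s", 1:30),
    ratio = rep(1:10, each = 3) + rep(c(-0.1, 0, 0.1), 10),
    batch = rep(paste0("fc", 1:10), each = 3)
  )
  bs <- batch_summary(df, top_fraction = 0.1)
  expect_equal(sum(bs$top_flag), 1)
  expect_equal(bs$batch[bs$top_flag], "fc10")

  # ties at the boundary are all flagged
  df2 <- data.frame(sample = paste0("s", 1:4), ratio = c(1, 2, 5, 5),
                    batch = paste0("fc", 1:4))
  bs2 <- batch_summary(df2, top_fraction = 0.25)
  expect_equal(sort(bs2$batch[bs2$top_flag]), c("fc3", "fc4"))

  # outliers beyond 1.5 x IQR
  df3 <- data.frame(sample = paste0("s", 1:7),
                    ratio = c(1, 1.1, 1.2, 1.1, 1.0, 1.15, 9),
                    batch = "fc1")
  bs3 <- batch_summary(df3)
  expect_equal(bs3$outlier_samples[[1]], "s7")

  # undefined ratios are excluded with a note
  df4 <- data.frame(sample = c("a", "b"), ratio = c(2, NA), batch = "fc1")
  expect_message(bs4 <- batch_summary(df4), "excluded")
  expect_equal(bs4$n_samples, 1L)

  # empty input -> empty summary
  expect_equal(nrow(batch_summary(data.frame(sample = character(),
                                             ratio = double(),
                                             batch = character()))), 0)
})
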