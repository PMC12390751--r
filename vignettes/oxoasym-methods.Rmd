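---
title: "Methods: strand-asymmetric oxidative damage artefacts and their simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-asymmetric oxidative damage artefacts and their simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxoasym)
```

## The phenomenon

8-oxo-guanine (8-oxo-G), the principal product of guanine oxidation, pairs
with adenine via Hoogsteen geometry during replication; after a second
round of replication the lesion is read out as a G>T substitution. When the
oxidation happens *ex vivo* — acoustic shearing, library amplification,
reagent contamination — the resulting calls are artefacts, and they carry a
strand signature: the T appears only on DNA descended from the
lesion-bearing strand. At a single locus this is the familiar F1R2/F2R1
orientation bias. Across loci, single-stranded capture probes make the
signature *systematic*, because at every locus only one strand is enriched:

* probes designed against the **forward reference strand** retain
  forward-strand lesions everywhere, producing a genome-wide excess of G>T
  over C>A relative to the reference;
* probes designed against the **transcription template strand** retain
  template-strand lesions, producing asymmetry aligned with gene
  orientation. Since roughly half of genes lie on each reference strand,
  the reference-frame excess cancels — "summing to neutrality exome-wide" —
  and is only visible in the transcription frame;
* oxidation occurring **before** capture affects both strands of the
  original duplex; descendants of either strand are captured equiprobably,
  so pre-capture damage contributes G>T and C>A symmetrically in every
  frame.

`oxoasym` measures these signatures from data and reproduces them
generatively, so that every statistic in the package can be validated
against a known ground truth.

## The counting procedure

Counting starts from pileup text (six-column samtools dialect). Reads
contributing to pileups are assumed pre-filtered to primary, mapped,
non-duplicate, vendor-passing alignments with mapped mates and MAPQ ≥ 60;
`filter_alignments()` applies exactly this rule to SAM records when the
package is given reads rather than pileups. Within a pileup column:

1. calls below base quality 37 are dropped (`min_bq`, configurable);
2. the **singleton rule**: a site contributes only if *exactly one*
   retained call differs from the reference. True variants present on many
   reads; requiring a single mismatching read depletes biological variation
   and leaves mostly technical artefacts. We read "single mismatch" as one
   mismatching *read*; the alternative reading (one distinct mismatching
   allele) is available behind `multiple_alleles = TRUE`;
3. the mismatch is keyed by its directed type on the forward reference
   sense, by the coding strand of the covering capture region, and by the
   alignment direction of the mismatching read.

Loci covered by regions with conflicting strand annotations are undefined
in the transcription frame; we tally them under `strand = "none"`, where
they still contribute to reference-strand totals. Strand-unannotated
regions are treated the same way. This exclusion rule is our choice —
capture-kit BEDs rarely say how to resolve genes overlapping on both
strands — and it is deliberately conservative.

Normalization divides each count by the number of captured positions
carrying the relevant reference base (`composition_of_regions()`), always
tallied once per position on the forward sense; the transcription frame
re-keys counts to the template strand rather than re-tallying, so no
position is ever counted twice. Zero denominators are flagged, never
silently divided.

Ratios default to raw counts rather than normalized rates: within a
mismatch/complement pair the two denominators are the G and C content of
the same captured regions, which are nearly equal, and raw counts keep the
binomial error model exact. A `pseudocount` argument (off by default)
handles zero denominators explicitly; undefined ratios are returned
flagged, not dropped.

## The generative model

`simulate_dataset()` draws a pseudo-chromosome with configurable GC
content, places `n_genes` equal-length target regions with alternating,
balanced-random, or all-forward coding strands, and sequences each region
with `depth` single-end molecules. Per molecule the captured strand follows
the design (`forward_reference`, `template_strand`, `coding_strand`, or
`double_stranded`). Per molecule and site, exactly one event is drawn:

| event | probability | effect |
| --- | --- | --- |
| pre-capture lesion (fwd) | λ_pre·p_mispair/2 at forward-sense G | G→T |
| pre-capture lesion (rev) | λ_pre·p_mispair/2 at forward-sense C | C→A |
| post-capture lesion | λ_post·p_mispair at captured-strand G | G→T or C→A |
| sequencing error | e/3 per alternative base | any |
| germline / somatic allele | site-level, AF ½ / `somatic_vaf` | alt base |

The factor ½ on the pre-capture arm collapses pre-capture amplification to
its essential consequence — a sequenced molecule descends from either
original strand equiprobably — without modelling a PCR tree. Drawing
mutually exclusive events with these exact probabilities (rather than
layering independent processes) keeps `expected_mismatch_rates()` exact by
construction and lets every non-reference call be attributed to exactly one
ground-truth event, which the truth-table audits in the test suite rely
on. The cost is that second-order coincidences (a lesion and an error on
the same call) are absent; at the rates involved (~10⁻³) these are ~10⁻⁶
effects, far below the resolution of any test in the package.

Alignment direction and F1R2/F2R1 class are per-molecule: deterministic
from the lesion strand for lesion-bearing molecules (forward-strand lesion
→ forward alignment, F1R2), uniform otherwise. A read has a single
direction, so the assignment is made at the molecule level; the
deterministic lesion→class mapping is a modelling idealization — real
post-capture amplification dilutes it — but it is the limit in which
orientation-based diagnostics are cleanest.

### Parameters and defaults

| parameter | default | meaning |
| --- | --- | --- |
| `lambda_pre` | 0 | per-G pre-capture lesion probability, per strand |
| `lambda_post` | 0.003 | per-G post-capture lesion probability, captured strand |
| `p_mispair` | 1/3 | P(lesion read as T) |
| `seq_error` | 0.0015 | uniform per-base error, split across 3 alternatives |
| `read_length` | 50 bp | read = region length (one molecule spans its region) |
| `depth` | 40 | molecules per region |
| `gc_fraction` | 0.45 | simulated reference GC |
| `het_rate` / `somatic_rate` | 10⁻³ / 10⁻⁴ | per-site variant probabilities |
| `somatic_vaf` | 0.2 | somatic allele fraction |
| `base_quality` | 40 | uniform Phred quality of calls |

The damage defaults give a closed-form G>T/C>A ratio of
(λ_post·p_mispair + e/3)/(e/3) = 3 under forward capture — the middle of
the per-cohort range reported for heavily affected exome cohorts — and the
50 bp read length matches large biobank exome releases. The heterozygote
rate is the human ~1 per kb; the somatic parameters describe a moderately
mutated tumour. These defaults are the package's study conditions and are
not tuned per analysis.

### What the simulator does not emulate

Fragment-length variation, paired-end inserts, per-cycle quality profiles,
alignment and mapping error, FFPE deamination, copy number, and
context-dependent oxidation (real 8-oxo-G formation is strongly
context-biased, e.g. toward GGC/CGG) are all absent. Passing tests
therefore show that the *statistics* are correct and that the
capture-strand mechanism produces the claimed signatures — not that real
data are this clean. In particular the simulator's uniform base quality
means the BQ filter is exercised by dedicated fixtures, not by the
generative model.

## Statistical machinery

**Exact binomial departure.** For a unique-site type/complement pair the
expected split under no asymmetry is q = n_G/(n_G + n_C) from the captured
composition; `binomial_departure()` returns the exact two-sided p-value in
the minimum-likelihood convention (sum of outcome probabilities no larger
than the observation's), delegated to `stats::binom.test()` and
cross-checked in the tests against direct pmf summation to 10⁻¹². A
calibration test confirms the nominal size at α = 0.05 over 1000 null
replicates of 2000 calls each; 2000 was chosen a priori to keep the exact
test's discreteness from depressing the achievable size below the
two-sided 99% acceptance envelope.

**Batch summaries.** Per-flowcell medians and SDs of per-sample ratios,
with the top ⌈0.1·B⌉ medians flagged (boundary ties all flagged, for
determinism) and within-batch outliers defined by 1.5×IQR. The IQR rule is
a conventional stand-in; the display this reproduces does not state its
own outlier definition.

**Rebalancing filter.** `rebalance_filter()` removes G>T calls from the
lowest quality upward (VCF QUAL, else alt-read support; ties broken by
coordinate for determinism) until the retained count no longer exceeds the
C>A count. On simulated data with read-support qualities, planted somatic
variants survive preferentially over planted single-read artefacts.

**Somatic fraction.** `estimate_somatic_fraction()` converts a per-cell
somatic load into the expected fraction of mismatches that are genuinely
somatic. The per-cell load itself is an input, not estimated here: the
age-based substitution-load model it typically comes from belongs to the
mutation-rate literature, and hard-coding it would couple this package to
one cohort's demography.

## Numerical and design notes

* Coordinates are 0-based half-open internally (BED convention); pileup
  and VCF I/O convert from 1-based at the boundary.
* The singleton rule introduces a second-order depletion at high depth: a
  site yields a singleton with probability d·p·(1−p_any)^(d−1), so strata
  with higher total mismatch rates are slightly under-counted. The effect
  on a ratio is a factor exp(−(d−1)·Δp_any); at the default rates it is
  &lt;1% for depth ≤ 30, which is why the validation studies simulate many
  regions at modest depth (e.g. 1000 regions × 50 bp × depth 20, 10⁶
  site-reads) rather than few regions deeply.
* Validation bands are ±3 binomial standard errors on the log-ratio scale,
  `sqrt(1/numerator + 1/denominator)` — the delta-method SE of a ratio of
  independent counts.
* Replicate seeds in `run_recovery_study()` are `seed + i`; all
  randomness flows through a single integer seed, and fixed seeds give
  byte-identical output files (manifests deliberately carry no
  timestamps).
* `strand_at()` distinguishes `ambiguous` (conflicting annotations) from
  `unknown` (no annotation); both are excluded from transcription-frame
  statistics but kept in reference-frame totals.

## A worked validation

```{r neutrality, eval = FALSE}
cfg <- sim_config(capture_design = "template_strand",
                  n_genes = 1000, depth = 20, genome_length = 100000,
                  lambda_pre = 0, lambda_post = 0.003, p_mispair = 1/3,
                  seq_error = 0.0015, het_rate = 0, somatic_rate = 0,
                  seed = 2027)
ds <- simulate_dataset(cfg)
ct <- tally_mismatches(ds$calls, ds$regions)
reference_strand_ratio(ct, "G>T")$ratio      # ~1: hidden exome-wide
transcription_strand_ratio(ct, "G>T")$ratio  # ~3: the closed form
```

This is the template-strand mechanism end to end: heavy, systematic
oxidative artefact contamination that a reference-strand QC metric would
call clean. The same run under `capture_design = "forward_reference"`
moves the signal into the reference frame; `double_stranded` capture or
`lambda_post = 0` removes it from both. The test suite runs all four
configurations at 10⁶ site-reads.

## Known limitations

* Pileups are consumed, not produced: generating pileups from BAM is left
  to samtools (or the simulator), and overlapping-mate double counting is
  not corrected.
* The variant module reads FILTER strings; it does not re-implement any
  caller's filters or orientation-bias learning.
* Common-variant exclusion takes a user-supplied site list; no annotation
  database is bundled.
* The simulator's lesion→orientation mapping is deterministic (see above);
  per-site orientation fractions on real data will be noisier than
  simulated ones.
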