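#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with exactly one of
#' `input` (paths `pileup`, `bed`, `ref`) or `simulate` (arguments for
#' [sim_config()]), plus optional `min_bq` (default 37), `min_mapq` (60),
#' `pseudocount` (0), `batches` (path to a sample/batch TSV), `outdir`, and
#' `seed` (default 1).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config list, invisibly classed `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    abort("config error: exactly one of 'input' or 'simulate' must be present")
  }
  if (has_input) {
    for (f in c("pileup", "bed", "ref")) {
      if (is.null(config$input[[f]])) {
        abort(paste0("config error: input$", f, " is required"))
      }
      if (!file.exists(config$input[[f]])) {
        abort(paste0("config error: no such file: ", config$input[[f]]))
      }
    }
  }
  config$min_bq <- config$min_bq %||% 37
  config$min_mapq <- config$min_mapq %||% 60
  config$pseudocount <- config$pseudocount %||% 0
  config$seed <- as.integer(config$seed %||% 1L)
  for (f in c("min_bq", "min_mapq", "pseudocount")) {
    if (!is.numeric(config[[f]]) || config[[f]] < 0) {
      abort(paste0("config error: ", f, " must be a non-negative number"))
    }
  }
  if (has_sim && !is.list(config$simulate)) {
    abort("config error: 'simulate' must be a list of sim_config() arguments")
  }
  structure(config, class = "run_config")
}

#' Run the full mismatch-asymmetry pipeline
#'
#' Executes, in order: input loading (or simulation), region composition,
#' singleton-mismatch tallying, composition normalization, and asymmetry
#' ratios in all three modes, writing one TSV per stage plus a JSON manifest
#' (package version, parameters, seed, stage status) and a human-readable
#' summary of the six mismatch/complement pair ratios in both strand frames.
#' Outputs are deterministic given the seed; the manifest carries no
#' timestamps so repeated runs are byte-identical. On a stage failure the
#' outputs of completed stages are retained and the manifest records the
#' failure point before the error is re-signalled.
#'
#' @param config A run configuration (list, YAML path, or `run_config`); see
#'   [validate_run_config()].
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list of class `oxo_run`: `config`, `counts`,
#'   `normalized`, `ratios`, `paths`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_run_config(config)
  outdir <- outdir %||% config$outdir %||% abort("config error: outdir required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "oxoasym",
    version = as.character(utils::packageVersion("oxoasym")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("input", "simulate"))],
    mode = if (!is.null(config$simulate)) "simulate" else "input",
    stages = list()
  )
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fn) {
    result <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      .write_manifest(manifest, outdir)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "ok")
    result
  }

  run_stage("load", function() {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      cfg <- do.call(sim_config, sim_args)
      ds <- simulate_dataset(cfg)
      write_dataset(ds, file.path(outdir, "sim"))
      state$regions <- ds$regions
      state$reference <- ds$reference
      state$pileup <- ds$calls
    } else {
      state$regions <- read_capture_bed(config$input$bed)
      state$reference <- config$input$ref
      state$pileup <- parse_pileup(config$input$pileup)
    }
    invisible(NULL)
  })
  composition <- run_stage("composition", function() {
    comp <- composition_of_regions(state$regions, state$reference)
    .write_tsv(comp, file.path(outdir, "composition.tsv"),
               "composition_of_regions")
    comp
  })
  counts <- run_stage("tally", function() {
    ct <- tally_mismatches(state$pileup, state$regions, min_bq = config$min_bq)
    .write_tsv(ct, file.path(outdir, "counts.tsv"), "tally_mismatches",
               c(sites_considered = attr(ct, "sites_considered"),
                 sites_excluded_multi = attr(ct, "sites_excluded_multi")))
    ct
  })
  normalized <- run_stage("normalize", function() {
    nm <- normalize_counts(counts, composition, frame = "reference")
    .write_tsv(nm, file.path(outdir, "normalized.tsv"), "normalize_counts")
    nm
  })
  ratios <- run_stage("asymmetry", function() {
    rt <- bind_rows(
      asymmetry_ratios(counts, "reference", pseudocount = config$pseudocount),
      asymmetry_ratios(counts, "transcription", pseudocount = config$pseudocount),
      asymmetry_ratios(counts, "alignment_direction",
                       pseudocount = config$pseudocount)
    )
    .write_tsv(rt, file.path(outdir, "ratios.tsv"), "asymmetry_ratios")
    writeLines(.summary_text(rt), file.path(outdir, "summary.txt"))
    rt
  })
  .write_manifest(manifest, outdir)
  invisible(structure(
    list(config = config, counts = counts, normalized = normalized,
         ratios = ratios,
         paths = file.path(outdir, c("composition.tsv", "counts.tsv",
                                     "normalized.tsv", "ratios.tsv",
                                     "summary.txt", "manifest.json"))),
    class = "oxo_run"))
}

.write_tsv <- function(df, path, stage, extra = NULL) {
  header <- paste0("# stage: ", stage)
  if (!is.null(extra)) {
    header <- c(header, paste0("# ", names(extra), ": ", unlist(extra)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df <- as.data.frame(df)
  df$outlier_samples <- NULL
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.summary_text <- function(ratios) {
  six <- ratios %>%
    filter(.data$type < .data$complement) %>%
    mutate(line = sprintf("  %-9s %-20s ratio = %s  (%s / %s)",
                          .data$pair, .data$mode,
                          ifelse(.data$defined, sprintf("%.3f", .data$ratio),
                                 "undefined"),
                          format(.data$numerator), format(.data$denominator)))
  c("Mismatch/complement asymmetry ratios", six$line)
}

#' Parameter-recovery study over replicate simulations
#'
#' Simulates `n_replicates` datasets under one configuration, runs the full
#' tally, and compares the observed reference- and transcription-strand
#' G>T/C>A ratios to their closed-form expectations ([expected_mismatch_rates()]
#' combined with the realized per-stratum base composition). A replicate is
#' "covered" when the observed log-ratio lies within 3 binomial standard
#' errors (`sqrt(1/numerator + 1/denominator)` on the log scale) of the
#' expectation.
#'
#' @param config A run configuration with a `simulate` block.
#' @param n_replicates Number of replicates (>= 2). Replicate `i` uses seed
#'   `seed + i`.
#' @return A `recovery_study` tibble with one row per replicate and
#'   attributes `bias` (mean log2 observed/expected) and `coverage`
#'   (fraction within the 3-SE band) for each mode.
#' @export
run_recovery_study <- function(config, n_replicates) {
  config <- validate_run_config(config)
  if (is.null(config$simulate)) {
    abort("config error: run_recovery_study requires a 'simulate' block")
  }
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    sim_args <- config$simulate
    sim_args$seed <- (sim_args$seed %||% config$seed) + i
    cfg <- do.call(sim_config, sim_args)
    ds <- simulate_dataset(cfg)
    counts <- tally_mismatches(ds$calls, ds$regions, min_bq = config$min_bq)
    comp <- composition_of_regions(ds$regions, ds$reference)
    exp_ratio <- .expected_gt_ca_ratios(cfg, comp)
    obs_ref <- reference_strand_ratio(counts, "G>T")
    obs_txn <- transcription_strand_ratio(counts, "G>T")
    band <- function(obs, expected) {
      if (!obs$defined || obs$numerator == 0) return(NA)
      se <- sqrt(1 / obs$numerator + 1 / obs$denominator)
      abs(log(obs$ratio) - log(expected)) <= 3 * se
    }
    tibble(
      replicate = i, seed = cfg$seed, design = cfg$capture_design,
      ref_numerator = obs_ref$numerator, ref_denominator = obs_ref$denominator,
      ref_ratio = obs_ref$ratio, ref_expected = exp_ratio["reference"],
      ref_covered = band(obs_ref, exp_ratio["reference"]),
      txn_numerator = obs_txn$numerator, txn_denominator = obs_txn$denominator,
      txn_ratio = obs_txn$ratio, txn_expected = exp_ratio["transcription"],
      txn_covered = band(obs_txn, exp_ratio["transcription"])
    )
  }) %>% bind_rows()
  structure(rows,
    bias = c(reference = mean(log2(rows$ref_ratio / rows$ref_expected)),
             transcription = mean(log2(rows$txn_ratio / rows$txn_expected))),
    coverage = c(reference = mean(rows$ref_covered, na.rm = TRUE),
                 transcription = mean(rows$txn_covered, na.rm = TRUE)),
    class = c("recovery_study", class(tibble())))
}

# expected G>T/C>A ratios (reference and transcription frame) from the
# closed-form per-read rates and the realized per-stratum G/C composition
.expected_gt_ca_ratios <- function(cfg, composition) {
  comp <- as_tibble(composition)
  nG <- function(s) sum(comp$count[comp$strand == s & comp$base == "G"])
  nC <- function(s) sum(comp$count[comp$strand == s & comp$base == "C"])
  # captured-strand class of each coding stratum under the design
  class_of <- function(coding) {
    switch(cfg$capture_design,
      forward_reference = "forward",
      coding_strand = if (coding == "+") "forward" else "reverse",
      template_strand = if (coding == "+") "reverse" else "forward",
      double_stranded = "double"
    )
  }
  rate <- function(coding, type) {
    r <- expected_mismatch_rates(cfg, class_of(coding))
    r$rate[r$type == type]
  }
  e_gt <- function(s) nG(s) * rate(s, "G>T")
  e_ca <- function(s) nC(s) * rate(s, "C>A")
  ref_ratio <- (e_gt("+") + e_gt("-")) / (e_ca("+") + e_ca("-"))
  template <- e_ca("+") + e_gt("-")
  coding <- e_gt("+") + e_ca("-")
  c(reference = ref_ratio, transcription = template / coding)
}
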