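# Reporting front-ends: each published summary table maps to one run_*
# function (and one CLI subcommand in inst/cli/aptaquad.R). Every run writes
# its configuration (including seeds) as JSON next to its outputs so results
# are reproducible byte-for-byte.

.read_input <- function(input, column_map = NULL, alphabet = "auto") {
  if (!file.exists(input)) stop("cannot read input: ", input)
  if (grepl("\\.(fa|fasta|fna)$", input, ignore.case = TRUE)) {
    lapply(read_fasta(input, alphabet = alphabet), aptamer_record)
  } else {
    if (is.null(column_map)) column_map <- c(id = "id", sequence = "sequence")
    read_catalog(input, column_map = column_map, alphabet = alphabet)
  }
}

.write_run_config <- function(output_dir, command, config, extra = list()) {
  cfg <- c(list(command = command,
                window = config$window,
                thresholds = config$thresholds,
                report_negative = config$report_negative),
           extra)
  jsonlite::write_json(cfg, file.path(output_dir, paste0(command, "_config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Score and classify a catalog or FASTA file
#'
#' Writes `scores.tsv` with one row per record (whole-sequence score, best
#' window score, sign, and per-threshold motif flags and counts; see
#' [classify_library()]).
#'
#' @param input path to a FASTA file (`.fa`/`.fasta`/`.fna`) or a delimited
#'   catalog.
#' @param output_dir directory for outputs (created if needed).
#' @param config a [scan_config()].
#' @param column_map catalog column mapping (see [read_catalog()]).
#' @param alphabet default alphabet for the input.
#' @return The classification data frame, invisibly.
#' @export
run_score <- function(input, output_dir = ".", config = scan_config(),
                      column_map = NULL, alphabet = "auto") {
  records <- .read_input(input, column_map, alphabet)
  cls <- classify_library(records, config)
  .ensure_dir(output_dir)
  utils::write.table(cls, file.path(output_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_run_config(output_dir, "score", config,
                    list(input = input, n_records = nrow(cls)))
  invisible(cls)
}

#' Scan a library and write merged PQS regions
#'
#' Writes `regions.bed`, the BED-like region table of [find_pqs()] calls over
#' all records at one threshold.
#'
#' @inheritParams run_score
#' @param threshold region-calling threshold (default: the smallest
#'   configured threshold).
#' @return The combined region data frame, invisibly.
#' @export
run_scan <- function(input, output_dir = ".", config = scan_config(),
                     threshold = min(config$thresholds),
                     column_map = NULL, alphabet = "auto") {
  records <- .read_input(input, column_map, alphabet)
  regions <- do.call(rbind, lapply(records, function(r)
    find_pqs(r$sequence, config, threshold)))
  .ensure_dir(output_dir)
  write_regions(regions, file.path(output_dir, "regions.bed"))
  .write_run_config(output_dir, "scan", config,
                    list(input = input, threshold = threshold,
                         n_regions = if (is.null(regions)) 0L else nrow(regions)))
  invisible(regions)
}

#' Shuffle study on the motif-positive records of a catalog
#'
#' Filters the input to records with at least one motif at `threshold`, runs
#' [shuffle_study()], and writes `shuffle_summary.tsv` (a two-column
#' feature/value table) plus a JSON summary with seed and configuration.
#'
#' @inheritParams run_score
#' @param threshold motif threshold.
#' @param seed integer seed (recorded in the outputs).
#' @param n_shuffles shuffle replicates per record.
#' @return The `shuffle_summary`, invisibly.
#' @export
run_shuffle <- function(input, output_dir = ".", threshold = 1.2,
                        seed = NULL, n_shuffles = 1L, config = scan_config(),
                        column_map = NULL, alphabet = "auto") {
  records <- .read_input(input, column_map, alphabet)
  cls <- classify_library(records, scan_config(config$window, threshold,
                                               config$report_negative))
  pos <- records[cls[[paste0("has_", threshold)]]]
  if (!length(pos))
    stop("no record carries a motif at threshold ", threshold)
  summ <- shuffle_study(pos, threshold = threshold, config = config,
                        seed = seed, n_shuffles = n_shuffles)
  .ensure_dir(output_dir)
  tab <- data.frame(
    feature = c("sequences_analyzed", "g4_count_original", "g4_count_shuffled",
                "seqs_with_g4_original", "seqs_with_g4_shuffled",
                "delta_seqs_with_g4", "pct_decrease_seqs",
                "delta_g4_count", "pct_decrease_count"),
    value = c(summ$n_sequences_analyzed, summ$g4_count_original,
              summ$g4_count_shuffled, summ$seqs_with_g4_original,
              summ$seqs_with_g4_shuffled, summ$delta_seqs_with_g4,
              summ$pct_decrease_seqs, summ$delta_g4_count,
              summ$pct_decrease_count))
  utils::write.table(tab, file.path(output_dir, "shuffle_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summ[setdiff(names(summ), "config")],
                       file.path(output_dir, "shuffle_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_run_config(output_dir, "shuffle", config,
                    list(input = input, threshold = threshold,
                         seed = summ$seed, n_shuffles = n_shuffles))
  invisible(summ)
}

#' Compare catalog motif prevalence against a random baseline
#'
#' Generates `n` i.i.d. random sequences of the given length and
#' composition, then for each configured threshold runs a pooled
#' two-proportion z-test of catalog vs baseline prevalence, separately for
#' G-rich and C-rich motifs (quadruplex enrichment is a claim about the
#' G-rich sign; the C-rich test is its i-motif counterpart). Writes
#' `baseline_ztest.tsv` and a JSON report.
#'
#' @inheritParams run_score
#' @param n number of baseline sequences (>= 100).
#' @param length baseline sequence length in nucleotides.
#' @param composition baseline base probabilities (A, C, G, T); default
#'   uniform.
#' @param match_composition if `TRUE`, ignore `composition` and use the
#'   empirical mean base composition of the catalog.
#' @param seed integer seed for the baseline draw.
#' @return A data frame with one row per threshold x sign: catalog and
#'   baseline counts, proportions, `z`, and `p`, invisibly.
#' @export
run_baseline <- function(input, output_dir = ".", n = 100000L, length = 80L,
                         composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         match_composition = FALSE, seed = NULL,
                         config = scan_config(), column_map = NULL,
                         alphabet = "auto") {
  n <- as.integer(n)
  if (is.na(n) || n < 100L) stop("'n' must be >= 100 baseline sequences")
  records <- .read_input(input, column_map, alphabet)
  if (match_composition) {
    comp <- composition_report(records)
    comp <- tapply(comp$mean_pct * comp$n_records, comp$base, sum) /
      sum(vapply(records, function(r) 1L, 0L)) / 100
    comp["T"] <- sum(comp[c("T", "U")], na.rm = TRUE)
    composition <- comp[c("A", "C", "G", "T")] / sum(comp[c("A", "C", "G", "T")])
  }
  .check_composition(composition)
  cat_prev <- motif_prevalence(records, config)
  base_lib <- random_library(n, length = length, composition = composition,
                             seed = seed, as_records = FALSE)
  base_prev <- motif_prevalence(base_lib, config)
  rows <- NULL
  for (i in seq_along(config$thresholds)) {
    for (sgn in c("g_rich", "c_rich")) {
      x1 <- cat_prev[[paste0("n_", sgn)]][i]
      x2 <- base_prev[[paste0("n_", sgn)]][i]
      zt <- two_proportion_z(x1, cat_prev$n[i], x2, base_prev$n[i])
      rows <- rbind(rows, data.frame(
        threshold = config$thresholds[i], sign = sgn,
        catalog_with = x1, catalog_n = cat_prev$n[i],
        baseline_with = x2, baseline_n = base_prev$n[i],
        catalog_pct = 100 * zt$p1_hat, baseline_pct = 100 * zt$p2_hat,
        z = zt$z, p = zt$p_two_sided, stringsAsFactors = FALSE))
    }
  }
  .ensure_dir(output_dir)
  utils::write.table(rows, file.path(output_dir, "baseline_ztest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = if (is.null(seed)) NA else seed, n_baseline = n,
         baseline_length = length,
         composition = as.list(stats::setNames(as.numeric(composition),
                                               c("A", "C", "G", "T"))),
         tests = rows),
    file.path(output_dir, "baseline_ztest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_run_config(output_dir, "baseline", config,
                    list(input = input, n = n, length = length,
                         seed = if (is.null(seed)) NA else seed))
  invisible(rows)
}

#' Simulate a SELEX-like library to disk
#'
#' Writes `library.fasta` and the truth-label sidecar `truth_labels.tsv`
#' for a [library_spec()].
#'
#' @param spec a [library_spec()] (set `spec$seed` for reproducible output).
#' @param output_dir directory for outputs.
#' @return The `synthetic_library`, invisibly.
#' @export
run_simulate <- function(spec, output_dir = ".") {
  lib <- generate_library(spec)
  .ensure_dir(output_dir)
  write_fasta(lib$records, file.path(output_dir, "library.fasta"))
  utils::write.table(lib$labels, file.path(output_dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_run_config(output_dir, "simulate", scan_config(),
                    list(n_records = spec$n_records,
                         planted_fraction = spec$planted_fraction,
                         planted_motif = spec$planted_motif,
                         seed = spec$seed))
  invisible(lib)
}
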