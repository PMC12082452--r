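#' Shuffle a sequence (composition-preserving null)
#'
#' Returns a uniformly random permutation of the residues: the exact base
#' multiset is preserved, so any drop in propensity after shuffling reflects
#' base *ordering* (clustered G runs), not base content.
#'
#' @inheritParams per_base_scores
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can seed once for a whole study).
#' @return A `nucleic_sequence` with permuted residues and unchanged id,
#'   alphabet, and ambiguity count.
#' @export
shuffle_sequence <- function(x, seed = NULL) {
  s <- as_nucleic(x)
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(s$residues, "", fixed = TRUE)[[1L]]
  out <- s
  out$residues <- paste(sample(chars), collapse = "")
  out
}

#' Shuffle study: does motif prevalence survive permutation?
#'
#' Takes motif-bearing records, shuffles each one (preserving composition),
#' rescans, and summarizes how many sequences and how many merged motifs
#' survive. Records without a motif at `threshold` are dropped with a
#' warning: the study is defined on the motif-positive subset.
#'
#' With `n_shuffles > 1`, shuffled counts are averaged over replicates and
#' their standard deviations reported.
#'
#' @param records motif-positive sequence collection.
#' @param threshold scan threshold defining a motif (absolute window mean).
#' @param config a [scan_config()].
#' @param seed integer seed for reproducibility (recorded in the summary).
#' @param n_shuffles independent shuffle replicates (default 1, the
#'   one-shuffle-per-sequence design).
#' @return An object of class `shuffle_summary`: counts for the original and
#'   shuffled libraries, deltas, percent decreases (100 * delta / original),
#'   retained fractions, replicate standard deviations (if `n_shuffles > 1`),
#'   the seed, threshold, and config. Motif counts are merged regions of
#'   either sign (see [find_pqs()]).
#' @export
shuffle_study <- function(records, threshold = 1.2, config = scan_config(),
                          seed = NULL, n_shuffles = 1L) {
  seqs <- as_nucleic_list(records)
  if (!length(seqs)) stop("empty record list")
  n_shuffles <- as.integer(n_shuffles)
  if (is.na(n_shuffles) || n_shuffles < 1L) stop("'n_shuffles' must be >= 1")

  count_motifs <- function(ss) vapply(ss, function(s)
    nrow(find_pqs(s, config, threshold)), 0L)

  orig_counts <- count_motifs(seqs)
  if (any(orig_counts == 0L)) {
    if (all(orig_counts == 0L))
      stop("no record carries a motif at threshold ", threshold,
           "; the shuffle study is defined on motif-positive records")
    warning(sum(orig_counts == 0L),
            " record(s) without a motif at threshold ", threshold, " dropped")
    seqs <- seqs[orig_counts > 0L]
    orig_counts <- orig_counts[orig_counts > 0L]
  }
  n <- length(seqs)
  if (!is.null(seed)) set.seed(seed)
  shuf_seq <- numeric(n_shuffles)   # sequences retaining >= 1 motif
  shuf_cnt <- numeric(n_shuffles)   # total motif count after shuffling
  for (r in seq_len(n_shuffles)) {
    counts <- count_motifs(lapply(seqs, shuffle_sequence))
    shuf_seq[r] <- sum(counts > 0L)
    shuf_cnt[r] <- sum(counts)
  }
  g4_orig <- sum(orig_counts)
  structure(
    list(n_sequences_analyzed = n,
         g4_count_original = g4_orig,
         g4_count_shuffled = mean(shuf_cnt),
         seqs_with_g4_original = n,
         seqs_with_g4_shuffled = mean(shuf_seq),
         seqs_without_g4_shuffled = n - mean(shuf_seq),
         delta_seqs_with_g4 = n - mean(shuf_seq),
         pct_decrease_seqs = 100 * (n - mean(shuf_seq)) / n,
         pct_retained_seqs = 100 * mean(shuf_seq) / n,
         delta_g4_count = g4_orig - mean(shuf_cnt),
         pct_decrease_count = 100 * (g4_orig - mean(shuf_cnt)) / g4_orig,
         pct_retained_count = 100 * mean(shuf_cnt) / g4_orig,
         sd_seqs_with_g4_shuffled = if (n_shuffles > 1L) stats::sd(shuf_seq) else NA_real_,
         sd_g4_count_shuffled = if (n_shuffles > 1L) stats::sd(shuf_cnt) else NA_real_,
         n_shuffles = n_shuffles,
         threshold = threshold,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         config = config),
    class = "shuffle_summary"
  )
}

#' @export
print.shuffle_summary <- function(x, ...) {
  cat("Shuffle study (motif = merged region, |window mean| >=",
      x$threshold, ")\n")
  fmt <- function(v) formatC(v, digits = 1, format = "f", drop0trailing = TRUE)
  cat(sprintf("  Sequences analyzed:        %d\n", x$n_sequences_analyzed))
  cat(sprintf("  Motif count:               %d -> %s after shuffling\n",
              x$g4_count_original, fmt(x$g4_count_shuffled)))
  cat(sprintf("  Sequences with motif:      %d -> %s after shuffling\n",
              x$seqs_with_g4_original, fmt(x$seqs_with_g4_shuffled)))
  cat(sprintf("  Delta sequences with motif: %s (%.1f%% decrease)\n",
              fmt(x$delta_seqs_with_g4), x$pct_decrease_seqs))
  cat(sprintf("  Delta motif count:          %s (%.1f%% decrease)\n",
              fmt(x$delta_g4_count), x$pct_decrease_count))
  if (x$n_shuffles > 1L)
    cat(sprintf("  (%d shuffle replicates; sd retained seqs %.2f, sd count %.2f)\n",
                x$n_shuffles, x$sd_seqs_with_g4_shuffled, x$sd_g4_count_shuffled))
  invisible(x)
}

#' Generate an i.i.d. random sequence library
#'
#' Each base is drawn independently from `composition`; the standard baseline
#' against which catalog motif prevalence is compared (the published analysis
#' used 100,000 random 80-nt sequences).
#'
#' @param n number of sequences (>= 1).
#' @param length sequence length in nucleotides.
#' @param composition probabilities for A, C, G, T (or U for RNA), in that
#'   order; must sum to 1.
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @param seed optional integer seed.
#' @param as_records if `TRUE` (default) return a list of
#'   `nucleic_sequence`; if `FALSE` return a bare character vector (cheaper
#'   for very large baselines, accepted by [motif_prevalence()] and
#'   [classify_library()]).
#' @return A list of `nucleic_sequence`, or a named character vector.
#' @export
random_library <- function(n, length = 80L,
                           composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           alphabet = c("DNA", "RNA"), seed = NULL,
                           as_records = TRUE) {
  alphabet <- match.arg(alphabet)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  .check_composition(composition)
  if (!is.null(seed)) set.seed(seed)
  bases <- if (alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  chr <- vapply(seq_len(n), function(i)
    paste(sample(bases, length, replace = TRUE, prob = composition), collapse = ""),
    "")
  names(chr) <- sprintf("rand_%06d", seq_len(n))
  if (!as_records) return(chr)
  mapply(function(s, id) {
    structure(list(id = id, residues = s, alphabet = alphabet,
                   n_ambiguous = 0L), class = "nucleic_sequence")
  }, chr, names(chr), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

.check_composition <- function(composition) {
  if (!is.numeric(composition) || length(composition) != 4L ||
      any(is.na(composition)) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8)
    stop("'composition' must be 4 non-negative probabilities summing to 1")
  invisible(TRUE)
}

#' Two-proportion z-test (pooled)
#'
#' Compares `x1/n1` against `x2/n2` with the pooled-variance normal
#' approximation: `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' `p = (x1 + x2)/(n1 + n2)`; two-sided p-value from the standard normal.
#' When the pooled proportion is degenerate (0 or 1) the test is vacuous and
#' returns `z = 0`, `p = 1` by convention.
#'
#' @param x1,n1 successes and size of group 1.
#' @param x2,n2 successes and size of group 2.
#' @param correct apply the continuity correction `0.5*(1/n1 + 1/n2)` to the
#'   absolute difference (default `FALSE`, the conventional plain z-test).
#' @return An object of class `two_prop_z` with elements `p1_hat`, `p2_hat`,
#'   `p_pooled`, `z`, `p_two_sided`, the input counts, and `correct`.
#' @examples
#' two_proportion_z(20, 100, 10, 100)  # z ~ 1.98, p ~ 0.048
#' @export
two_proportion_z <- function(x1, n1, x2, n2, correct = FALSE) {
  if (any(!is.finite(c(x1, n1, x2, n2)))) stop("counts must be finite")
  if (n1 < 1 || n2 < 1) stop("'n1' and 'n2' must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("need 0 <= x1 <= n1 and 0 <= x2 <= n2")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    z <- 0
    p <- 1
  } else {
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    d <- p1 - p2
    if (correct) {
      cc <- 0.5 * (1 / n1 + 1 / n2)
      d <- sign(d) * max(0, abs(d) - cc)
    }
    z <- d / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(p1_hat = p1, p2_hat = p2, p_pooled = pp, z = z,
                 p_two_sided = p, x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                 correct = correct),
            class = "two_prop_z")
}

#' @export
print.two_prop_z <- function(x, ...) {
  cat("Two-proportion z-test (pooled",
      if (x$correct) ", continuity-corrected)" else ")", "\n", sep = "")
  cat(sprintf("  p1 = %d/%d = %.4f   p2 = %d/%d = %.4f   pooled = %.4f\n",
              round(x$x1), round(x$n1), x$p1_hat,
              round(x$x2), round(x$n2), x$p2_hat, x$p_pooled))
  cat(sprintf("  z = %.4f,  two-sided p = %.4g\n", x$z, x$p_two_sided))
  invisible(x)
}

#' Motif prevalence stratified by alphabet and threshold
#'
#' Counts, per alphabet stratum (DNA, RNA, and the pooled `all` stratum) and
#' per configured threshold, the records carrying at least one motif of
#' either sign (|window mean| >= threshold, whole-sequence fallback for short
#' records).
#'
#' @inheritParams classify_library
#' @return A data frame with columns `alphabet`, `threshold`, `n_with_g4`,
#'   `n_without`, `pct_with`. Strata with zero records are omitted with a
#'   warning.
#' @export
prevalence_by_stratum <- function(x, config = scan_config()) {
  seqs <- as_nucleic_list(x)
  if (!length(seqs)) stop("empty sequence collection")
  alpha <- vapply(seqs, function(s) s$alphabet, "")
  out <- NULL
  for (a in c("DNA", "RNA", "all")) {
    sel <- if (a == "all") rep(TRUE, length(seqs)) else alpha == a
    if (!any(sel)) {
      warning("no ", a, " records; stratum omitted")
      next
    }
    prev <- motif_prevalence(seqs[sel], config)
    out <- rbind(out, data.frame(alphabet = a, threshold = prev$threshold,
                                 n_with_g4 = prev$n_any,
                                 n_without = prev$n - prev$n_any,
                                 pct_with = prev$pct_any,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Sign bias of motif-bearing records
#'
#' Counts records with at least one G-rich motif and records with at least
#' one C-rich motif at the given threshold. A record carrying motifs of both
#' signs contributes to both counts (once each).
#'
#' @inheritParams classify_library
#' @param threshold scan threshold.
#' @return A named integer vector
#'   `c(n_positive_sign = ..., n_negative_sign = ...)`.
#' @export
sign_bias <- function(x, threshold = 1.2, config = scan_config()) {
  cfg <- scan_config(config$window, threshold, report_negative = TRUE)
  prev <- motif_prevalence(x, cfg)
  c(n_positive_sign = as.integer(prev$n_g_rich),
    n_negative_sign = as.integer(prev$n_c_rich))
}
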