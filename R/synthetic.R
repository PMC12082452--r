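#' Specification of a synthetic SELEX-like library
#'
#' Describes a pool of aptamer-like sequences with the architecture of a raw
#' SELEX library: a central randomized core (default 20-50 nt) flanked by
#' fixed primer-binding regions (default 18 nt each, generated once per
#' library), with an optional fraction of records carrying a planted
#' quadruplex motif at a random core offset, recorded in truth labels.
#'
#' @param n_records number of sequences.
#' @param core_length_range integer `c(min, max)` core length (default
#'   `c(20, 50)`); cores are drawn uniformly in this range.
#' @param primer_5,primer_3 either a flank sequence (character) used as-is,
#'   or an integer length (default 18) for a flank generated once per
#'   library from `composition`.
#' @param composition probabilities for A, C, G, T/U in the random core.
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @param planted_fraction fraction of records that carry `planted_motif`;
#'   exactly `round(planted_fraction * n_records)` records are planted.
#' @param planted_motif motif inserted into planted cores. The default
#'   `GGGTGGGTGGG TGGG`-style 4xG3 tract scores 36/15 = 2.4 over its own
#'   length. Use a C-rich motif to plant i-motif truth instead.
#' @param flank_style `"gc_run_free"` (default): generated flanks are
#'   rejected until they contain no G or C run of length >= 3, giving clean
#'   detection truth; `"random"`: flanks drawn like the core, which makes
#'   non-planted records statistically identical to an i.i.d. random library
#'   of the same length.
#' @param clean_site if `TRUE` (default), up to 10 nt of core on each side of
#'   a planted motif are resampled cytosine-free, so the planted spike-in is
#'   detectable by construction: a 25-nt window aligned on the default 15-nt
#'   motif then sums to at least 36 (mean 1.44 >= 1.2), whereas chance C runs
#'   beside the motif would otherwise cancel ~0.3% of plantings below
#'   threshold. Set `FALSE` for fully uniform surroundings.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(n_records,
                         core_length_range = c(20L, 50L),
                         primer_5 = 18L, primer_3 = 18L,
                         composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         alphabet = c("DNA", "RNA"),
                         planted_fraction = 0,
                         planted_motif = "GGGTGGGTGGGTGGG",
                         flank_style = c("gc_run_free", "random"),
                         clean_site = TRUE,
                         seed = NULL) {
  alphabet <- match.arg(alphabet)
  flank_style <- match.arg(flank_style)
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L) stop("'n_records' must be >= 1")
  core_length_range <- as.integer(core_length_range)
  if (length(core_length_range) != 2L || any(is.na(core_length_range)) ||
      core_length_range[1L] < 1L || core_length_range[1L] > core_length_range[2L])
    stop("'core_length_range' must be c(min, max) with 1 <= min <= max")
  .check_composition(composition)
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("'planted_fraction' must be in [0, 1]")
  planted_motif <- toupper(planted_motif)
  if (planted_fraction > 0 && nchar(planted_motif) > core_length_range[1L])
    stop("planted motif (", nchar(planted_motif),
         " nt) is longer than the minimum core length (", core_length_range[1L], ")")
  structure(list(n_records = n_records,
                 core_length_range = core_length_range,
                 primer_5 = primer_5, primer_3 = primer_3,
                 composition = composition,
                 alphabet = alphabet,
                 planted_fraction = planted_fraction,
                 planted_motif = planted_motif,
                 flank_style = flank_style,
                 clean_site = isTRUE(clean_site),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> %d %s records: flank(%s) + core[%d-%d] + flank(%s)\n",
              x$n_records, x$alphabet,
              if (is.character(x$primer_5)) x$primer_5 else paste0(x$primer_5, " nt"),
              x$core_length_range[1L], x$core_length_range[2L],
              if (is.character(x$primer_3)) x$primer_3 else paste0(x$primer_3, " nt")))
  if (x$planted_fraction > 0)
    cat(sprintf("  planted: %s in %.0f%% of records\n",
                x$planted_motif, 100 * x$planted_fraction))
  invisible(x)
}

# One random flank; gc_run_free flanks are rejection-sampled until free of
# any G or C run of length >= 3 and, in the 10 bases adjacent to the core,
# free of CC dinucleotides. The edge condition bounds the C penalty a scan
# window picks up when a planted motif sits in a minimal-length core and the
# window spills into the flank: isolated Cs cost at most 1 each, so the
# clean-site detection guarantee (see library_spec) extends to every core
# length. 'side' is "5p" (core-adjacent end is the tail) or "3p" (the head).
.random_flank <- function(len, bases, composition, style, side) {
  repeat {
    f <- paste(sample(bases, len, replace = TRUE, prob = composition), collapse = "")
    if (style == "random") return(f)
    if (grepl("GGG|CCC", f)) next
    edge <- if (side == "5p") substr(f, max(1L, len - 9L), len) else
      substr(f, 1L, min(len, 10L))
    if (!grepl("CC", edge)) return(f)
  }
}

#' Generate a synthetic library with truth labels
#'
#' Deterministic given `spec$seed`: the same spec yields byte-identical
#' sequences. Flanks are generated once and shared by all records, as in a
#' real SELEX pool. Exactly `round(planted_fraction * n_records)` records
#' (chosen at random) have the planted motif written into their core at a
#' uniformly random offset; the motif's position in the full record is
#' recorded in the labels.
#'
#' @param spec a [library_spec()].
#' @return An object of class `synthetic_library`: a list with `records`
#'   (list of `aptamer_record`), `labels` (data frame: `id`, `planted`,
#'   `motif_start`, `motif_end` in 0-based half-open full-record
#'   coordinates), and `spec`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  if (!is.na(spec$seed)) set.seed(spec$seed)
  bases <- if (spec$alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  motif <- spec$planted_motif
  if (spec$alphabet == "RNA") motif <- chartr("T", "U", motif)

  mk_flank <- function(p, side) {
    if (is.character(p)) return(toupper(p))
    .random_flank(as.integer(p), bases, spec$composition, spec$flank_style, side)
  }
  f5 <- mk_flank(spec$primer_5, "5p")
  f3 <- mk_flank(spec$primer_3, "3p")

  n <- spec$n_records
  lens <- if (spec$core_length_range[1L] == spec$core_length_range[2L])
    rep(spec$core_length_range[1L], n)
  else
    sample(spec$core_length_range[1L]:spec$core_length_range[2L], n, replace = TRUE)

  n_plant <- round(spec$planted_fraction * n)
  planted <- rep(FALSE, n)
  if (n_plant > 0) planted[sample(n, n_plant)] <- TRUE
  mlen <- nchar(motif)

  ids <- sprintf("synth_%05d", seq_len(n))
  records <- vector("list", n)
  motif_start <- rep(NA_integer_, n)
  motif_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    core <- paste(sample(bases, lens[i], replace = TRUE, prob = spec$composition),
                  collapse = "")
    if (planted[i]) {
      off <- sample.int(lens[i] - mlen + 1L, 1L) - 1L  # 0-based core offset
      substr(core, off + 1L, off + mlen) <- motif
      if (spec$clean_site) {
        # C-free insertion-site pads: guarantees a qualifying scan window
        nonC <- bases[bases != "C"]
        pC <- if (sum(spec$composition[-2L]) > 0)
          spec$composition[-2L] / sum(spec$composition[-2L])
        else rep(1 / 3, 3L)
        for (pad in list(c(max(1L, off - 9L), off),
                         c(off + mlen + 1L, min(lens[i], off + mlen + 10L)))) {
          if (pad[1L] <= pad[2L]) {
            k <- pad[2L] - pad[1L] + 1L
            substr(core, pad[1L], pad[2L]) <-
              paste(sample(nonC, k, replace = TRUE, prob = pC), collapse = "")
          }
        }
      }
      motif_start[i] <- nchar(f5) + off
      motif_end[i] <- motif_start[i] + mlen
    }
    s <- structure(list(id = ids[i],
                        residues = paste0(f5, core, f3),
                        alphabet = spec$alphabet,
                        n_ambiguous = 0L),
                   class = "nucleic_sequence")
    records[[i]] <- structure(list(sequence = s, target = NA_character_,
                                   reference = NA_character_,
                                   length_nt = nchar(s$residues)),
                              class = "aptamer_record")
  }
  structure(list(records = records,
                 labels = data.frame(id = ids, planted = planted,
                                     motif_start = motif_start,
                                     motif_end = motif_end,
                                     stringsAsFactors = FALSE),
                 primer_5 = f5, primer_3 = f3,
                 spec = spec),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  lens <- vapply(x$records, function(r) r$length_nt, 0L)
  cat(sprintf("<synthetic_library> %d %s records, %d-%d nt (%d planted)\n",
              length(x$records), x$spec$alphabet, min(lens), max(lens),
              sum(x$labels$planted)))
  cat(sprintf("  flanks: 5' %s / 3' %s\n", x$primer_5, x$primer_3))
  invisible(x)
}

#' Base-composition report of a library
#'
#' Mean and standard deviation, across records, of each record's base
#' percentages (A, C, G, T/U; `N` placeholders dilute the denominator).
#' Mixed DNA/RNA input is stratified by alphabet.
#'
#' @inheritParams classify_library
#' @return A data frame with columns `alphabet`, `base`, `mean_pct`,
#'   `sd_pct`, and `n_records`.
#' @export
composition_report <- function(x) {
  seqs <- as_nucleic_list(x)
  if (!length(seqs)) stop("empty sequence collection")
  alpha <- vapply(seqs, function(s) s$alphabet, "")
  out <- NULL
  for (a in unique(alpha)) {
    sub <- seqs[alpha == a]
    bases <- if (a == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
    pct <- t(vapply(sub, function(s) {
      chars <- strsplit(s$residues, "", fixed = TRUE)[[1L]]
      100 * vapply(bases, function(b) sum(chars == b), 0) / length(chars)
    }, numeric(4L)))
    out <- rbind(out, data.frame(
      alphabet = a, base = bases,
      mean_pct = colMeans(pct),
      sd_pct = if (nrow(pct) > 1L) apply(pct, 2L, stats::sd) else rep(0, 4L),
      n_records = length(sub), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
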