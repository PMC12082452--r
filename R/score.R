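# Window-qualification tolerance: a window qualifies when its integer score
# sum s satisfies s >= t*W - .score_eps. Thresholds like 1.2 are not exactly
# representable in binary floating point (1.2 * 25 evaluates slightly above
# 30), so a strict comparison on t*W would wrongly reject windows that sit
# exactly on the threshold. The brute-force test oracle shares this rule as
# part of the contract.
.score_eps <- 1e-9

#' Scan configuration for propensity analysis
#'
#' Holds the sliding-window width and the classification thresholds used
#' throughout the package. The defaults (window of 25 nt; thresholds 1.2,
#' 1.5, 2.0) are the standard operating point for quadruplex-propensity
#' screening: 1.2 flags likely candidates, 1.5 marks sequences that almost
#' always form stable G4s, and 2.0 is near-certain.
#'
#' @param window integer window width in nucleotides (>= 2).
#' @param thresholds strictly increasing positive thresholds.
#' @param report_negative if `TRUE` (default), C-rich (i-motif candidate)
#'   regions with window means `<= -threshold` are reported alongside G-rich
#'   regions.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window = 25L, thresholds = c(1.2, 1.5, 2.0),
                        report_negative = TRUE) {
  window <- as.integer(window)
  if (is.na(window) || window < 2L) stop("'window' must be an integer >= 2")
  if (!is.numeric(thresholds) || length(thresholds) < 1L || any(thresholds <= 0))
    stop("'thresholds' must be positive numbers")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing")
  structure(list(window = window,
                 thresholds = as.numeric(thresholds),
                 report_negative = isTRUE(report_negative)),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> window = %d nt, thresholds = %s, C-rich reported: %s\n",
              x$window, paste(x$thresholds, collapse = "/"),
              if (x$report_negative) "yes" else "no"))
  invisible(x)
}

# Per-base run scores from a residue string, no validation. The unit of the
# whole engine: each base inside a maximal run of k consecutive G scores
# +min(k, 4); each base in a run of k consecutive C scores -min(k, 4); every
# other character (A, T, U, N) scores 0 and terminates runs.
.pb_scores <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  code <- integer(length(chars))
  code[chars == "G"] <- 1L
  code[chars == "C"] <- -1L
  r <- rle(code)
  rep.int(r$values * pmin.int(r$lengths, 4L), r$lengths)
}

# Sliding-window integer sums of a per-base vector (step 1); numeric(0) when
# the sequence is shorter than the window.
.window_sums <- function(pb, window) {
  n <- length(pb)
  if (n < window) return(integer(0))
  cs <- cumsum(c(0L, pb))
  cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
}

#' Per-base quadruplex-propensity scores
#'
#' Each base in a maximal run of `k` consecutive guanines scores `+min(k, 4)`;
#' each base in a run of `k` consecutive cytosines scores `-min(k, 4)`; all
#' other residues (A, T, U, and the `N` placeholder) score 0 and terminate
#' runs. The arithmetic mean of these values over a window or a whole
#' sequence is the propensity score: positive means G4-prone, negative means
#' C-rich / i-motif-prone on the given strand.
#'
#' @param x a `nucleic_sequence`, `aptamer_record`, or bare string.
#' @return Integer vector, one value in `[-4, 4]` per residue.
#' @examples
#' per_base_scores("GGTTGGTGTGGTTGG")  # sums to 17
#' @export
per_base_scores <- function(x) {
  s <- as_nucleic(x)
  .pb_scores(s$residues)
}

#' Whole-sequence propensity score
#'
#' The arithmetic mean of [per_base_scores()] over the full sequence. This is
#' the value reported for aptamers shorter than the scan window, e.g. the
#' 15-nt thrombin-binding aptamer `GGTTGGTGTGGTTGG` scores 17/15 = 1.133.
#'
#' @inheritParams per_base_scores
#' @return A number in `[-4, 4]`.
#' @examples
#' sequence_score("GGTTGGTGTGGTTGG")          # 1.1333...
#' sequence_score("CCCCCTCCTCCCTCCCCCACCC")   # -2.8181...
#' @export
sequence_score <- function(x) {
  pb <- per_base_scores(x)
  sum(pb) / length(pb)
}

#' Sliding-window mean scores
#'
#' Window means are slices of one global per-base score vector: runs are
#' measured once over the full sequence and then averaged per window, so a
#' run crossing a window edge keeps the value earned from its full length.
#' This makes whole-sequence and windowed scores mutually consistent (for a
#' sequence of exactly the window length the single window mean equals
#' [sequence_score()]).
#'
#' @inheritParams per_base_scores
#' @param config a [scan_config()].
#' @return A data frame with columns `start` (0-based window start) and
#'   `mean`; zero rows, with attribute `fallback = TRUE`, when the sequence
#'   is shorter than the window (callers then use the whole-sequence score).
#' @export
window_means <- function(x, config = scan_config()) {
  pb <- per_base_scores(x)
  ws <- .window_sums(pb, config$window)
  if (!length(ws)) {
    out <- data.frame(start = integer(0), mean = numeric(0))
    attr(out, "fallback") <- TRUE
    return(out)
  }
  out <- data.frame(start = seq_along(ws) - 1L, mean = ws / config$window)
  attr(out, "fallback") <- FALSE
  out
}

#' Score profile of one sequence
#'
#' Bundles the per-base scores, the whole-sequence mean, and the window means
#' for one sequence under one configuration.
#'
#' @inheritParams window_means
#' @return An object of class `score_profile` with elements `sequence_id`,
#'   `alphabet`, `per_base`, `mean_score`, `window`, `window_means`
#'   (data frame, empty with `fallback = TRUE` for short sequences), and
#'   `fallback`.
#' @export
score_profile <- function(x, config = scan_config()) {
  s <- as_nucleic(x)
  pb <- .pb_scores(s$residues)
  wm <- window_means(s, config)
  structure(
    list(sequence_id = s$id,
         alphabet = s$alphabet,
         per_base = pb,
         mean_score = sum(pb) / length(pb),
         window = config$window,
         window_means = wm,
         fallback = isTRUE(attr(wm, "fallback"))),
    class = "score_profile"
  )
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> %s [%s, %d nt]\n", x$sequence_id, x$alphabet,
              length(x$per_base)))
  cat(sprintf("  whole-sequence score: %.3f\n", x$mean_score))
  if (x$fallback) {
    cat(sprintf("  shorter than window (%d nt): whole-sequence fallback\n", x$window))
  } else {
    cat(sprintf("  %d windows of %d nt; window mean range [%.3f, %.3f]\n",
                nrow(x$window_means), x$window,
                min(x$window_means$mean), max(x$window_means$mean)))
  }
  invisible(x)
}

#' Plot a score profile
#'
#' Draws the per-base run scores as a step line with the window means
#' overlaid, the usual way windowed propensity scans are inspected.
#'
#' @param x a `score_profile`.
#' @param threshold optional threshold drawn as horizontal guides at
#'   `+threshold` and `-threshold`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.score_profile <- function(x, threshold = NULL, ...) {
  n <- length(x$per_base)
  plot(seq_len(n), x$per_base, type = "s", ylim = c(-4, 4),
       xlab = "position (nt)", ylab = "run score",
       main = x$sequence_id, col = "grey50", ...)
  if (!x$fallback)
    graphics::lines(x$window_means$start + (x$window + 1) / 2, x$window_means$mean,
                    col = "firebrick", lwd = 2)
  graphics::abline(h = 0, col = "grey80")
  if (!is.null(threshold))
    graphics::abline(h = c(-threshold, threshold), lty = 2, col = "steelblue")
  invisible(x)
}

# Merge sorted qualifying window starts of one sign into maximal regions.
# Windows are [s, s+W); overlapping or book-ended windows merge. Returns a
# matrix with columns start, end.
.merge_windows <- function(starts, window) {
  if (!length(starts)) return(matrix(integer(0), ncol = 2L))
  gap_open <- which(diff(starts) > window)  # gap >= window: spans disjoint
  first <- starts[c(1L, gap_open + 1L)]
  last <- starts[c(gap_open, length(starts))]
  cbind(first, last + window)
}

#' Find potential quadruplex / i-motif regions
#'
#' Scans the window means of a sequence and merges every maximal set of
#' qualifying windows (|window mean| >= `threshold`) of one sign whose spans
#' overlap or are adjacent into a single region. The region score is
#' recomputed as the per-base mean over the merged span, so a merged region's
#' score can be (slightly) below the threshold its windows met. G-rich and
#' C-rich windows never merge with each other. Sequences shorter than the
#' window fall back to the whole-sequence score: they yield one region
#' covering the sequence iff its absolute score meets the threshold.
#'
#' @inheritParams window_means
#' @param threshold positive threshold on the absolute window mean.
#' @return A data frame with columns `seqid`, `start`, `end` (0-based
#'   half-open), `width`, `sequence`, `score`, `sign` (`"+"` G-rich, `"-"`
#'   C-rich), sorted by `start`. Zero rows when nothing qualifies.
#' @examples
#' find_pqs("GGTTGGTGTGGTTGG", threshold = 1.2)  # empty: 1.133 < 1.2
#' @export
find_pqs <- function(x, config = scan_config(), threshold = 1.2) {
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  s <- as_nucleic(x)
  pb <- .pb_scores(s$residues)
  n <- length(pb)
  w <- config$window
  empty <- data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      width = integer(0), sequence = character(0),
                      score = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  region_df <- function(spans, sign) {
    if (!nrow(spans)) return(empty)
    sc <- vapply(seq_len(nrow(spans)), function(i)
      mean(pb[(spans[i, 1L] + 1L):spans[i, 2L]]), 0)
    data.frame(seqid = s$id,
               start = as.integer(spans[, 1L]),
               end = as.integer(spans[, 2L]),
               width = as.integer(spans[, 2L] - spans[, 1L]),
               sequence = substring(s$residues, spans[, 1L] + 1L, spans[, 2L]),
               score = sc, sign = sign, stringsAsFactors = FALSE)
  }
  if (n < w) {
    ms <- sum(pb) / n
    if (abs(ms) >= threshold - .score_eps) {
      sgn <- if (ms > 0) "+" else "-"
      if (sgn == "-" && !config$report_negative) return(empty)
      return(region_df(cbind(0L, n), sgn))
    }
    return(empty)
  }
  ws <- .window_sums(pb, w)
  lim <- threshold * w - .score_eps
  pos <- .merge_windows(which(ws >= lim) - 1L, w)
  out <- region_df(pos, "+")
  if (config$report_negative) {
    neg <- .merge_windows(which(-ws >= lim) - 1L, w)
    out <- rbind(out, region_df(neg, "-"))
  }
  out[order(out$start), , drop = FALSE]
}

#' Classify one record at each threshold
#'
#' @inheritParams window_means
#' @return A data frame with one row per configured threshold: `threshold`,
#'   `has_motif` (>= 1 merged region), `motif_count` (merged regions, both
#'   signs), `best_score` (the signed window mean with the largest absolute
#'   value; the whole-sequence score for records shorter than the window),
#'   and `sign` of the best score.
#' @export
classify_record <- function(x, config = scan_config()) {
  s <- as_nucleic(x)
  prof <- score_profile(s, config)
  best <- if (prof$fallback) prof$mean_score else {
    wm <- prof$window_means$mean
    wm[which.max(abs(wm))]
  }
  rows <- lapply(config$thresholds, function(t) {
    reg <- find_pqs(s, config, t)
    data.frame(threshold = t, has_motif = nrow(reg) > 0L,
               motif_count = nrow(reg), best_score = best,
               sign = if (best > 0) "+" else if (best < 0) "-" else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a whole library
#'
#' The workhorse behind prevalence tables and report output: one row per
#' record with the whole-sequence score, the best window score, and per
#' threshold a motif flag and merged-region count.
#'
#' @param x a sequence collection (list of `nucleic_sequence` /
#'   `aptamer_record`, or a character vector).
#' @inheritParams window_means
#' @return A data frame with columns `id`, `length`, `alphabet`,
#'   `whole_seq_score`, `max_window_score`, `sign`, and per threshold `t`
#'   columns `has_<t>` and `motif_count_<t>`.
#' @export
classify_library <- function(x, config = scan_config()) {
  seqs <- as_nucleic_list(x)
  if (!length(seqs)) stop("empty sequence collection")
  thr <- config$thresholds
  rows <- lapply(seqs, function(s) {
    pb <- .pb_scores(s$residues)
    ws <- .window_sums(pb, config$window)
    whole <- sum(pb) / length(pb)
    best <- if (length(ws)) {
      wm <- ws / config$window
      wm[which.max(abs(wm))]
    } else whole
    counts <- vapply(thr, function(t) nrow(find_pqs(s, config, t)), 0L)
    cbind(data.frame(id = s$id, length = length(pb), alphabet = s$alphabet,
                     whole_seq_score = whole, max_window_score = best,
                     sign = if (best > 0) "+" else if (best < 0) "-" else NA_character_,
                     stringsAsFactors = FALSE),
          as.data.frame(c(stats::setNames(as.list(counts > 0L), paste0("has_", thr)),
                          stats::setNames(as.list(counts), paste0("motif_count_", thr))),
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif prevalence of a library, by sign
#'
#' A fast path over [classify_library()] for large libraries (e.g. the
#' 100,000-sequence random baseline): for each threshold it counts sequences
#' carrying at least one qualifying G-rich window, at least one C-rich
#' window, and at least one of either, without building merged regions.
#' Sequences shorter than the window are judged on the whole-sequence score.
#'
#' @inheritParams classify_library
#' @return A data frame with columns `threshold`, `n`, `n_g_rich`,
#'   `n_c_rich`, `n_any`, `pct_g_rich`, `pct_c_rich`, `pct_any`.
#' @export
motif_prevalence <- function(x, config = scan_config()) {
  chr <- if (is.character(x)) toupper(x) else
    vapply(as_nucleic_list(x), function(s) s$residues, "")
  n <- length(chr)
  if (!n) stop("empty sequence collection")
  thr <- config$thresholds
  w <- config$window
  hi <- numeric(n)
  lo <- numeric(n)
  for (i in seq_len(n)) {
    pb <- .pb_scores(chr[[i]])
    ws <- .window_sums(pb, w)
    if (length(ws)) {
      hi[i] <- max(ws) / w
      lo[i] <- min(ws) / w
    } else {
      hi[i] <- lo[i] <- sum(pb) / length(pb)
    }
  }
  g <- vapply(thr, function(t) sum(hi >= t - .score_eps), 0L)
  c_ <- vapply(thr, function(t) sum(lo <= -(t - .score_eps)), 0L)
  any_ <- vapply(thr, function(t)
    sum(hi >= t - .score_eps | lo <= -(t - .score_eps)), 0L)
  data.frame(threshold = thr, n = n, n_g_rich = g, n_c_rich = c_, n_any = any_,
             pct_g_rich = 100 * g / n, pct_c_rich = 100 * c_ / n,
             pct_any = 100 * any_ / n)
}
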