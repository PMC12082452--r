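# Independent oracles, deliberately implemented by different routes than the
# package: an explicit character-walk run scorer (no rle), window means by
# direct slicing, and region merging by painting per-position coverage.
# They share only the contract-level threshold comparison convention
# (s >= t*W - 1e-9 on integer window sums).

oracle_per_base <- function(residues) {
  ch <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  n <- length(ch)
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    k <- j - i + 1L
    out[i:j] <- if (ch[i] == "G") min(k, 4L) else if (ch[i] == "C") -min(k, 4L) else 0L
    i <- j + 1L
  }
  out
}

oracle_score <- function(residues) {
  pb <- oracle_per_base(residues)
  sum(pb) / length(pb)
}

# Brute-force region scan: every window mean computed independently, merging
# done by marking covered positions per sign and reading off contiguous
# stretches.
oracle_pqs <- function(residues, window = 25L, threshold = 1.2) {
  pb <- oracle_per_base(residues)
  n <- length(pb)
  eps <- 1e-9
  mk <- function(start, end, sign) data.frame(
    start = start, end = end,
    score = vapply(seq_along(start),
                   function(i) mean(pb[(start[i] + 1L):end[i]]), 0),
    sign = sign, stringsAsFactors = FALSE)
  empty <- mk(integer(0), integer(0), character(0))
  if (n < window) {
    ms <- sum(pb) / n
    if (abs(ms) >= threshold - eps) return(mk(0L, n, if (ms > 0) "+" else "-"))
    return(empty)
  }
  out <- empty
  for (sgn in c(1, -1)) {
    cov <- logical(n)
    for (s0 in 0:(n - window)) {
      wsum <- sum(pb[(s0 + 1L):(s0 + window)])
      if (sgn * wsum >= threshold * window - eps)
        cov[(s0 + 1L):(s0 + window)] <- TRUE
    }
    if (any(cov)) {
      r <- rle(cov)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values
      out <- rbind(out, mk(as.integer(starts[keep]), as.integer(ends[keep]),
                           if (sgn > 0) "+" else "-"))
    }
  }
  out[order(out$start), , drop = FALSE]
}

random_dna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# Printed whole-sequence scores of the experimentally characterized aptamer
# panels shipped in extdata (ids after duplicate disambiguation).
published_scores <- c(
  TBA = 1.133,
  Apt8 = 1.61, Apt22 = 1.93, Apt51 = 1.80, Apta14 = 2.12, Apt2 = 1.65,
  Chi46 = 2.27, E1 = 1.79, F1 = 2.15, FKNS2 = 2.00, QA12 = 1.59,
  RNVL7 = 1.88, T24 = 1.93,
  `0913` = 1.20, `0469` = 1.20, `0053` = 1.27, `0058` = 1.30, `0560` = 1.34,
  `0143` = 1.42, `0600` = 1.51, `0200` = 1.54, `0646` = 1.54, `0060` = 1.60,
  `0478` = 1.62, `0672` = 1.66,
  `0902` = 1.24, `1248` = 1.28, `0898` = 1.31, `1052` = 1.44, `0861` = 1.48,
  `0192` = 1.55,
  PL1 = -2.23, PL2 = -2.31, PL3 = -2.82,
  BB1 = -2.00, BB1_2 = -1.75, BB1_3 = -1.90, BI1 = -1.68, AN1 = -1.82
)

load_validated_catalog <- function() {
  suppressWarnings(read_catalog(
    system.file("extdata", "validated_aptamers.tsv", package = "aptaquad"),
    column_map = c(id = "id", sequence = "sequence", alphabet = "type",
                   target = "target")))
}
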