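---
title: "Scoring quadruplex and i-motif propensity in aptamer libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring quadruplex and i-motif propensity in aptamer libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaquad)
```

## The problem

Aptamers are short single-stranded DNA or RNA oligonucleotides selected by
SELEX to bind a target. G-rich aptamer sequences frequently fold into
G-quadruplexes (G4): four-stranded structures built from stacked guanine
quartets. Their C-rich mirror images can form i-motifs at acidic pH. Whether
a candidate aptamer is quadruplex-prone matters both ways — the G4 may be the
functional fold, or an unwanted, poorly selective one — so a screening step
over a whole catalog or selection pool should be routine. `aptaquad`
implements that screen: a run-length propensity score, windowed scanning
with merged region calls, and the two null models (per-sequence shuffling
and a random-library baseline) needed to ask whether a collection is
*enriched* in quadruplex-prone motifs rather than merely G-rich.

## The score

Every residue receives an integer run score. A maximal run of $k$
consecutive guanines contributes $+\min(k, 4)$ to each of its bases; a run
of $k$ cytosines contributes $-\min(k, 4)$; A, T, U and the ambiguity
placeholder N score 0 and terminate runs. The propensity score of any
stretch of sequence is the arithmetic mean of these per-base values, so it
lives in $[-4, 4]$: positive values flag G4 propensity, negative values
C-rich (i-motif) propensity on the scored strand. The cap at $\pm 4$
reflects that four stacked quartets saturate the structural benefit of
longer runs; it is locked by golden tests against published per-sequence
scores (e.g. a 26-mer containing a 9-G run scoring $59/26 = 2.27$).

Two properties follow directly and are enforced as exact invariants:
reversal leaves the score unchanged (the multiset of run lengths is
preserved), and reverse-complementing a DNA sequence negates it exactly
(G runs become equal-length C runs).

Scanning uses windows of `window = 25` nt by default. Window means are
slices of **one** global per-base vector — runs are measured once over the
full sequence, then averaged per window — so a run crossing a window edge
keeps the value earned from its full length, and the single window of a
25-nt sequence equals its whole-sequence score. Sequences shorter than the
window fall back to the whole-sequence mean. This is the operating point at
which the thresholds have their published meaning: scores above 1.5 almost
always correspond to stable G4s, scores between 1.2 and 1.5 to likely but
not systematic formation, and the canonical counter-example is the 15-nt
thrombin-binding aptamer `GGTTGGTGTGGTTGG`, a bona fide G4 former whose
score of $17/15 = 1.133$ falls below the 1.2 cutoff.

## Region calls

`find_pqs()` marks every window whose mean magnitude meets the threshold
and merges qualifying windows of one sign whose spans overlap or are
book-ended into a maximal region; G-rich and C-rich windows never merge.
The region score is then **recomputed** as the per-base mean over the merged
span. Two consequences are deliberate and documented rather than hidden:

* a merged region's score can fall slightly below the threshold its
  constituent windows met (merging dilutes twin peaks with the valley
  between them);
* opposite-sign regions may overlap each other, since each sign is merged
  independently.

Equality at the threshold is accepted. Because thresholds like 1.2 are not
exactly representable in binary floating point ($1.2 \times 25$ evaluates
just above 30), qualification compares the integer window sum against
`threshold * window - 1e-9`; a window summing to exactly 30 at threshold
1.2 therefore qualifies, as it should. The brute-force oracle used in the
tests shares this comparison rule as part of the contract while computing
everything else by an independent route.

One small arithmetic footnote: with the default odd window, a perfectly
alternating `GCGC...` sequence has window means of $\pm 1/25$, not 0 — one
residue is always unpaired. An even window cancels exactly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 25 nt | averaging length for the scan; the scale on which a quadruplex core plus loops lives |
| `thresholds` | 1.2 / 1.5 / 2.0 | candidate / near-certain / extreme propensity cutoffs |
| `report_negative` | `TRUE` | also call C-rich (i-motif candidate) regions |
| baseline `n`, `length` | 100,000 × 80 nt | random-library size mirroring a raw SELEX pool |
| `composition` | uniform | baseline base probabilities; configurable, including matching a catalog's empirical composition |

Rounding for display uses R's default round-half-even at the table's
precision; published per-sequence scores are reproduced to within
$\pm 0.005$ (a printed 2.12 corresponds to a computed 2.125).

## Null models

**Shuffle null.** `shuffle_study()` permutes each motif-positive sequence
uniformly (exact base multiset preserved) and rescans. Surviving motifs
indicate that base *composition* alone, not selected base ordering, explains
the call. Percent decreases are defined as $100 \cdot \Delta /
\text{original}$; the retained fractions ($100 \cdot \text{shuffled} /
\text{original}$) are reported alongside, since summary tables in the
literature sometimes quote the retained fraction under a "decrease"
heading. One caveat worth knowing: for records shorter than the scan window
the score is the whole-sequence mean, which is a function of composition
only — shuffling cannot change it, so short motif-positive records always
survive. The shuffle null is informative for sequences longer than the
window.

**Random baseline.** `run_baseline()` draws an i.i.d. library (default
100,000 × 80 nt, uniform composition — the composition of a baseline is a
modelling choice, so it is explicit, configurable, and recorded in the
output) and compares prevalence with a pooled two-proportion z-test,
separately for G-rich and C-rich signs: quadruplex enrichment is a claim
about the G-rich sign, and the C-rich test is its i-motif counterpart.
The test is two-sided without continuity correction (the standard reading
of "two-proportion z-test"; a correction is available behind a flag), and
*enrichment* means $z > 0$ with $p < \alpha$. The degenerate pooled
proportions 0 and 1 return $z = 0$, $p = 1$ by convention. Calibration is
tested: under a simulated null the empirical type-I error at
$\alpha = 0.05$ sits within Monte-Carlo error of 0.05, and $z$ agrees with
an independent closed-form evaluation to $10^{-9}$.

## The synthetic-data generator

`generate_library()` emulates a raw SELEX pool: fixed 18-nt primer-like
flanks generated once per library, a uniformly random 20–50-nt core, and an
optional planted motif (default a 4×G₃ tract with T loops, whole-motif
score $36/15 = 2.4$) written into a uniformly chosen core offset of exactly
`round(planted_fraction * n_records)` records, with truth labels recording
the motif coordinates. Generation is deterministic given the seed, to the
byte, in the emitted FASTA.

Two "clean truth" choices make the planted labels usable as a benchmark:

* **Flanks** are by default rejection-sampled to carry no G/C run of length
  ≥ 3 (and no CC dinucleotide within 10 nt of the core), so the fixed
  regions cannot generate or destroy calls on their own. A `flank_style =
  "random"` flag provides realistic uniform flanks instead — useful when
  non-planted records should be statistically identical to an i.i.d.
  baseline.
* **Insertion sites** are cleaned: up to 10 nt of core on each side of a
  planted motif is resampled cytosine-free (`clean_site = TRUE`). Without
  this, chance C runs beside the motif cancel roughly 0.3% of plantings
  below the 1.2 threshold (a `CCCC` on one side and `CCC` on the other
  leave a best window mean of ~1.04), which silently corrupts
  sensitivity benchmarks. A spike-in positive control should be detectable
  by construction; with cleaning, some 25-nt window containing the default
  motif sums to at least $36 - 5 \ge 30 = 1.2 \times 25$, a deterministic
  guarantee. Disable it to study exactly this masking effect.

What the generator does **not** emulate: selection dynamics, PCR or
reverse-transcription bias, chemical modifications, length heterogeneity
beyond the core range, or the G/C skew of real selected pools (available
only as an explicit composition knob, not as a fitted model). A green test
on synthetic data therefore establishes correctness of the scanning and
statistics machinery on a stated world — not that any particular real
catalog is enriched.

## Degenerate inputs and conventions

* Coordinates are 0-based half-open internally and in BED-like output.
* Non-ACGT/U characters become `N` (counted per record), score 0, and break
  runs — ambiguity can never inflate propensity.
* A record mixing T and U is rejected under alphabet auto-detection; a
  forced alphabet interconverts T/U instead.
* RNA is scored on its own strand; no reverse complement is defined for it.
* Empty files, empty records, unmapped catalog columns, and out-of-range
  test counts are errors; duplicate catalog identifiers are kept but
  suffix-disambiguated with a warning; declared length columns lose to the
  computed residue count.

## Known limitations

The score is sequence-only: no loop-length penalties, no topology
(parallel/antiparallel) or thermodynamic stability prediction, and no
machine-learned rescoring. Region *counts* depend on the merging rule
stated above; other implementations with different merge conventions can
report different motif tallies from identical per-base scores, so
cross-tool count comparisons should be made at the level of per-sequence
scores, which are exact.
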