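test_that("per-base run scores follow the capped run rule", {
  expect_equal(per_base_scores("GGTTGGTGTGGTTGG"),
               c(2, 2, 0, 0, 2, 2, 0, 1, 0, 2, 2, 0, 0, 2, 2))
  expect_equal(per_base_scores("AAAA"), rep(0L, 4))
  expect_equal(per_base_scores("GGGGG"), rep(4L, 5))
  expect_equal(per_base_scores("CCC"), rep(-3L, 3))
  # placeholders score 0 and break runs
  expect_equal(per_base_scores("GGNGG"), c(2, 2, 0, 2, 2))
  # U behaves exactly like T
  expect_equal(per_base_scores("GGAU"), per_base_scores("GGAT"))
  expect_error(per_base_scores(""), "empty")
})

test_that("whole-sequence scores reproduce hand-checked values", {
  expect_equal(sequence_score("GGTTGGTGTGGTTGG"), 17 / 15)
  expect_equal(sequence_score("TGGGCGGGGAGTAGGGAGAGGGGT"), 51 / 24)
  expect_equal(sequence_score("CCCCCTCCTCCCTCCCCCACCC"), -62 / 22)
  expect_equal(sequence_score("ATAT"), 0)
})

test_that("window means slice one global per-base array", {
  cfg <- scan_config(window = 25)
  wm <- window_means(strrep("G", 30), cfg)
  expect_equal(nrow(wm), 6L)
  expect_true(all(wm$mean == 4))
  expect_equal(wm$start, 0:5)

  # one 25-nt window: equals the whole-sequence score
  wm <- window_means("GTGTACGGGGTCCGGTAGGGTGGCG", cfg)
  expect_equal(nrow(wm), 1L)
  expect_equal(wm$mean, 1.20)

  # alternating GC: +1/-1 cancel exactly over an even window; an odd window
  # keeps one unpaired residue
  wm <- window_means(strrep("GC", 20), scan_config(window = 24))
  expect_true(all(wm$mean == 0))
  wm <- window_means(strrep("GC", 20), cfg)
  expect_true(all(abs(wm$mean) == 1 / 25))

  wm <- window_means("GGTTGGTGTGGTTGG", cfg)
  expect_equal(nrow(wm), 0L)
  expect_true(attr(wm, "fallback"))

  # a run crossing the window edge keeps its full-run value inside the window
  s <- paste0(strrep("A", 24), strrep("G", 6))  # run starts at last window base
  wm <- window_means(s, cfg)
  expect_equal(wm$mean[1], 4 / 25)
})

test_that("find_pqs merges qualifying windows and recovers planted motifs", {
  cfg <- scan_config(window = 25)
  s <- paste0(strrep("A", 30), "GGGTGGGTGGGTGGG", strrep("A", 35))
  reg <- find_pqs(nucleic_sequence(s, id = "p"), cfg, threshold = 1.2)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$sign, "+")
  expect_true(reg$start <= 30 && reg$end >= 45)

  # below-threshold short sequence: no region
  expect_equal(nrow(find_pqs("GGTTGGTGTGGTTGG", cfg, 1.2)), 0L)
  # short sequence fallback calls the whole sequence when it qualifies
  reg <- find_pqs(nucleic_sequence("GGTTGGTGTGGTTGG", id = "TBA"), cfg, 1.1)
  expect_equal(reg[, c("start", "end", "sign")],
               data.frame(start = 0L, end = 15L, sign = "+"))
  expect_equal(reg$score, 17 / 15)

  expect_equal(nrow(find_pqs(strrep("A", 80), cfg, 1.2)), 0L)

  # opposite signs never merge, even when adjacent
  s <- paste0(strrep("G", 30), strrep("C", 30))
  reg <- find_pqs(nucleic_sequence(s, id = "gc"), cfg, threshold = 2)
  expect_equal(reg$sign, c("+", "-"))
  expect_true(all(reg$score == c(4, -4) | abs(reg$score) <= 4))
  expect_false(any(reg$start[-1] < reg$end[-nrow(reg)] &
                   reg$sign[-1] == reg$sign[-nrow(reg)]))

  expect_error(find_pqs("GGG", cfg, threshold = -1), "> 0")
})

test_that("region scores are recomputed over the merged span", {
  cfg <- scan_config(window = 10)
  s <- paste0("GGGGG", strrep("A", 8), "GGGGG")  # two runs, windows overlap the gap
  reg <- find_pqs(nucleic_sequence(s, id = "m"), cfg, threshold = 1.2)
  for (i in seq_len(nrow(reg))) {
    pb <- per_base_scores(s)
    expect_equal(reg$score[i], mean(pb[(reg$start[i] + 1):reg$end[i]]))
    expect_equal(reg$sequence[i],
                 substr(s, reg$start[i] + 1, reg$end[i]))
    expect_equal(reg$width[i], reg$end[i] - reg$start[i])
  }
})

test_that("classify_record flags thresholds and reports best scores", {
  cfg <- scan_config()
  cls <- classify_record(nucleic_sequence("CGGGGGGGGGAGAAGGCAATGGGGGA", id = "Chi46"), cfg)
  expect_equal(cls$threshold, c(1.2, 1.5, 2.0))
  expect_true(all(cls$has_motif))
  expect_equal(unique(cls$sign), "+")
  # 26 nt, window 25: best score is the larger of the two window means
  wm <- window_means(nucleic_sequence("CGGGGGGGGGAGAAGGCAATGGGGGA"), cfg)
  expect_equal(cls$best_score[1], max(wm$mean))

  pl1 <- classify_record(
    nucleic_sequence("CCCCCTCCTCCCTCCCCCACCCGACACTATTCCCCCCCACACC", id = "PL1"), cfg)
  expect_true(all(pl1$has_motif))
  expect_equal(unique(pl1$sign), "-")

  none <- classify_record(nucleic_sequence(strrep("A", 60)), cfg)
  expect_false(any(none$has_motif))
  expect_equal(none$motif_count, c(0L, 0L, 0L))
})

test_that("score algebra: bounds, consistency, reversal (property)", {
  set.seed(42)
  cfg <- scan_config(window = 25)
  for (i in 1:200) {
    s <- random_dna(sample(10:120, 1), prob = c(0.15, 0.35, 0.35, 0.15))
    ns <- nucleic_sequence(s)
    pb <- per_base_scores(ns)
    expect_true(all(pb >= -4 & pb <= 4))
    expect_equal(sequence_score(ns), sum(pb) / length(pb))
    wm <- window_means(ns, cfg)
    if (nrow(wm)) expect_true(all(abs(wm$mean) <= 4))
    if (nchar(s) == 25) expect_equal(wm$mean, sequence_score(ns))
    expect_identical(sequence_score(reverse_sequence(ns)), sequence_score(ns))
    expect_identical(sequence_score(reverse_complement(ns)), -sequence_score(ns))
  }
})

test_that("scan_config validates its arguments", {
  expect_error(scan_config(window = 1), ">= 2")
  expect_error(scan_config(thresholds = c(1.5, 1.2)), "increasing")
  expect_error(scan_config(thresholds = -1), "positive")
  cfg <- scan_config(window = 25, thresholds = 1.2, report_negative = FALSE)
  reg <- find_pqs(strrep("C", 40), cfg, 1.2)
  expect_equal(nrow(reg), 0L)  # C-rich suppressed when not reported
})
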