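test_that("shuffle_sequence preserves composition and is seed-deterministic", {
  expect_equal(shuffle_sequence("AAAA", seed = 3)$residues, "AAAA")
  set.seed(9)
  for (i in 1:25) {
    s <- nucleic_sequence(random_dna(sample(5:80, 1)))
    sh <- shuffle_sequence(s)
    expect_equal(sort(strsplit(sh$residues, "")[[1]]),
                 sort(strsplit(s$residues, "")[[1]]))
    expect_equal(sh$alphabet, s$alphabet)
  }
  s <- nucleic_sequence(random_dna(50))
  expect_identical(shuffle_sequence(s, seed = 1)$residues,
                   shuffle_sequence(s, seed = 1)$residues)
})

test_that("permutation score tail matches a direct sampling oracle", {
  # fraction of 4xG3 permutations keeping the unshuffled score (2.4):
  # package route (shuffle_sequence + sequence_score) vs an independent
  # sampler over character permutations with the oracle scorer
  s <- "GGGTGGGTGGGTGGG"
  n1 <- 20000
  set.seed(101)
  keep1 <- mean(vapply(seq_len(n1), function(i)
    sequence_score(shuffle_sequence(s)) >= 2.4 - 1e-9, NA))
  n2 <- 20000
  set.seed(202)
  ch <- strsplit(s, "")[[1]]
  keep2 <- mean(vapply(seq_len(n2), function(i)
    oracle_score(paste(ch[sample.int(15)], collapse = "")) >= 2.4 - 1e-9, NA))
  se <- sqrt(keep2 * (1 - keep2) * (1 / n1 + 1 / n2))
  expect_lt(abs(keep1 - keep2), 3 * se + 1e-12)
})

test_that("shuffle_study counts motif loss on a planted library", {
  lib <- generate_library(library_spec(100, planted_fraction = 1,
                                       core_length_range = c(30, 30), seed = 21))
  ss <- shuffle_study(lib$records, threshold = 1.2, seed = 77)
  expect_equal(ss$n_sequences_analyzed, 100L)
  expect_equal(ss$seqs_with_g4_original, 100L)
  expect_gt(ss$pct_decrease_seqs, 0)
  expect_equal(ss$delta_seqs_with_g4,
               ss$seqs_with_g4_original - ss$seqs_with_g4_shuffled)
  expect_equal(ss$pct_decrease_seqs,
               100 * ss$delta_seqs_with_g4 / ss$n_sequences_analyzed)
  expect_equal(ss$pct_decrease_count,
               100 * ss$delta_g4_count / ss$g4_count_original)

  # expected survival checked against a direct resampling oracle
  sub <- lib$records[1:30]
  ss_rep <- shuffle_study(sub, threshold = 1.2, seed = 5, n_shuffles = 40)
  set.seed(6)
  chars <- lapply(sub, function(r) strsplit(r$sequence$residues, "")[[1]])
  reps <- 200
  surv <- vapply(seq_len(reps), function(r) {
    mean(vapply(chars, function(ch) {
      perm <- paste(ch[sample.int(length(ch))], collapse = "")
      nrow(oracle_pqs(perm, 25, 1.2)) > 0
    }, NA))
  }, 0)
  se <- sqrt((ss_rep$sd_seqs_with_g4_shuffled / 30)^2 / 40 +
             stats::var(surv) / reps)
  expect_lt(abs(ss_rep$seqs_with_g4_shuffled / 30 - mean(surv)), 4 * se + 0.01)

  # homopolymer G: shuffling cannot destroy the motif
  homo <- lapply(1:10, function(i) nucleic_sequence(strrep("G", 40), id = paste0("g", i)))
  ss <- shuffle_study(homo, threshold = 1.2, seed = 1)
  expect_equal(ss$pct_decrease_seqs, 0)
  expect_equal(ss$delta_g4_count, 0)

  none <- lapply(1:5, function(i) nucleic_sequence(strrep("A", 40), id = paste0("a", i)))
  expect_error(shuffle_study(none, threshold = 1.2), "motif-positive")
  expect_error(shuffle_study(list(), 1.2), "empty")
})

test_that("random_library composition, determinism, and G/C symmetry", {
  lib <- random_library(10, length = 80, seed = 4)
  expect_length(lib, 10L)
  expect_true(all(vapply(lib, function(s) nchar(s$residues), 0L) == 80L))

  onlyA <- random_library(20, length = 60, composition = c(1, 0, 0, 0), seed = 4)
  expect_true(all(vapply(onlyA, function(s) s$residues, "") == strrep("A", 60)))
  expect_equal(motif_prevalence(onlyA)$n_any, c(0L, 0L, 0L))

  expect_error(random_library(5, composition = c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
  expect_identical(random_library(5, length = 30, seed = 8, as_records = FALSE),
                   random_library(5, length = 30, seed = 8, as_records = FALSE))

  # G-rich vs C-rich prevalence symmetric under a uniform composition
  chr <- random_library(4000, length = 80, seed = 12, as_records = FALSE)
  prev <- motif_prevalence(chr, scan_config(thresholds = 1.2))
  p <- (prev$n_g_rich + prev$n_c_rich) / (2 * prev$n)
  se <- sqrt(2 * p * (1 - p) * prev$n)  # se of the count difference
  expect_lt(abs(prev$n_g_rich - prev$n_c_rich), 3 * se + 1)
})

test_that("two_proportion_z matches hand values and conventions", {
  z <- two_proportion_z(50, 100, 50, 100)
  expect_equal(z$z, 0)
  expect_equal(z$p_two_sided, 1)

  z <- two_proportion_z(20, 100, 10, 100)
  expect_equal(z$z, 1.9803, tolerance = 1e-4)
  expect_equal(z$p_two_sided, 0.0477, tolerance = 1e-3)
  expect_equal(z$p_pooled, 0.15)

  z <- two_proportion_z(0, 10, 0, 10)
  expect_equal(z$z, 0)
  expect_equal(z$p_two_sided, 1)

  expect_error(two_proportion_z(5, 4, 1, 10), "<=")
  expect_error(two_proportion_z(1, 0, 1, 10), ">= 1")

  # antisymmetry under group swap
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(5:500, 1); n2 <- sample(5:500, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    a <- two_proportion_z(x1, n1, x2, n2)
    b <- two_proportion_z(x2, n2, x1, n1)
    expect_equal(a$z, -b$z)
    expect_equal(a$p_two_sided, b$p_two_sided)
  }

  # continuity correction shrinks |z| and never flips the sign
  a <- two_proportion_z(20, 100, 10, 100, correct = TRUE)
  expect_lt(a$z, 1.9803)
  expect_gt(a$z, 0)
})

test_that("prevalence_by_stratum counts and monotonicity", {
  strong <- paste0(strrep("A", 20), "GGGGTGGGGTGGGGTGGGG", strrep("A", 20))
  recs <- c(lapply(1:4, function(i) nucleic_sequence(strong, id = paste0("m", i))),
            lapply(1:6, function(i) nucleic_sequence(strrep("A", 60), id = paste0("z", i))))
  expect_warning(tab <- prevalence_by_stratum(recs), "no RNA")
  dna12 <- tab[tab$alphabet == "DNA" & tab$threshold == 1.2, ]
  expect_equal(dna12$n_with_g4, 4L)
  expect_equal(dna12$pct_with, 40)
  expect_equal(dna12$n_with_g4 + dna12$n_without, 10L)

  # monotone in threshold for any input
  chr <- random_library(500, length = 80, seed = 44, as_records = FALSE)
  prev <- motif_prevalence(chr)
  expect_true(all(diff(prev$n_any) <= 0))
  expect_true(all(diff(prev$n_g_rich) <= 0))
  expect_true(all(diff(prev$n_c_rich) <= 0))
})

test_that("sign_bias separates G-rich from C-rich and swaps under G<->C", {
  gs <- lapply(1:7, function(i) nucleic_sequence(strrep("G", 40), id = paste0("g", i)))
  expect_equal(unname(sign_bias(gs, 1.2)), c(7L, 0L))

  set.seed(55)
  chr <- random_library(300, length = 80, seed = 55, as_records = FALSE)
  swapped <- chartr("GC", "CG", chr)
  a <- sign_bias(chr, 1.2)
  b <- sign_bias(swapped, 1.2)
  expect_equal(unname(a), unname(rev(b)))
})
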