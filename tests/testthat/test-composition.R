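test_that("GC content follows the (#G + #C)/length definition", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AUAU"), 0.0)
  expect_equal(round(gc_content(MIR528_WT), 2), 0.62)
  expect_error(gc_content(""), "empty")
  # invariant under reverse complement
  seqs <- random_rna(25, 21, seed = 3)
  expect_equal(gc_content(reverse_complement(seqs)), gc_content(seqs))
})

test_that("segment GC splits precursors into arm/mature/loop/mature/arm", {
  p <- precursor_record("p", "AAAAGGCCUUUUGGCCAAAA", c(5, 8), c(13, 16))
  seg <- gc_by_segment(p)
  expect_equal(seg$gc, c(0, 1, 0, 1, 0))
  expect_equal(sum(seg$length), p$length)

  # degenerate loop: GC undefined, lengths still sum to L
  p2 <- precursor_record("p2", "GGCCAAUU", c(1, 4), c(5, 8))
  seg2 <- gc_by_segment(p2)
  expect_true(is.na(seg2$gc[seg2$segment == "loop"]))
  expect_equal(seg2$length[seg2$segment == "loop"], 0L)
  expect_equal(sum(seg2$length), 8L)
})

test_that("generated precursors recover planted arm and duplex GC", {
  # oracle: the generator's planted parameters (arm 0.30, duplex mature 0.52)
  matures <- gen_conditioned_mirnas(60, seed = 11)
  segs <- lapply(seq_along(matures), function(i)
    gc_by_segment(gen_precursor(matures[i], arm_gc = 0.30, seed = 100 + i)))
  arm_mean <- mean(vapply(segs, function(s) mean(s$gc[c(1, 5)]), numeric(1)))
  mat_mean <- mean(vapply(segs, function(s) s$gc[2], numeric(1)))
  expect_lt(abs(arm_mean - 0.30), 0.03)
  expect_gt(mat_mean - arm_mean, 0.15)
})

test_that("position frequency matrices normalize and weight correctly", {
  pfm <- position_frequency_matrix(c("AU", "GC"))
  expect_equal(pfm$freq[, 1], c(A = 0.5, C = 0, G = 0.5, U = 0))
  expect_equal(pfm$freq[, 2], c(A = 0, C = 0.5, G = 0, U = 0.5))
  expect_equal(unname(position_frequency_matrix("AA")$freq["A", ]), c(1, 1))
  expect_error(position_frequency_matrix(c("AU", "GCU")), "length")

  # every column sums to 1
  seqs <- random_rna(200, 21, seed = 5)
  pfm2 <- position_frequency_matrix(seqs)
  expect_true(all(abs(colSums(pfm2$freq) - 1) < 1e-9))

  # abundance weighting with equal counts reproduces unique weighting
  pfm_u <- position_frequency_matrix(seqs)
  pfm_a <- position_frequency_matrix(seqs, weighting = "abundance",
                                     counts = rep(3L, length(seqs)))
  expect_equal(pfm_a$freq, pfm_u$freq)
  # and unequal counts shift the frequencies toward the abundant sequence
  pfm_w <- position_frequency_matrix(c("AAA", "GGG"), "abundance", counts = c(9L, 1L))
  expect_equal(unname(pfm_w$freq["A", 1]), 0.9)
})

test_that("GC ratio track sums the G and C rows and complements the AU track", {
  pfm <- position_frequency_matrix(random_rna(50, 10, seed = 8))
  tr <- gc_ratio_track(pfm)
  expect_equal(tr$gc, unname(pfm$freq["G", ] + pfm$freq["C", ]))
  expect_equal(tr$gc + tr$au, rep(1, 10))
  all_a <- gc_ratio_track(position_frequency_matrix(c("AAAA", "AAAA")))
  expect_equal(all_a$gc, rep(0, 4))
})

test_that("dinucleotide frequencies are positionwise-normalized", {
  d <- dinucleotide_position_frequency("AUAU")
  expect_equal(unname(d$per_position["AU", c(1, 3)]), c(1, 1))
  expect_equal(unname(d$per_position["UA", 2]), 1)
  expect_true(all(abs(colSums(d$per_position) - 1) < 1e-9))
  expect_error(dinucleotide_position_frequency(character(0)), "empty")

  # pooled dinucleotide content is invariant under dinucleotide shuffling
  seqs <- random_rna(40, 21, seed = 12)
  shuf <- dinucleotide_shuffle(seqs, seed = 13)
  expect_equal(dinucleotide_position_frequency(shuf)$pooled,
               dinucleotide_position_frequency(seqs)$pooled)
})

test_that("random sampling control is reproducible and bounded", {
  seqs <- random_rna(30, 21, seed = 2)
  expect_identical(random_sample_control(seqs, 30), seqs)
  expect_length(random_sample_control(seqs, 0, seed = 1), 0L)
  expect_identical(random_sample_control(seqs, 10, seed = 9),
                   random_sample_control(seqs, 10, seed = 9))
  expect_error(random_sample_control(seqs, 31), "exceeds")
})

test_that("Mann-Whitney comparison matches its identities and a permutation oracle", {
  a <- seq(0.1, 0.9, by = 0.1)
  same <- compare_distributions(a, a)
  expect_gt(same$p, 0.9)
  # U(a,b) + U(b,a) == n_a * n_b
  b <- withr::with_seed(4, stats::rnorm(12, 0.4, 0.05))
  expect_equal(compare_distributions(a, b)$U + compare_distributions(b, a)$U,
               length(a) * length(b))
  expect_error(compare_distributions(0.5, a), "at least 2")

  # separated GC distributions: significant by both routes
  x <- withr::with_seed(5, stats::rnorm(100, 0.52, 0.03))
  y <- withr::with_seed(6, stats::rnorm(100, 0.30, 0.03))
  expect_lt(compare_distributions(x, y)$p, 0.001)
  expect_lt(permutation_p(x, y), 0.001)
})
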