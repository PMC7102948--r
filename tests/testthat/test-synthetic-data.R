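test_that("PFM sampling recovers the generating matrix", {
  # binomial oracle: at n draws each cell estimate has SE <= 0.5/sqrt(n)
  pfm <- signature_pfm()
  seqs <- gen_mirnas(pfm, 4000, seed = 100)
  est <- position_frequency_matrix(seqs)
  expect_lt(max(abs(est$freq - pfm$freq)), 0.03)

  # one-hot matrix: deterministic output
  onehot <- uniform_pfm()
  onehot$freq[] <- 0
  onehot$freq["U", ] <- 1
  expect_equal(unique(gen_mirnas(onehot, 5, seed = 1)), strrep("U", 21))

  expect_identical(gen_mirnas(pfm, 10, seed = 2), gen_mirnas(pfm, 10, seed = 2))
})

test_that("conditioned sampling hits the requested classification", {
  model <- default_signature_model()
  carriers <- gen_conditioned_mirnas(30, seed = 101)
  tabs <- signature_table(carriers, model)
  expect_true(all(tabs$has_signature & tabs$in_band))
  non <- gen_conditioned_mirnas(30, seed = 102, carry = FALSE)
  tabs2 <- signature_table(non, model)
  expect_false(any(tabs2$has_signature & tabs2$in_band))
})

test_that("generated precursors have exact spans and planted composition", {
  mature <- gen_conditioned_mirnas(1, seed = 103)
  p <- gen_precursor(mature, arm_gc = 0, loop_gc = 0, seed = 104)
  # spans recover the mature and star exactly
  expect_equal(suppressWarnings(
    locate_mature_in_precursor(p$sequence, mature)), p$mature5p_span)
  expect_equal(span_seq(p$sequence, p$mature3p_span), design_star(mature)$star)
  # with AU-only arms and loop, GC is confined to the duplex segments
  seg <- gc_by_segment(p)
  expect_equal(seg$gc[c(1, 3, 5)], c(0, 0, 0))
  expect_gt(seg$gc[2], 0.4)
})

test_that("dicing pools honor the fidelity parameter", {
  prec <- gen_precursor(gen_conditioned_mirnas(1, seed = 105), seed = 106)
  mature <- span_seq(prec$sequence, prec$mature5p_span)
  star <- span_seq(prec$sequence, prec$mature3p_span)

  pure <- gen_dicing_reads(prec, fidelity = 1, n = 500, seed = 107)
  expect_setequal(pure$sequence, c(mature, star))

  noise <- gen_dicing_reads(prec, fidelity = 0, n = 500, seed = 108)
  expect_false(any(noise$sequence %in% c(mature, star)))

  mixed <- gen_dicing_reads(prec, fidelity = 0.8, n = 4000, seed = 109)
  canon <- sum(mixed$count[mixed$sequence %in% c(mature, star)]) / 4000
  expect_lt(abs(canon - 0.8), 0.02)
  # all reads are substrings of the precursor and RPM sums to 1e6
  expect_true(all(vapply(mixed$sequence, function(s)
    grepl(s, prec$sequence, fixed = TRUE), logical(1))))
  expect_equal(sum(mixed$rpm), 1e6)
})

test_that("planted target mRNAs contain the reverse complement at the site", {
  tm <- gen_target_mrna(MIR528_M1, seed = 110)
  expect_equal(span_seq(tm$mrna$sequence, c(tm$site$start, tm$site$end)),
               reverse_complement(MIR528_M1))
  expect_identical(gen_target_mrna(MIR528_M1, seed = 110)$mrna$sequence,
                   tm$mrna$sequence)
  expect_error(gen_target_mrna(MIR528_M1, mrna_length = 30, site_position = 20),
               "fit")
  # mismatch positions break pairing at exactly those site coordinates
  tm2 <- gen_target_mrna(MIR528_M1, mismatch_positions = c(5, 12), seed = 111)
  site <- span_seq(tm2$mrna$sequence, c(tm2$site$start, tm2$site$end))
  rc <- reverse_complement(MIR528_M1)
  diff <- which(strsplit(site, "")[[1]] != strsplit(rc, "")[[1]])
  expect_equal(diff, c(5L, 12L))
})

test_that("the four-stem construct preset plants the documented inserts", {
  cs <- gen_four_stem_construct(seed = 5)
  m <- cs$matures
  expect_equal(round(m$gc[m$stem == "gc28"] * 21), 6)
  expect_equal(round(m$gc[m$stem == "gc52_signature"] * 21), 11)
  expect_equal(round(m$gc[m$stem == "gc52_scrambled"] * 21), 11)
  expect_equal(round(m$gc[m$stem == "gc71"] * 21), 15)
  expect_equal(m$has_signature, c(FALSE, TRUE, FALSE, FALSE))
  # scrambled insert has the same letters as the signature insert
  expect_equal(sort(strsplit(m$sequence[m$stem == "gc52_signature"], "")[[1]]),
               sort(strsplit(m$sequence[m$stem == "gc52_scrambled"], "")[[1]]))
  # identical backbone across stems: stems differ only inside the spans
  s1 <- cs$stems[[1]]; s2 <- cs$stems[[2]]
  expect_equal(span_seq(s1$sequence, c(1, s1$mature5p_span[1] - 1)),
               span_seq(s2$sequence, c(1, s2$mature5p_span[1] - 1)))
  # construct coordinates recover each mature
  for (i in seq_len(nrow(cs$stem_offsets))) {
    st <- cs$stem_offsets$mature5p_start[i]
    expect_equal(substr(cs$construct, st, st + 20L), m$sequence[i])
  }
  expect_identical(gen_four_stem_construct(seed = 5)$construct, cs$construct)
})
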