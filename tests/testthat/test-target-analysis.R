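test_that("sliding-window GC matches direct computation", {
  s21 <- random_rna(1, 21, seed = 60)
  prof <- sliding_window_gc(s21)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$gc, gc_content(s21))

  expect_equal(sliding_window_gc(strrep("A", 50))$gc, rep(0, 30))
  expect_error(sliding_window_gc("ACGU"), "shorter")

  # profile inside a region is invariant to flanking sequence
  core <- random_rna(1, 40, seed = 61)
  padded <- paste0(strrep("G", 10), core, strrep("G", 10))
  expect_equal(sliding_window_gc(core)$gc,
               sliding_window_gc(padded)$gc[11:30])
})

test_that("a planted GC-rich site is the profile maximum in AU-poor context", {
  # rate at which the profile maximum is achieved by a window overlapping the
  # planted span, via the package pipeline
  hit_rate <- function(n_rep) {
    hits <- 0
    for (rep in seq_len(n_rep)) {
      tm <- gen_target_mrna(MIR528_M1, mrna_length = 150, background_gc = 0.30,
                            site_position = 60, seed = 600 + rep)
      prof <- sliding_window_gc(tm$mrna$sequence)
      overlaps <- prof$start + 20 >= tm$site$start & prof$start <= tm$site$end
      if (max(prof$gc[overlaps]) == max(prof$gc)) hits <- hits + 1
    }
    hits / n_rep
  }
  # independent oracle: the same planted experiment simulated in raw base R
  oracle_rate <- function(n_rep) {
    site_gc_count <- sum(strsplit(MIR528_M1, "")[[1]] %in% c("G", "C"))
    withr::with_seed(599, {
      hits <- 0
      for (rep in seq_len(n_rep)) {
        is_gc <- stats::runif(150) < 0.30
        # reverse complement preserves GC-ness and reverses the order
        is_gc[60:80] <- rev(strsplit(MIR528_M1, "")[[1]] %in% c("G", "C"))
        win_gc <- vapply(1:130, function(s) sum(is_gc[s:(s + 20)]), numeric(1))
        overlaps <- (1:130) + 20 >= 60 & (1:130) <= 80
        if (max(win_gc[overlaps]) == max(win_gc)) hits <- hits + 1
      }
      hits / n_rep
    })
  }
  observed <- hit_rate(100)
  expected <- oracle_rate(400)
  expect_lt(abs(observed - expected), 0.12)
  expect_gt(observed, 0.7)  # the planted enrichment dominates the background
})

test_that("background GC from i.i.d. cDNA windows is flat at the planted level", {
  cdnas <- random_seq(30, 300, gc = 0.5, seed = 62)
  bg <- background_position_gc(cdnas, n_windows = 8000, seed = 63)
  se <- sqrt(0.5 * 0.5 / 8000)
  expect_true(all(abs(bg - 0.5) < 4 * se))
  # determinism and degenerate input
  expect_identical(bg, background_position_gc(cdnas, n_windows = 8000, seed = 63))
  expect_equal(background_position_gc(strrep("G", 21), 5, seed = 1),
               rep(1, 21), ignore_attr = TRUE)
  expect_error(background_position_gc("ACGU", 10), "no cDNA")
})

test_that("normalized site GC mirrors the miRNA signature at mapped positions", {
  model <- default_signature_model()
  mirnas <- gen_conditioned_mirnas(150, seed = 64)
  pieces <- lapply(seq_along(mirnas), function(i)
    gen_target_mrna(mirnas[i], mrna_length = 200, background_gc = 0.42,
                    site_position = 90, seed = 700 + i,
                    id = paste0("m", i)))
  mrnas <- do.call(rbind, lapply(pieces, `[[`, "mrna"))
  sites <- do.call(rbind, lapply(pieces, `[[`, "site"))
  bg <- background_position_gc(mrnas$sequence, n_windows = 8000, seed = 65)
  ratios <- normalized_site_gc(sites, mrnas, bg)

  gc_target_pos <- mirna_target_position_map(model$core_gc_positions)
  au_target_pos <- mirna_target_position_map(model$core_au_positions)
  expect_true(all(ratios$site_ratio[gc_target_pos] > 1.3))
  expect_true(all(ratios$site_ratio[au_target_pos] < 0.8))
  # flanking windows carry no signal
  expect_lt(max(abs(c(ratios$upstream_ratio, ratios$downstream_ratio) - 1)), 0.35)

  # sites drawn from the background itself self-normalize to ~1
  null_sites <- sites
  null_sites$start <- 20L
  null_sites$end <- 40L
  null_ratios <- normalized_site_gc(null_sites, mrnas, bg)
  expect_lt(max(abs(null_ratios$site_ratio - 1)), 0.35)

  expect_error(normalized_site_gc(sites[0, ], mrnas, bg), "empty")
})

test_that("the miRNA-to-target position map is the antiparallel involution", {
  expect_equal(mirna_target_position_map(12), 10)
  expect_equal(mirna_target_position_map(1), 21)
  expect_equal(mirna_target_position_map(11), 11)
  expect_equal(mirna_target_position_map(mirna_target_position_map(1:21)), 1:21)
  expect_error(mirna_target_position_map(22), "range")
})

test_that("the naive site finder recovers planted sites and matches brute force", {
  # exact reverse complement: full score at the planted span
  tm <- gen_target_mrna(MIR528_M1, seed = 70)
  hit <- find_site_naive(MIR528_M1, tm$mrna$sequence)
  expect_equal(hit$start, tm$site$start)
  expect_equal(hit$score, 21)

  # planted mismatches lower the score by exactly their count
  for (rep in 1:10) {
    tm2 <- gen_target_mrna(MIR528_M1, mismatch_positions = c(3, 14),
                           seed = 800 + rep)
    hit2 <- find_site_naive(MIR528_M1, tm2$mrna$sequence)
    oracle <- brute_site_scan(MIR528_M1, tm2$mrna$sequence)
    expect_equal(hit2$start, oracle$start)
    expect_equal(hit2$score, oracle$score)
    expect_equal(hit2$start, tm2$site$start)
    expect_equal(hit2$score, 19)
  }

  # all-A vs all-A: only U:A pairing possible, leftmost tie wins
  hit3 <- find_site_naive(strrep("A", 21), strrep("A", 40))
  expect_equal(hit3$start, 1L)
  expect_equal(hit3$score, 0)
})
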