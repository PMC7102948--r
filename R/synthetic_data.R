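# Synthetic inputs with the statistical structure the analyses assume:
# 21-nt miRNA populations drawn from positional nucleotide probabilities,
# hairpin precursors with AU-rich arms flanking a GC-richer miRNA/miRNA*
# duplex, dicing read pools with canonical/isomiR/sib-miR structure, mRNAs
# with a planted reverse-complement target site, and the four-stem artificial
# construct preset. Every generator is deterministic for a fixed seed.

pfm_matrix <- function(pfm) {
  if (inherits(pfm, "pfm")) pfm$freq else pfm
}

#' Positional probability matrix implied by the signature model
#'
#' Builds a generating matrix for 21-nt miRNAs: core-preference positions
#' place probability `core` on their preferred pair (split equally, e.g.
#' G/C each at `core/2`), loose positions use `loose`, position 1 carries a
#' 5'-U bias (`five_prime_u` on U, the remainder split over A/C/G) and the
#' remaining positions are uniform.
#'
#' @param model a [default_signature_model()].
#' @param core probability mass on the preferred pair at core positions.
#' @param loose same for loose positions.
#' @param five_prime_u probability of U at position 1.
#' @return a `pfm` object usable with [gen_mirnas()].
#' @export
signature_pfm <- function(model = default_signature_model(), core = 0.8,
                          loose = 0.65, five_prime_u = 0.6) {
  L <- model$length
  freq <- matrix(0.25, nrow = 4, ncol = L, dimnames = list(RNA_BASES, seq_len(L)))
  set_pair <- function(pos, pair, p) {
    other <- setdiff(RNA_BASES, pair)
    freq[pair, pos] <<- p / 2
    freq[other, pos] <<- (1 - p) / 2
  }
  set_pair(model$core_gc_positions, c("G", "C"), core)
  set_pair(model$core_au_positions, c("A", "U"), core)
  set_pair(model$loose_gc_positions, c("G", "C"), loose)
  set_pair(model$loose_au_positions, c("A", "U"), loose)
  if (!1L %in% unlist(model[c("core_gc_positions", "core_au_positions",
                              "loose_gc_positions", "loose_au_positions")])) {
    freq["U", 1L] <- five_prime_u
    freq[c("A", "C", "G"), 1L] <- (1 - five_prime_u) / 3
  }
  structure(list(freq = freq, L = L, n_sequences = NA_integer_,
                 weighting = "generator"), class = "pfm")
}

#' Uniform positional probability matrix
#'
#' @param L sequence length.
#' @return a `pfm` with probability 0.25 everywhere (signature-free null).
#' @export
uniform_pfm <- function(L = 21L) {
  freq <- matrix(0.25, nrow = 4, ncol = L, dimnames = list(RNA_BASES, seq_len(L)))
  structure(list(freq = freq, L = L, n_sequences = NA_integer_,
                 weighting = "generator"), class = "pfm")
}

#' Sample sequences from a positional probability matrix
#'
#' Positions are sampled independently.
#'
#' @param pfm a `pfm` object or 4 x L matrix (rows A/C/G/U).
#' @param n number of sequences.
#' @param seed integer seed.
#' @return character vector of `n` sequences of length L.
#' @export
gen_mirnas <- function(pfm, n, seed = NULL) {
  freq <- pfm_matrix(pfm)
  L <- ncol(freq)
  run_seeded(seed, {
    mat <- vapply(seq_len(L), function(i)
      sample(RNA_BASES, n, replace = TRUE, prob = freq[, i]), character(n))
    if (n == 1L) mat <- matrix(mat, nrow = 1L)
    apply(mat, 1L, paste, collapse = "")
  })
}

#' Sample 21-mers conditioned on carrying (or lacking) the GC signature
#'
#' Rejection-samples from a positional matrix until `n` sequences satisfy
#' (or, with `carry = FALSE`, fail) "inside the GC band AND all core
#' positions match".
#'
#' @param n number of sequences.
#' @param seed integer seed.
#' @param model a `signature_model`.
#' @param pfm generating matrix; defaults to [signature_pfm()] when
#'   conditioning on carriers and [uniform_pfm()] otherwise.
#' @param carry condition direction.
#' @return character vector of `n` sequences.
#' @export
gen_conditioned_mirnas <- function(n, seed = NULL,
                                   model = default_signature_model(),
                                   pfm = NULL, carry = TRUE) {
  if (is.null(pfm)) pfm <- if (carry) signature_pfm(model) else uniform_pfm(model$length)
  run_seeded(seed, {
    out <- character(0)
    while (length(out) < n) {
      batch <- gen_mirnas(pfm, max(2L * n, 64L))
      tab <- signature_table(batch, model)
      ok <- tab$in_band & tab$has_signature
      if (!carry) ok <- !ok
      out <- c(out, batch[ok])
    }
    out[seq_len(n)]
  })
}

#' Synthetic read pool with a planted signature-carrier fraction
#'
#' Each of `n` read draws is, independently with probability
#' `signature_fraction`, a band-and-signature 21-mer, otherwise a 21-mer
#' failing that classification. Draws are aggregated into a collapsed read
#' table with RPM.
#'
#' @param n number of read draws.
#' @param signature_fraction planted carrier probability.
#' @param seed integer seed.
#' @param model a `signature_model`.
#' @return data.frame with `sequence`, `count`, `rpm`, `length`; attribute
#'   `planted_fraction` records the realized carrier fraction of the draws.
#' @export
gen_read_pool <- function(n, signature_fraction, seed = NULL,
                          model = default_signature_model()) {
  run_seeded(seed, {
    carrier <- stats::runif(n) < signature_fraction
    pool_sig <- gen_conditioned_mirnas(max(sum(carrier), 1L), model = model)
    pool_bad <- gen_conditioned_mirnas(max(sum(!carrier), 1L), model = model,
                                       carry = FALSE)
    seqs <- character(n)
    seqs[carrier] <- pool_sig[seq_len(sum(carrier))]
    seqs[!carrier] <- pool_bad[seq_len(sum(!carrier))]
    agg <- stats::aggregate(list(count = rep(1L, n)), by = list(sequence = seqs), FUN = sum)
    reads <- compute_rpm(agg, library_total = n)
    attr(reads, "planted_fraction") <- mean(carrier)
    reads
  })
}

#' Random i.i.d. sequences of a given GC content
#'
#' Per-base probabilities: G and C each `gc/2`, A and U each `(1 - gc)/2`.
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param gc target GC fraction.
#' @param seed integer seed.
#' @return character vector.
#' @export
random_seq <- function(n, length, gc, seed = NULL) {
  run_seeded(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
    vapply(seq_len(n), function(i)
      paste(sample(RNA_BASES, length, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
}

#' Random sequence with an exact G/C count
#'
#' Places exactly `n_gc` G/C bases (G vs C equally likely) at random
#' positions, A/U elsewhere.
#'
#' @param length sequence length.
#' @param n_gc exact number of G/C bases.
#' @param seed integer seed.
#' @return a single sequence.
#' @export
random_seq_exact_gc <- function(length, n_gc, seed = NULL) {
  stopifnot(n_gc >= 0L, n_gc <= length)
  run_seeded(seed, {
    ch <- sample(c("A", "U"), length, replace = TRUE)
    pos <- sample.int(length, n_gc)
    ch[pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    paste(ch, collapse = "")
  })
}

#' Generate a hairpin precursor around a mature 21-mer
#'
#' Precursor layout, 5' to 3': random 5' arm (`arm_gc`), the mature (5p arm),
#' random loop (`loop_gc`), the star strand from [design_star()] (3p arm),
#' random 3' arm (`arm_gc`). Mature spans are recorded exactly.
#'
#' @param mature 21-nt mature sequence.
#' @param arm_length,loop_length segment lengths (nt).
#' @param arm_gc,loop_gc GC fractions of the random segments.
#' @param seed integer seed.
#' @param id precursor identifier.
#' @return a [precursor_record()].
#' @export
gen_precursor <- function(mature, arm_length = 40L, loop_length = 40L,
                          arm_gc = 0.30, loop_gc = 0.30, seed = NULL,
                          id = "synthetic-precursor") {
  mature <- normalize_rna(mature)
  k <- nchar(mature)
  run_seeded(seed, {
    arm5 <- random_seq(1L, arm_length, arm_gc)
    loop <- random_seq(1L, loop_length, loop_gc)
    arm3 <- random_seq(1L, arm_length, arm_gc)
    star <- design_star(mature)$star
    seqn <- paste0(arm5, mature, loop, star, arm3)
    m5 <- c(arm_length + 1L, arm_length + k)
    m3 <- c(arm_length + k + loop_length + 1L, arm_length + k + loop_length + k)
    precursor_record(id = id, sequence = seqn,
                     mature5p_span = m5, mature3p_span = m3)
  })
}

#' Simulate a dicing read population from a precursor
#'
#' With probability `fidelity` a read draw is the exact mature or star
#' (equal odds). Otherwise it is an isomiR/sib-miR: its start is either
#' offset within +/-3 nt of a mature-span start or uniform over the
#' precursor (equal odds), its length is drawn from `len_weights`
#' (20/21/22/24-nt by default), and draws identical to a canonical sequence
#' are resampled so the canonical fraction is exactly the planted one.
#' Draws are aggregated into a collapsed read table with RPM (library total
#' = `n`).
#'
#' @param precursor a [precursor_record()] with both spans.
#' @param fidelity canonical-read probability.
#' @param n number of read draws.
#' @param seed integer seed.
#' @param len_weights named numeric vector of isomiR length weights.
#' @return data.frame with `sequence`, `count`, `rpm`, `length`; attribute
#'   `canonical_fraction` records the realized canonical draw fraction.
#' @export
gen_dicing_reads <- function(precursor, fidelity = 0.8, n = 1000L, seed = NULL,
                             len_weights = c("20" = 0.15, "21" = 0.55,
                                             "22" = 0.15, "24" = 0.15)) {
  m5 <- precursor$mature5p_span
  m3 <- precursor$mature3p_span
  if (is.null(m5) || is.null(m3)) stop("precursor needs both spans", call. = FALSE)
  mature <- span_seq(precursor$sequence, m5)
  star <- span_seq(precursor$sequence, m3)
  lens <- as.integer(names(len_weights))
  L <- precursor$length
  run_seeded(seed, {
    canonical <- stats::runif(n) < fidelity
    seqs <- character(n)
    seqs[canonical] <- sample(c(mature, star), sum(canonical), replace = TRUE)
    for (i in which(!canonical)) {
      repeat {
        len <- sample(lens, 1L, prob = len_weights)
        if (stats::runif(1) < 0.5) {
          anchor <- sample(c(m5[1], m3[1]), 1L)
          start <- anchor + sample(-3L:3L, 1L)
        } else {
          start <- sample.int(L - len + 1L, 1L)
        }
        start <- min(max(start, 1L), L - len + 1L)
        sq <- substr(precursor$sequence, start, start + len - 1L)
        if (sq != mature && sq != star) break
      }
      seqs[i] <- sq
    }
    agg <- stats::aggregate(list(count = rep(1L, n)), by = list(sequence = seqs), FUN = sum)
    reads <- compute_rpm(agg, library_total = n)
    attr(reads, "canonical_fraction") <- mean(canonical)
    reads
  })
}

COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Generate an mRNA with a planted miRNA target site
#'
#' An i.i.d. background of the given GC content with the reverse complement
#' of the miRNA planted at `site_position`; bases at `mismatch_positions`
#' (site coordinates, 1..21) are replaced by a base that neither Watson-Crick
#' pairs nor G:U wobbles with the miRNA base they face.
#'
#' @param mirna 21-nt miRNA.
#' @param mrna_length mRNA length.
#' @param background_gc background GC fraction.
#' @param site_position 1-based start of the planted site.
#' @param mismatch_positions site coordinates to un-pair.
#' @param seed integer seed.
#' @param id mRNA identifier.
#' @return list with `mrna` (data.frame row: `id`, `sequence`, `length`) and
#'   `site` (data.frame: `mrna_id`, `start`, `end`, `mirna_id`).
#' @export
gen_target_mrna <- function(mirna, mrna_length = 200L, background_gc = 0.42,
                            site_position = 90L, mismatch_positions = integer(0),
                            seed = NULL, id = "synthetic-mrna") {
  mirna <- normalize_rna(mirna)
  k <- nchar(mirna)
  if (site_position < 1L || site_position + k - 1L > mrna_length)
    stop("site does not fit within the mRNA", call. = FALSE)
  run_seeded(seed, {
    seqn <- random_seq(1L, mrna_length, background_gc)
    site <- reverse_complement(mirna)
    mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
    if (length(mismatch_positions) > 0L) {
      sch <- strsplit(site, "", fixed = TRUE)[[1]]
      for (j in mismatch_positions) {
        b <- mi[k + 1L - j]  # miRNA base paired with site position j
        forbidden <- COMPLEMENT[[b]]
        if (b == "G") forbidden <- c(forbidden, "U")
        if (b == "U") forbidden <- c(forbidden, "G")
        sch[j] <- sample(setdiff(RNA_BASES, forbidden), 1L)
      }
      site <- paste(sch, collapse = "")
    }
    substr(seqn, site_position, site_position + k - 1L) <- site
    list(
      mrna = data.frame(id = id, sequence = seqn, length = mrna_length,
                        stringsAsFactors = FALSE),
      site = data.frame(mrna_id = id, start = site_position,
                        end = site_position + k - 1L,
                        mirna_id = "synthetic-mirna", stringsAsFactors = FALSE)
    )
  })
}

#' Four-stem artificial construct preset
#'
#' Emulates the in-vivo dicing-preference construct: four stem-loops with an
#' identical backbone (AU-rich arms and loop) differing only in their
#' miRNA/miRNA* insert — matures at approximately 28% GC, 52% GC carrying
#' the full core signature, 52% GC with the signature scrambled (same
#' nucleotide composition, core violated), and 71% GC.
#'
#' @param seed integer seed.
#' @param arm_length,loop_length backbone segment lengths.
#' @param arm_gc backbone GC fraction.
#' @return list with `stems` (named list of four [precursor_record()]s),
#'   `matures` (data.frame: `stem`, `sequence`, `gc`, `has_signature`),
#'   `construct` (concatenated sequence) and `stem_offsets` (data.frame of
#'   stem start positions and mature spans in construct coordinates).
#' @export
gen_four_stem_construct <- function(seed = 1L, arm_length = 30L,
                                    loop_length = 30L, arm_gc = 0.25) {
  run_seeded(seed, {
    model <- default_signature_model()
    # 52% GC (11/21) with the full core signature
    sig <- NULL
    repeat {
      cand <- gen_conditioned_mirnas(1L, model = model)
      if (round(gc_content(cand) * 21) == 11) { sig <- cand; break }
    }
    # scrambled: same letters as the signature insert, core destroyed
    ch <- strsplit(sig, "", fixed = TRUE)[[1]]
    repeat {
      scr <- paste(sample(ch), collapse = "")
      if (!evaluate_signature(scr, model)$has_signature) break
    }
    # low- and high-GC inserts, conditioned to lack the signature
    low <- NULL
    repeat {
      cand <- random_seq_exact_gc(21L, 6L)
      if (!evaluate_signature(cand, model)$has_signature) { low <- cand; break }
    }
    high <- NULL
    repeat {
      cand <- random_seq_exact_gc(21L, 15L)
      if (!evaluate_signature(cand, model)$has_signature) { high <- cand; break }
    }
    matures <- c(gc28 = low, gc52_signature = sig, gc52_scrambled = scr,
                 gc71 = high)
    arm5 <- random_seq(1L, arm_length, arm_gc)
    loop <- random_seq(1L, loop_length, arm_gc)
    arm3 <- random_seq(1L, arm_length, arm_gc)
    stems <- lapply(names(matures), function(nm) {
      m <- matures[[nm]]
      star <- design_star(m)$star
      seqn <- paste0(arm5, m, loop, star, arm3)
      precursor_record(
        id = paste0("stem-", nm), sequence = seqn,
        mature5p_span = c(arm_length + 1L, arm_length + 21L),
        mature3p_span = c(arm_length + 21L + loop_length + 1L,
                          arm_length + 21L + loop_length + 21L))
    })
    names(stems) <- names(matures)
    construct <- paste(vapply(stems, `[[`, character(1), "sequence"),
                       collapse = "")
    stem_len <- nchar(stems[[1]]$sequence)
    offsets <- (seq_along(stems) - 1L) * stem_len
    stem_offsets <- data.frame(
      stem = names(stems),
      stem_start = offsets + 1L,
      mature5p_start = offsets + arm_length + 1L,
      mature3p_start = offsets + arm_length + 21L + loop_length + 1L,
      stringsAsFactors = FALSE)
    list(stems = stems,
         matures = data.frame(stem = names(matures),
                              sequence = unname(matures),
                              gc = gc_content(unname(matures)),
                              has_signature = vapply(unname(matures), function(s)
                                evaluate_signature(s, model)$has_signature, logical(1)),
                              row.names = NULL, stringsAsFactors = FALSE),
         construct = construct,
         stem_offsets = stem_offsets)
  })
}
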