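# GC content and positional composition statistics. GC content is the number
# of G plus the number of C divided by sequence length. Positional analyses
# operate on uniform-length (21-nt) sets; shorter/longer sequences are
# filtered out by the caller, never padded.

#' GC content of sequences
#'
#' (#G + #C) / length, on normalized RNA sequences. Vectorized.
#'
#' @param sequence character vector of non-empty sequences.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  nchar(gsub("[^GC]", "", sequence)) / nchar(sequence)
}

#' Per-segment GC content of a hairpin precursor
#'
#' Splits the precursor into five segments — 5' arm, 5p mature, loop, 3p
#' mature, 3' arm — from the annotated mature spans and reports GC and length
#' per segment. Zero-length segments report GC as `NA` (undefined, never 0)
#' so segment means are not biased.
#'
#' @param precursor a [precursor_record()] with both mature spans.
#' @return data.frame with columns `segment`, `gc`, `length`.
#' @export
gc_by_segment <- function(precursor) {
  m5 <- precursor$mature5p_span
  m3 <- precursor$mature3p_span
  if (is.null(m5) || is.null(m3))
    stop("both mature spans are required for segment analysis", call. = FALSE)
  L <- precursor$length
  spans <- list(arm5     = c(1L, m5[1] - 1L),
                mature5p = m5,
                loop     = c(m5[2] + 1L, m3[1] - 1L),
                mature3p = m3,
                arm3     = c(m3[2] + 1L, L))
  seg_len <- vapply(spans, function(sp) max(0L, sp[2] - sp[1] + 1L), integer(1))
  stopifnot(sum(seg_len) == L)
  gc <- vapply(names(spans), function(nm) {
    sp <- spans[[nm]]
    if (sp[2] < sp[1]) return(NA_real_)
    gc_content(span_seq(precursor$sequence, sp))
  }, numeric(1))
  data.frame(segment = names(spans), gc = unname(gc), length = unname(seg_len),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Position-specific nucleotide frequency matrix
#'
#' Relative frequency of each nucleotide at each position: the count of the
#' nucleotide at position x divided by the total number of sequences (or, in
#' abundance mode, by the total read count — "redundant reads" weighting).
#'
#' @param seqs character vector of sequences, all the same length.
#' @param weighting `"unique"` (each sequence once) or `"abundance"`
#'   (each sequence weighted by its read count).
#' @param counts integer vector of read counts, required iff
#'   `weighting == "abundance"`.
#' @return object of class `pfm`: list with `freq` (4 x L matrix, rows
#'   A/C/G/U, columns summing to 1), `L`, `n_sequences`, `weighting`.
#' @export
position_frequency_matrix <- function(seqs, weighting = c("unique", "abundance"),
                                      counts = NULL) {
  weighting <- match.arg(weighting)
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("mixed sequence lengths: e.g. ",
         paste(utils::head(seqs[lens != lens[1]], 3L), collapse = ", "),
         call. = FALSE)
  }
  L <- lens[1]
  w <- if (weighting == "abundance") {
    if (is.null(counts) || length(counts) != length(seqs))
      stop("abundance weighting requires one count per sequence", call. = FALSE)
    as.numeric(counts)
  } else rep(1, length(seqs))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  freq <- vapply(seq_len(L), function(i) {
    col <- mat[, i]
    vapply(RNA_BASES, function(b) sum(w[col == b]), numeric(1))
  }, numeric(4))
  freq <- freq / sum(w)
  dimnames(freq) <- list(RNA_BASES, seq_len(L))
  structure(list(freq = freq, L = L, n_sequences = length(seqs),
                 weighting = weighting),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix: L =", x$L, ", n =", x$n_sequences,
      paste0("(", x$weighting, " weighting)\n"))
  print(round(x$freq, 3))
  invisible(x)
}

#' Per-position G/C ratio track of a frequency matrix
#'
#' @param pfm a [position_frequency_matrix()] result.
#' @return data.frame with `position`, `gc` (= freq G + freq C) and
#'   `au` (= 1 - gc).
#' @export
gc_ratio_track <- function(pfm) {
  gc <- pfm$freq["G", ] + pfm$freq["C", ]
  data.frame(position = seq_len(pfm$L), gc = unname(gc), au = 1 - unname(gc))
}

#' Position-specific dinucleotide frequencies
#'
#' Frequency of each of the 16 dinucleotides starting at positions 1..L-1,
#' plus the pooled (position-free) dinucleotide frequencies.
#'
#' @param seqs character vector of uniform-length sequences (length >= 2).
#' @return list with `per_position` (16 x (L-1) matrix, columns summing to 1)
#'   and `pooled` (named vector of 16 frequencies summing to 1).
#' @export
dinucleotide_position_frequency <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("mixed sequence lengths", call. = FALSE)
  L <- lens[1]
  if (L < 2L) stop("sequences must be at least 2 nt", call. = FALSE)
  dinucs <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  per <- vapply(seq_len(L - 1L), function(i) {
    di <- substr(seqs, i, i + 1L)
    tab <- table(factor(di, levels = dinucs))
    as.numeric(tab) / length(seqs)
  }, numeric(16))
  dimnames(per) <- list(dinucs, seq_len(L - 1L))
  pooled <- rowSums(per) / (L - 1L)
  list(per_position = per, pooled = pooled)
}

#' Uniform random subset of sequences (sampling control)
#'
#' Reproducible sampling without replacement, used as the "randomly sampled
#' sequences still show the bias" control.
#'
#' @param seqs character vector.
#' @param k subset size, `0 <= k <= length(seqs)`.
#' @param seed integer seed.
#' @return character vector of length `k`.
#' @export
random_sample_control <- function(seqs, k, seed = NULL) {
  if (k > length(seqs)) stop("k exceeds the number of sequences", call. = FALSE)
  if (k == length(seqs)) return(seqs)
  run_seeded(seed, seqs[sample.int(length(seqs), k)])
}

#' Compare two GC distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test with tie correction, delegated to
#' [stats::wilcox.test()].
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return list with `U` and `p`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  wt <- stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value)
}
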