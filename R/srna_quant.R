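# Exact-match mapping of collapsed small-RNA reads to a precursor (no
# mismatches, no gaps, forward orientation by default) and class-wise
# abundance summaries: all 21-24-nt reads, 21-nt reads, reads in the 40-60%
# GC band, and band-plus-signature reads.

#' Map reads to a precursor by exact matching
#'
#' Reports every exact occurrence of each read in the precursor sequence.
#' Reads are length-filtered (16-35 nt by default) before mapping. Forward
#' orientation only by default: sRNAs derive from the expressed hairpin
#' transcript; antisense matching can be enabled.
#'
#' @param reads data.frame with `sequence`, `count`, `rpm`.
#' @param precursor a [precursor_record()] or a plain sequence string.
#' @param min_len,max_len read-length filter bounds (inclusive).
#' @param antisense also match the reverse complement of each read.
#' @return data.frame with `sequence`, `start`, `end`, `length`, `strand`,
#'   `count`, `rpm`; attribute `n_unmapped` counts length-passing reads with
#'   no placement.
#' @export
map_reads <- function(reads, precursor, min_len = 16L, max_len = 35L,
                      antisense = FALSE) {
  prec_seq <- if (inherits(precursor, "precursor_record")) precursor$sequence else precursor
  keep <- nchar(reads$sequence) >= min_len & nchar(reads$sequence) <= max_len
  reads <- reads[keep, , drop = FALSE]
  rows <- vector("list", nrow(reads))
  n_unmapped <- 0L
  for (r in seq_len(nrow(reads))) {
    sq <- reads$sequence[r]
    hits <- find_occurrences(sq, prec_seq)
    placements <- NULL
    if (length(hits) > 0L) {
      placements <- data.frame(sequence = sq, start = hits,
                               end = hits + nchar(sq) - 1L,
                               length = nchar(sq), strand = "+",
                               count = reads$count[r], rpm = reads$rpm[r],
                               stringsAsFactors = FALSE)
    }
    if (antisense) {
      rc_hits <- find_occurrences(reverse_complement(sq), prec_seq)
      if (length(rc_hits) > 0L) {
        placements <- rbind(placements, data.frame(
          sequence = sq, start = rc_hits,
          end = rc_hits + nchar(sq) - 1L,
          length = nchar(sq), strand = "-",
          count = reads$count[r], rpm = reads$rpm[r],
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(placements)) n_unmapped <- n_unmapped + 1L else rows[[r]] <- placements
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(), start = integer(), end = integer(),
                      length = integer(), strand = character(),
                      count = integer(), rpm = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Keep reads above an RPM threshold
#'
#' Strict inequality: a read at exactly the threshold is excluded ("more
#' than 5 RPM").
#'
#' @param reads data.frame with an `rpm` column.
#' @param threshold RPM cutoff (default 5).
#' @return the subset with `rpm > threshold`.
#' @export
filter_rpm <- function(reads, threshold = 5) {
  reads[reads$rpm > threshold, , drop = FALSE]
}

#' Class-wise abundance summary of mapped reads
#'
#' Summarizes mapped reads into the four nested display classes — all
#' 21-24-nt reads; 21-nt reads; reads in the 40-60% GC band (any length);
#' reads in the band that are 21-nt and carry the GC signature — plus a
#' per-size breakdown. A read contributes once per class by sequence, even
#' when it maps to several positions.
#'
#' @param alignments output of [map_reads()].
#' @param model a [default_signature_model()].
#' @return object of class `abundance_summary`: list with `rpm` and
#'   `n_unique` (named vectors over classes `all_21_24`, `len21`, `gc_band`,
#'   `band_and_signature`) and `by_size` (data.frame `length`, `rpm`,
#'   `n_unique` over observed mapped lengths).
#' @export
abundance_by_class <- function(alignments, model = default_signature_model()) {
  uniq <- alignments[!duplicated(alignments$sequence),
                     c("sequence", "length", "count", "rpm"), drop = FALSE]
  gc <- if (nrow(uniq)) gc_content(uniq$sequence) else numeric(0)
  in_band <- gc >= model$gc_band[1] & gc <= model$gc_band[2]
  is21 <- uniq$length == model$length
  has_sig <- rep(FALSE, nrow(uniq))
  if (any(is21)) {
    has_sig[is21] <- vapply(uniq$sequence[is21], function(s)
      evaluate_signature(s, model)$has_signature, logical(1))
  }
  classes <- list(
    all_21_24 = uniq$length >= 21L & uniq$length <= 24L,
    len21 = is21,
    gc_band = in_band,
    band_and_signature = in_band & is21 & has_sig
  )
  rpm <- vapply(classes, function(sel) sum(uniq$rpm[sel]), numeric(1))
  n_unique <- vapply(classes, function(sel) sum(sel), integer(1))
  sizes <- sort(unique(uniq$length))
  by_size <- data.frame(
    length = sizes,
    rpm = vapply(sizes, function(l) sum(uniq$rpm[uniq$length == l]), numeric(1)),
    n_unique = vapply(sizes, function(l) sum(uniq$length == l), integer(1))
  )
  structure(list(rpm = rpm, n_unique = n_unique, by_size = by_size),
            class = "abundance_summary")
}

#' @export
print.abundance_summary <- function(x, ...) {
  cat("abundance summary (RPM):\n")
  print(round(x$rpm, 2))
  cat("unique sequences:\n")
  print(x$n_unique)
  invisible(x)
}
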