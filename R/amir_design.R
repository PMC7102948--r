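# Artificial miRNA (amiR) design: star strand with canonical duplex geometry
# (19-bp duplex, 2-nt 3' overhangs on both strands), embedding a guide/star
# pair into a natural precursor backbone, signature-aware ranking of
# candidate 21-mers, and the anthocyanin readout formula used to quantify
# silencing of an anthocyanin-inducing target.

#' Design the star strand of a 21-nt guide
#'
#' Dicing of a plant pre-miRNA releases a 19-bp duplex with 2-nt 3'
#' overhangs: guide position i pairs star position 20 - i for i in 1..19, so
#' star positions 1..19 are the reverse complement of guide positions 1..19
#' and positions 20-21 of both strands are unpaired. The star overhang
#' defaults to "UU"; real designers take it from backbone context, so it is
#' overridable.
#'
#' @param guide 21-nt RNA sequence.
#' @param overhang 2-nt star 3' overhang.
#' @return list of class `duplex_design`: `guide`, `star`, `paired_length`
#'   (19), `overhang_length` (2).
#' @export
design_star <- function(guide, overhang = "UU") {
  guide <- normalize_rna(guide)
  if (nchar(guide) != 21L) stop("guide must be 21 nt", call. = FALSE)
  if (nchar(overhang) != 2L) stop("overhang must be 2 nt", call. = FALSE)
  star <- paste0(reverse_complement(substr(guide, 1L, 19L)),
                 normalize_rna(overhang))
  structure(list(guide = guide, star = star,
                 paired_length = 19L, overhang_length = 2L),
            class = "duplex_design")
}

#' Replace the mature arms of a backbone precursor with a guide/star pair
#'
#' Swaps the annotated mature spans of a natural precursor backbone for an
#' amiR guide and its star, leaving every other base untouched (no indel
#' surgery: replacement lengths must equal the span lengths).
#'
#' @param backbone a [precursor_record()] with both mature spans.
#' @param guide,star 21-nt sequences (see [design_star()]).
#' @param guide_arm which arm receives the guide: `"5p"` or `"3p"`.
#' @return a new `precursor_record` with the same spans and the guide/star
#'   inserted.
#' @export
embed_in_backbone <- function(backbone, guide, star, guide_arm = c("5p", "3p")) {
  guide_arm <- match.arg(guide_arm)
  m5 <- backbone$mature5p_span
  m3 <- backbone$mature3p_span
  if (is.null(m5) || is.null(m3))
    stop("backbone must have both mature spans", call. = FALSE)
  ins5 <- if (guide_arm == "5p") guide else star
  ins3 <- if (guide_arm == "5p") star else guide
  if (nchar(ins5) != m5[2] - m5[1] + 1L || nchar(ins3) != m3[2] - m3[1] + 1L)
    stop("replacement length must equal the span length", call. = FALSE)
  s <- backbone$sequence
  substr(s, m5[1], m5[2]) <- ins5
  substr(s, m3[1], m3[2]) <- ins3
  precursor_record(id = paste0(backbone$id, "-amir"), sequence = s,
                   mature5p_span = m5, mature3p_span = m3,
                   family = backbone$family)
}

#' Rank amiR candidates by GC band, signature score and 5' nucleotide
#'
#' Ordering keys, in descending priority: (1) inside the 40-60% GC band
#' first; (2) signature score, descending; (3) distance of GC from 0.50,
#' ascending; (4) 5'-U before non-U (5'-U miRNAs associate with AGO1);
#' (5) sequence lexicographic, for determinism. The keys are this package's
#' synthesis of the qualitative design conclusions (band and signature
#' dominate accumulation); each key can be inspected in the output.
#'
#' @param candidates data.frame with `name` and `sequence` (21-nt) columns.
#' @param model a [default_signature_model()].
#' @return the candidates with `gc`, `in_band`, `score`, `core_matches`,
#'   `has_signature`, `five_prime_u` and `rank` columns, sorted by rank.
#' @export
rank_amirs <- function(candidates, model = default_signature_model()) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  seqs <- normalize_rna(candidates$sequence, ids = candidates$name)
  if (any(nchar(seqs) != model$length))
    stop("all candidates must be ", model$length, " nt", call. = FALSE)
  tab <- signature_table(seqs, model)
  out <- data.frame(name = candidates$name, sequence = seqs,
                    gc = tab$gc, in_band = tab$in_band, score = tab$score,
                    core_matches = tab$core_matches,
                    has_signature = tab$has_signature,
                    five_prime_u = substr(seqs, 1L, 1L) == "U",
                    stringsAsFactors = FALSE)
  ord <- order(!out$in_band, -out$score, abs(out$gc - 0.5),
               !out$five_prime_u, out$sequence)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Relative anthocyanin content per gram fresh weight
#'
#' \eqn{[A_{530} - 0.25 \times A_{657}] \times 5 / \mathrm{FW(g)}}. A
#' negative corrected absorbance is reported as-is with a warning.
#'
#' @param abs530,abs657 absorbances at 530 and 657 nm (>= 0), vectorized.
#' @param fresh_weight_g fresh tissue weight in grams (> 0).
#' @return relative anthocyanin content per g fresh weight.
#' @export
anthocyanin_content <- function(abs530, abs657, fresh_weight_g) {
  if (any(fresh_weight_g <= 0)) stop("fresh weight must be > 0", call. = FALSE)
  if (any(abs530 < 0) || any(abs657 < 0)) stop("absorbances must be >= 0", call. = FALSE)
  val <- (abs530 - 0.25 * abs657) * 5 / fresh_weight_g
  if (any(val < 0)) warning("negative corrected absorbance reported as-is", call. = FALSE)
  val
}
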