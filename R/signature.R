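# The flexible positional GC signature of 21-nt plant miRNAs. Core
# preferences: G/C at positions 8-9 and 18-19, A/U at positions 5, 7, 10 and
# 15. Less stringent (loose) preferences: G/C at 2-4, 6 and 21, A/U at 17
# and 20. Abundantly processed miRNAs additionally sit in a 40-60% overall
# GC band. Only 21-nt sequences are in the signature's domain.

#' Default 21-nt GC signature model
#'
#' @param policy `"strict"`: a sequence has the signature iff all 8 core
#'   positions match; `"at_least_k"`: iff at least `k` core positions match.
#' @param k minimum core matches for the `"at_least_k"` policy.
#' @param include_15_in_core keep position 15 in the A/U core (default) or
#'   demote it to the loose A/U set.
#' @return object of class `signature_model`.
#' @export
default_signature_model <- function(policy = c("strict", "at_least_k"), k = 8L,
                                    include_15_in_core = TRUE) {
  policy <- match.arg(policy)
  core_au <- if (include_15_in_core) c(5L, 7L, 10L, 15L) else c(5L, 7L, 10L)
  loose_au <- if (include_15_in_core) c(17L, 20L) else c(15L, 17L, 20L)
  m <- structure(list(
    core_gc_positions  = c(8L, 9L, 18L, 19L),
    core_au_positions  = core_au,
    loose_gc_positions = c(2L, 3L, 4L, 6L, 21L),
    loose_au_positions = loose_au,
    loose_weight = 0.5,
    gc_band = c(0.40, 0.60),
    length = 21L,
    policy = policy,
    k = as.integer(k)
  ), class = "signature_model")
  validate_signature_model(m)
  m
}

validate_signature_model <- function(m) {
  sets <- list(m$core_gc_positions, m$core_au_positions,
               m$loose_gc_positions, m$loose_au_positions)
  all_pos <- unlist(sets)
  if (anyDuplicated(all_pos)) stop("signature position sets overlap", call. = FALSE)
  if (any(all_pos < 1L | all_pos > m$length))
    stop("signature positions outside [1, length]", call. = FALSE)
  if (m$loose_weight <= 0 || m$loose_weight > 1)
    stop("loose_weight must be in (0, 1]", call. = FALSE)
  invisible(m)
}

#' @export
print.signature_model <- function(x, ...) {
  cat("21-nt GC signature model\n",
      " core  G/C: ", paste(x$core_gc_positions, collapse = ","), "\n",
      " core  A/U: ", paste(x$core_au_positions, collapse = ","), "\n",
      " loose G/C: ", paste(x$loose_gc_positions, collapse = ","),
      " (weight ", x$loose_weight, ")\n",
      " loose A/U: ", paste(x$loose_au_positions, collapse = ","), "\n",
      " GC band:   [", x$gc_band[1], ", ", x$gc_band[2], "]",
      "  policy: ", x$policy, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a signature model (YAML)
#'
#' @param model a `signature_model`.
#' @param path file path.
#' @return `read_signature_model()` returns a `signature_model`.
#' @export
write_signature_model <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  m <- yaml::read_yaml(path)
  int_fields <- c("core_gc_positions", "core_au_positions",
                  "loose_gc_positions", "loose_au_positions", "length", "k")
  for (f in int_fields) m[[f]] <- as.integer(m[[f]])
  m$gc_band <- as.numeric(m$gc_band)
  m <- structure(m, class = "signature_model")
  validate_signature_model(m)
  m
}

#' Score a 21-nt sequence against the GC signature
#'
#' A position matches when it holds G/C at a G/C-preference position or A/U
#' at an A/U-preference position. The score is
#' `core_matches + loose_weight * loose_matches`. `has_signature` follows the
#' model policy (strict: all core positions match). Sequences of any length
#' other than `model$length` are rejected, not truncated.
#'
#' @param sequence normalized RNA sequence of length `model$length`.
#' @param model a [default_signature_model()].
#' @return object of class `signature_report`: list with `matches` (named
#'   logical over all signature positions), `core_matches`, `loose_matches`,
#'   `score`, `has_signature`, `gc`, `in_band`.
#' @export
evaluate_signature <- function(sequence, model = default_signature_model()) {
  if (nchar(sequence) != model$length)
    stop("sequence length ", nchar(sequence), " != model length ",
         model$length, call. = FALSE)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_gc <- ch %in% c("G", "C")
  pos_match <- function(pos, want_gc) {
    stats::setNames(if (want_gc) is_gc[pos] else !is_gc[pos], pos)
  }
  core <- c(pos_match(model$core_gc_positions, TRUE),
            pos_match(model$core_au_positions, FALSE))
  loose <- c(pos_match(model$loose_gc_positions, TRUE),
             pos_match(model$loose_au_positions, FALSE))
  core_matches <- sum(core)
  loose_matches <- sum(loose)
  has_sig <- if (model$policy == "strict") all(core) else core_matches >= model$k
  gc <- gc_content(sequence)
  structure(list(
    matches = c(core, loose),
    core_matches = core_matches,
    loose_matches = loose_matches,
    score = core_matches + model$loose_weight * loose_matches,
    has_signature = has_sig,
    gc = gc,
    in_band = gc >= model$gc_band[1] && gc <= model$gc_band[2]
  ), class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("signature report: core ", x$core_matches, ", loose ", x$loose_matches,
      ", score ", x$score, ", GC ", round(x$gc, 3),
      if (x$in_band) " (in band)" else " (out of band)",
      if (x$has_signature) ", has signature\n" else ", no signature\n", sep = "")
  invisible(x)
}

#' Signature table for a set of 21-nt sequences
#'
#' Convenience wrapper applying [evaluate_signature()] to each sequence.
#'
#' @param seqs character vector of sequences of the model length.
#' @param model a `signature_model`.
#' @return data.frame with `sequence`, `gc`, `in_band`, `core_matches`,
#'   `loose_matches`, `score`, `has_signature`.
#' @export
signature_table <- function(seqs, model = default_signature_model()) {
  reps <- lapply(seqs, evaluate_signature, model = model)
  data.frame(
    sequence = seqs,
    gc = vapply(reps, `[[`, numeric(1), "gc"),
    in_band = vapply(reps, `[[`, logical(1), "in_band"),
    core_matches = vapply(reps, `[[`, integer(1), "core_matches"),
    loose_matches = vapply(reps, `[[`, integer(1), "loose_matches"),
    score = vapply(reps, `[[`, numeric(1), "score"),
    has_signature = vapply(reps, `[[`, logical(1), "has_signature"),
    stringsAsFactors = FALSE
  )
}

#' Fraction of 21-nt reads carrying the GC signature within the GC band
#'
#' Among reads of the model length, the fraction that are both inside the GC
#' band and carry the signature — reported unweighted (unique sequences) and
#' abundance-weighted (by RPM). Returns `NA` fractions (with a warning) when
#' no read has the model length.
#'
#' @param reads data.frame with `sequence`, `count`, `rpm` (see
#'   [read_read_table()]).
#' @param model a `signature_model`.
#' @return list with `unique_fraction`, `weighted_fraction`, `n_unique`
#'   (denominator, unique 21-nt sequences), `rpm_total` (denominator, RPM).
#' @export
signature_fraction <- function(reads, model = default_signature_model()) {
  sel <- nchar(reads$sequence) == model$length
  if (!any(sel)) {
    warning("no reads of the model length; signature fraction undefined",
            call. = FALSE)
    return(list(unique_fraction = NA_real_, weighted_fraction = NA_real_,
                n_unique = 0L, rpm_total = 0))
  }
  sub <- reads[sel, , drop = FALSE]
  tab <- signature_table(sub$sequence, model)
  hit <- tab$in_band & tab$has_signature
  list(unique_fraction = mean(hit),
       weighted_fraction = sum(sub$rpm[hit]) / sum(sub$rpm),
       n_unique = nrow(sub),
       rpm_total = sum(sub$rpm))
}
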