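# Dinucleotide-preserving shuffle (Altschul-Erickson style). A shuffled
# sequence has exactly the same dinucleotide multiset as the input — hence
# the same mononucleotide counts and the same first and last nucleotide.
# Construction: the sequence is a walk on the 4-vertex nucleotide multigraph
# whose edges are its dinucleotides; a uniformly random Eulerian path with
# the same endpoints is drawn by (i) rejection-sampling a uniform "last-edge"
# arborescence rooted at the terminal nucleotide and (ii) uniformly permuting
# the remaining out-edges of every vertex (BEST theorem), which yields a
# uniform draw over all dinucleotide-preserving shuffles.

shuffle_one <- function(ch) {
  n <- length(ch)
  if (n <= 2L || length(unique(ch)) == 1L) return(paste(ch, collapse = ""))
  from <- ch[-n]
  to <- ch[-1L]
  verts <- unique(ch)
  adj <- split(to, factor(from, levels = verts))
  t_v <- ch[n]
  need_last <- setdiff(names(adj)[lengths(adj) > 0L], t_v)

  reaches_root <- function(last_edge) {
    for (v in need_last) {
      cur <- v
      for (step in seq_len(length(verts) + 1L)) {
        cur <- last_edge[[cur]]
        if (identical(cur, t_v)) break
        if (is.null(last_edge[[cur]])) return(FALSE)  # dead end before root
        if (step > length(verts)) return(FALSE)       # cycle
      }
      if (!identical(cur, t_v)) return(FALSE)
    }
    TRUE
  }

  repeat {
    last_edge <- lapply(adj[need_last], function(tt) tt[sample.int(length(tt), 1L)])
    if (reaches_root(last_edge)) break
  }

  ordered <- lapply(names(adj), function(v) {
    tt <- adj[[v]]
    if (v %in% need_last) {
      le <- last_edge[[v]]
      tt <- tt[-match(le, tt)]
      c(if (length(tt)) sample(tt) else character(0), le)
    } else {
      if (length(tt) > 1L) sample(tt) else tt
    }
  })
  names(ordered) <- names(adj)

  out <- character(n)
  out[1L] <- ch[1L]
  ptr <- stats::setNames(rep(1L, length(ordered)), names(ordered))
  cur <- ch[1L]
  for (i in 2L:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide-preserving shuffle
#'
#' Uniformly shuffles each sequence over all arrangements that preserve its
#' dinucleotide multiset (Euler-path construction). Mononucleotide counts and
#' the first and last nucleotide are preserved by construction. Deterministic
#' for a given `(sequence, seed)` pair.
#'
#' @param sequence character vector of sequences (each length >= 2).
#' @param seed integer seed.
#' @return character vector of shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (any(nchar(sequence) < 2L)) stop("sequences must be at least 2 nt", call. = FALSE)
  run_seeded(seed, vapply(strsplit(sequence, "", fixed = TRUE), shuffle_one,
                          character(1)))
}

#' Positional-null check on a dinucleotide-shuffled set
#'
#' Shuffles each sequence, builds the positional frequency matrix of the
#' shuffled set, and reports the per-position z-value of the G/C ratio
#' against the mean interior G/C ratio (binomial standard error at the set
#' size). Positions 1, 2, L-1 and L are excluded: a dinucleotide-preserving
#' shuffle fixes the terminal nucleotides outright, and the composition of
#' the positions adjacent to them is pinned by the preserved dinucleotide
#' multiset (position 2 is a uniform draw from the successors of the fixed
#' first base, position L-1 from the predecessors of the fixed last base),
#' so those four positions retain structure by construction and carry no
#' information about the positional null.
#'
#' @param seqs uniform-length sequences (the signature-bearing set).
#' @param seed integer seed for the shuffles.
#' @return data.frame with `position`, `gc`, `z` for interior positions, plus
#'   attributes `p0` (interior mean GC) and `se`.
#' @export
shuffle_null_track <- function(seqs, seed = NULL) {
  shuf <- dinucleotide_shuffle(seqs, seed = seed)
  pfm <- position_frequency_matrix(shuf)
  track <- gc_ratio_track(pfm)
  interior <- track[track$position > 2L & track$position < pfm$L - 1L, , drop = FALSE]
  p0 <- mean(interior$gc)
  se <- sqrt(p0 * (1 - p0) / pfm$n_sequences)
  interior$z <- (interior$gc - p0) / se
  attr(interior, "p0") <- p0
  attr(interior, "se") <- se
  interior
}
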