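# GC structure around miRNA target sites on mRNAs: sliding-window GC, a
# per-position GC background from random cDNA windows, site GC normalized by
# that background, and the antiparallel position map between a 21-nt miRNA
# and its 21-nt target site.

#' Sliding-window GC profile
#'
#' GC content in windows of `window` nt advanced by `step` nt.
#'
#' @param sequence normalized sequence, length >= `window`.
#' @param window window size (nt); 21 matches the miRNA target-site length.
#' @param step step size (nt).
#' @return data.frame with `start` (1-based window start) and `gc`.
#' @export
sliding_window_gc <- function(sequence, window = 21L, step = 1L) {
  L <- nchar(sequence)
  if (L < window) stop("sequence shorter than the window", call. = FALSE)
  starts <- seq.int(1L, L - window + 1L, by = step)
  gc <- vapply(starts, function(s)
    gc_content(substr(sequence, s, s + window - 1L)), numeric(1))
  data.frame(start = starts, gc = gc)
}

#' Per-position GC background from random cDNA windows
#'
#' Draws `n_windows` random 21-nt windows uniformly over all eligible
#' (sequence, start) pairs of the cDNA pool and reports the per-position
#' G/C fraction — the normalizing background for site GC tracks.
#'
#' @param cdnas character vector of cDNA sequences (each >= 21 nt is
#'   eligible; shorter ones are skipped).
#' @param n_windows number of windows to draw.
#' @param seed integer seed.
#' @param window window length (default 21).
#' @return numeric vector of length `window` with attribute `n_windows`.
#' @export
background_position_gc <- function(cdnas, n_windows = 10000L, seed = NULL,
                                   window = 21L) {
  elig <- nchar(cdnas) >= window
  if (!any(elig)) stop("no cDNA of at least the window length", call. = FALSE)
  cdnas <- cdnas[elig]
  n_starts <- nchar(cdnas) - window + 1L
  run_seeded(seed, {
    pick <- sample.int(sum(n_starts), n_windows, replace = TRUE)
    seq_idx <- findInterval(pick - 1L, cumsum(c(0L, n_starts)),
                            rightmost.closed = FALSE)
    start <- pick - c(0L, cumsum(n_starts))[seq_idx]
    wins <- substr(cdnas[seq_idx], start, start + window - 1L)
    mat <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
    bg <- colMeans(mat == "G" | mat == "C")
    attr(bg, "n_windows") <- n_windows
    bg
  })
}

#' Background-normalized positional GC of target sites
#'
#' For each site position i (1..21, mRNA 5' to 3') computes the fraction of
#' sites carrying G or C at i divided by the background GC at i, and the same
#' ratio for one adjacent upstream and one downstream 21-nt window (spans
#' shifted by -21 / +21 nt). Sites too close to an mRNA end for an adjacent
#' window contribute only to the windows that fit (logged via attributes).
#'
#' @param sites data.frame with `mrna_id`, `start`, `end` (1-based inclusive,
#'   21-nt spans), `mirna_id`.
#' @param mrnas named character vector (or data.frame from [read_fasta()])
#'   of mRNA sequences.
#' @param background numeric length-21 vector from [background_position_gc()];
#'   all values must be > 0.
#' @return data.frame with `position`, `site_ratio`, `upstream_ratio`,
#'   `downstream_ratio`; attributes `n_sites`, `n_upstream`, `n_downstream`.
#' @export
normalized_site_gc <- function(sites, mrnas, background) {
  if (nrow(sites) == 0L) stop("empty site list", call. = FALSE)
  if (any(background <= 0)) stop("background positions must be > 0", call. = FALSE)
  if (is.data.frame(mrnas)) mrnas <- stats::setNames(mrnas$sequence, mrnas$id)
  window <- length(background)
  if (any(sites$end - sites$start + 1L != window))
    stop("all site spans must have the window length", call. = FALSE)
  missing <- setdiff(sites$mrna_id, names(mrnas))
  if (length(missing) > 0L)
    stop("site mRNA(s) not supplied: ", paste(missing, collapse = ", "),
         call. = FALSE)

  extract <- function(shift) {
    s <- sites$start + shift
    e <- sites$end + shift
    ok <- s >= 1L & e <= nchar(mrnas[sites$mrna_id])
    substr(mrnas[sites$mrna_id[ok]], s[ok], e[ok])
  }
  gc_frac <- function(wins) {
    if (length(wins) == 0L) return(rep(NA_real_, window))
    mat <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
    colMeans(mat == "G" | mat == "C")
  }
  site_w <- extract(0L)
  up_w <- extract(-window)
  down_w <- extract(window)
  out <- data.frame(
    position = seq_len(window),
    site_ratio = gc_frac(site_w) / background,
    upstream_ratio = gc_frac(up_w) / background,
    downstream_ratio = gc_frac(down_w) / background
  )
  attr(out, "n_sites") <- length(site_w)
  attr(out, "n_upstream") <- length(up_w)
  attr(out, "n_downstream") <- length(down_w)
  out
}

#' Map a miRNA position to its paired target-site position
#'
#' Under antiparallel pairing of two 21-mers, miRNA position i (5' to 3')
#' pairs with target-site position 22 - i (5' to 3' on the mRNA); e.g. miRNA
#' position 12 pairs with target position 10. The map is an involution.
#'
#' @param i miRNA position(s), 1..21.
#' @param length duplex length (default 21).
#' @return paired target position(s).
#' @export
mirna_target_position_map <- function(i, length = 21L) {
  i <- as.integer(i)
  if (any(i < 1L | i > length)) stop("position out of range", call. = FALSE)
  (as.integer(length) + 1L) - i
}

#' Naive complementarity target-site finder
#'
#' Scans every 21-nt window of the mRNA and scores antiparallel pairing to
#' the miRNA: Watson-Crick pairs score 1, G:U wobble pairs score `wobble`
#' (default 0.5), everything else 0. The best-scoring window is returned,
#' ties broken by the smallest start. This is plumbing for pipelines without
#' psRNATarget/Tapir exports, not a reimplementation of those tools.
#'
#' @param mirna 21-nt miRNA sequence.
#' @param mrna mRNA sequence (>= 21 nt).
#' @param wobble score contribution of a G:U pair.
#' @return list with `start`, `end`, `score`, `site_sequence`.
#' @export
find_site_naive <- function(mirna, mrna, wobble = 0.5) {
  k <- nchar(mirna)
  L <- nchar(mrna)
  if (L < k) stop("mRNA shorter than the miRNA", call. = FALSE)
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  mr <- strsplit(mrna, "", fixed = TRUE)[[1]]
  pair_score <- function(b, t) {
    if ((b == "A" && t == "U") || (b == "U" && t == "A") ||
        (b == "G" && t == "C") || (b == "C" && t == "G")) return(1)
    if ((b == "G" && t == "U") || (b == "U" && t == "G")) return(wobble)
    0
  }
  # miRNA position i pairs with window offset (k - i): antiparallel geometry
  best <- list(start = NA_integer_, score = -1)
  for (s in seq_len(L - k + 1L)) {
    sc <- 0
    for (i in seq_len(k)) sc <- sc + pair_score(mi[i], mr[s + k - i])
    if (sc > best$score) best <- list(start = s, score = sc)
  }
  list(start = best$start, end = best$start + k - 1L, score = best$score,
       site_sequence = substr(mrna, best$start, best$start + k - 1L))
}
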