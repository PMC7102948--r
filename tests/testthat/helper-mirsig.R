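# Shared fixtures and small independent oracles, all built in code.

# miRBase r21 mature osa-miR528-5p, used as a printed-sequence input; its m1
# derivative replaces the G/C at positions 7 and 10 with A/U.
MIR528_WT <- "UGGAAGGGGCAUGCAGAGGAG"
MIR528_M1 <- local({
  s <- MIR528_WT
  substr(s, 7, 7) <- "A"
  substr(s, 10, 10) <- "U"
  s
})

random_rna <- function(n, length, seed = NULL) {
  f <- function() vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE), collapse = ""),
    character(1))
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

# dinucleotide multiset of a sequence (oracle for shuffle checks)
dinuc_multiset <- function(x) {
  n <- nchar(x)
  sort(substring(x, seq_len(n - 1L), 2:n))
}

# exhaustive enumeration of all character permutations (tiny n only)
all_permutations <- function(chars) {
  if (length(chars) == 1L) return(list(chars))
  do.call(c, lapply(seq_along(chars), function(i)
    lapply(all_permutations(chars[-i]), function(p) c(chars[i], p))))
}

# brute-force permutation test of a location difference (oracle for the
# Mann-Whitney comparison)
permutation_p <- function(a, b, n_perm = 10000, seed = 42) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    hits <- sum(replicate(n_perm, {
      idx <- sample.int(length(pool), na)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
    }))
    (hits + 1) / (n_perm + 1)
  })
}

# brute-force best-window complementarity scan (oracle for find_site_naive)
brute_site_scan <- function(mirna, mrna, wobble = 0.5) {
  k <- nchar(mirna)
  mi <- strsplit(mirna, "")[[1]]
  score1 <- function(b, t) {
    if ((b == "A" && t == "U") || (b == "U" && t == "A") ||
        (b == "G" && t == "C") || (b == "C" && t == "G")) 1
    else if ((b == "G" && t == "U") || (b == "U" && t == "G")) wobble
    else 0
  }
  best_s <- NA; best <- -1
  for (s in seq_len(nchar(mrna) - k + 1L)) {
    win <- strsplit(substr(mrna, s, s + k - 1L), "")[[1]]
    sc <- sum(vapply(seq_len(k), function(i) score1(mi[i], win[k + 1L - i]),
                     numeric(1)))
    if (sc > best) { best <- sc; best_s <- s }
  }
  list(start = best_s, score = best)
}
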