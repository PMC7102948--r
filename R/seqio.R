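# All internal computation is in the RNA alphabet {A,C,G,U}; DNA input is
# accepted and converted (T -> U, case folded). Coordinates are 1-based
# inclusive everywhere user-facing.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize sequences to the RNA alphabet
#'
#' Upper-cases, maps T to U, and validates that only A/C/G/U remain.
#' Ambiguity codes (N, R, Y, ...) are rejected rather than skipped because
#' positional statistics would otherwise be biased.
#'
#' @param x character vector of nucleotide sequences.
#' @param ids optional identifiers used in error messages.
#' @return character vector over \{A,C,G,U\}.
#' @export
normalize_rna <- function(x, ids = NULL) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("sequences contain characters outside {A,C,G,U/T}: ",
         paste(utils::head(lab, 5L), collapse = ", "), call. = FALSE)
  }
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of normalized RNA sequences.
#' @return character vector of reverse complements (5' to 3').
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Read a FASTA file into a sequence table
#'
#' Sequences are normalized to the RNA alphabet. The species code is parsed
#' from the identifier prefix (text before the first "-") when it looks like
#' a miRBase-style 3-4 letter code, otherwise left empty. Duplicate ids are
#' kept (miRBase mature entries can repeat across precursors) with a warning.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id`, `sequence`, `species`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      species = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- names(set)
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path, call. = FALSE)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("sequence-less FASTA record(s): ",
         paste(utils::head(ids[!nzchar(seqs)], 5L), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_rna(seqs, ids = ids)
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids kept: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sp <- sub("-.*$", "", ids)
  sp <- ifelse(grepl("^[a-zA-Z]{3,4}$", sp) & sp != ids, tolower(sp), "")
  data.frame(id = ids, sequence = unname(seqs), species = sp,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Parse a miRBase-style miRNA identifier
#'
#' Splits an identifier such as "osa-miR528-5p" into the species prefix, the
#' family ("miR" plus the first digit run, variant letters and numeric
#' sub-indices stripped, MIR case-normalized) and the arm suffix. Ids without
#' a miR-number pattern get an empty family and arm "unknown" but are kept.
#'
#' @param id character vector of identifiers.
#' @return data.frame with columns `id`, `species`, `family`, `arm`.
#' @export
parse_mirna_id <- function(id) {
  stopifnot(is.character(id), all(nzchar(id)))
  species <- ifelse(grepl("-", id, fixed = TRUE), sub("-.*$", "", id), "")
  species <- tolower(species)
  m <- regmatches(id, regexpr("[Mm][Ii][Rr]-?[0-9]+", id))
  fam <- character(length(id))
  hit <- regexpr("[Mm][Ii][Rr]-?[0-9]+", id) > 0L
  fam[hit] <- paste0("miR", sub("^[Mm][Ii][Rr]-?", "", m))
  if (any(!hit)) {
    warning("no miR-number pattern in: ",
            paste(utils::head(id[!hit], 5L), collapse = ", "), call. = FALSE)
  }
  arm <- rep("unknown", length(id))
  arm[grepl("-5p$", id)] <- "5p"
  arm[grepl("-3p$", id)] <- "3p"
  data.frame(id = id, species = species, family = fam, arm = arm,
             stringsAsFactors = FALSE)
}

#' Annotate a sequence table with parsed miRNA identifier fields
#'
#' @param records data.frame from [read_fasta()].
#' @return the same data.frame with `family` and `arm` columns added and
#'   `species` filled from the id prefix.
#' @export
as_mirna_records <- function(records) {
  p <- parse_mirna_id(records$id)
  records$species <- p$species
  records$family <- p$family
  records$arm <- p$arm
  records
}

#' Construct a precursor record with mature-arm spans
#'
#' @param id precursor identifier.
#' @param sequence precursor sequence (normalized on construction).
#' @param mature5p_span,mature3p_span 1-based inclusive `c(start, end)` or
#'   `NULL` when the arm is not annotated.
#' @param family miRNA family label.
#' @return object of class `precursor_record`.
#' @export
precursor_record <- function(id, sequence, mature5p_span = NULL,
                             mature3p_span = NULL, family = "") {
  sequence <- normalize_rna(sequence, ids = id)
  L <- nchar(sequence)
  chk <- function(sp, what) {
    if (is.null(sp)) return(NULL)
    sp <- as.integer(sp)
    if (length(sp) != 2L || sp[1] < 1L || sp[2] > L || sp[1] > sp[2])
      stop(what, " span out of bounds for ", id, call. = FALSE)
    sp
  }
  m5 <- chk(mature5p_span, "mature5p")
  m3 <- chk(mature3p_span, "mature3p")
  if (!is.null(m5) && !is.null(m3) && m5[2] >= m3[1])
    stop("5p arm must precede 3p arm in ", id, call. = FALSE)
  structure(list(id = id, sequence = sequence, length = L,
                 mature5p_span = m5, mature3p_span = m3, family = family),
            class = "precursor_record")
}

#' Extract a 1-based inclusive subsequence
#'
#' @param sequence character scalar.
#' @param span `c(start, end)`, 1-based inclusive.
#' @return the subsequence.
#' @export
span_seq <- function(sequence, span) {
  substr(sequence, span[1], span[2])
}

#' Locate a mature sequence within a precursor
#'
#' Returns the 1-based inclusive span of the first exact occurrence; if the
#' mature occurs more than once the first span is reported with an ambiguity
#' warning; if absent, `NULL`.
#'
#' @param precursor,mature normalized sequences (character scalars).
#' @return integer `c(start, end)` or `NULL`.
#' @export
locate_mature_in_precursor <- function(precursor, mature) {
  hits <- find_occurrences(mature, precursor)
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    warning("ambiguous placement: mature occurs ", length(hits),
            " times in precursor; first occurrence reported", call. = FALSE)
  }
  c(hits[1], hits[1] + nchar(mature) - 1L)
}

# All (possibly overlapping) start positions of an exact substring match.
# Sequences are plain A/C/G/U text, so the pattern needs no regex escaping.
find_occurrences <- function(pattern, subject) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Read a collapsed small-RNA read table
#'
#' Expects tab-separated `sequence<TAB>count` lines (no header). RPM is
#' count / library_total x 1e6; when `library_total` is omitted the sum of
#' counts is used. Counts must be positive integers.
#'
#' @param path TSV file.
#' @param library_total optional library size for RPM normalization.
#' @return data.frame with columns `sequence`, `count`, `rpm`, `length`.
#' @export
read_read_table <- function(path, library_total = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "character"),
                           col.names = c("sequence", "count"))
  cnt <- suppressWarnings(as.numeric(tab$count))
  bad <- is.na(cnt) | cnt != floor(cnt) | cnt < 1
  if (any(bad)) {
    stop("non-positive-integer count at line(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  reads <- data.frame(sequence = normalize_rna(tab$sequence),
                      count = as.integer(cnt), stringsAsFactors = FALSE)
  compute_rpm(reads, library_total = library_total)
}

#' Attach RPM values to a read table
#'
#' @param reads data.frame with `sequence` and `count`.
#' @param library_total optional library size; defaults to `sum(count)`.
#' @return `reads` with `rpm` and `length` columns.
#' @export
compute_rpm <- function(reads, library_total = NULL) {
  total <- if (is.null(library_total)) sum(reads$count) else library_total
  stopifnot(total > 0)
  reads$rpm <- reads$count / total * 1e6
  reads$length <- nchar(reads$sequence)
  reads
}
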