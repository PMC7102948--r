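# Conserved vs less-conserved classification of miRNA families from
# dicot/monocot co-occurrence: a family present in at least one dicot AND at
# least one monocot species is conserved; clade- or species-specific families
# are less-conserved. Species of clade "other" (mosses, algae, ...) count
# toward neither clade.

#' Default species-to-clade map for common miRBase plant codes
#'
#' Covers frequently used miRBase species prefixes; users can extend or
#' override it (e.g. from a two-column TSV via [read_clade_map()]).
#'
#' @return named character vector mapping species code to
#'   `"dicot"`, `"monocot"` or `"other"`.
#' @export
default_clade_map <- function() {
  c(
    # dicots
    ath = "dicot", aly = "dicot", gma = "dicot", mtr = "dicot",
    vvi = "dicot", stu = "dicot", ptc = "dicot", csi = "dicot",
    sly = "dicot", bna = "dicot", bra = "dicot", cme = "dicot",
    mdm = "dicot", ppe = "dicot", fve = "dicot", ghr = "dicot",
    nta = "dicot", nbe = "dicot", cca = "dicot", lja = "dicot",
    # monocots
    osa = "monocot", zma = "monocot", sbi = "monocot", tae = "monocot",
    hvu = "monocot", bdi = "monocot", ssp = "monocot", sof = "monocot",
    ata = "monocot", mac = "monocot",
    # neither (non-angiosperm lineages)
    ppt = "other", smo = "other", cre = "other", pta = "other"
  )
}

#' Read a clade map from a two-column TSV
#'
#' @param path TSV with columns `species_code` and `clade` (no header
#'   required; first two columns are used).
#' @return named character vector as in [default_clade_map()].
#' @export
read_clade_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  clade <- tolower(tab[[2]])
  bad <- !clade %in% c("dicot", "monocot", "other")
  if (any(bad)) stop("unknown clade label(s): ",
                     paste(unique(clade[bad]), collapse = ", "), call. = FALSE)
  stats::setNames(clade, tolower(tab[[1]]))
}

#' Classify miRNA families as conserved or less-conserved
#'
#' A family is conserved iff it has at least one species in each of the dicot
#' and monocot clades; each species counts once per family regardless of how
#' many paralogues it contributes. Records with an empty family are excluded
#' (with a message giving the count). Species missing from the clade map are
#' an error.
#'
#' @param records data.frame with `family` and `species` columns
#'   (see [as_mirna_records()]).
#' @param clades named character vector, see [default_clade_map()].
#' @return data.frame with one row per family: `family`, `status`
#'   (`"conserved"`/`"less_conserved"`), `n_dicot_species`,
#'   `n_monocot_species`.
#' @export
classify_families <- function(records, clades = default_clade_map()) {
  keep <- nzchar(records$family)
  if (any(!keep)) {
    message(sum(!keep), " record(s) with empty family excluded from classification")
  }
  rec <- records[keep, , drop = FALSE]
  unresolved <- setdiff(unique(rec$species), names(clades))
  if (length(unresolved) > 0L) {
    stop("species code(s) missing from clade map: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  pairs <- unique(rec[, c("family", "species")])
  pairs$clade <- unname(clades[pairs$species])
  fams <- sort(unique(pairs$family))
  nd <- vapply(fams, function(f)
    length(unique(pairs$species[pairs$family == f & pairs$clade == "dicot"])), integer(1))
  nm <- vapply(fams, function(f)
    length(unique(pairs$species[pairs$family == f & pairs$clade == "monocot"])), integer(1))
  data.frame(family = fams,
             status = ifelse(nd >= 1L & nm >= 1L, "conserved", "less_conserved"),
             n_dicot_species = nd, n_monocot_species = nm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition miRNA records by family conservation status
#'
#' @param records data.frame with a `family` column.
#' @param statuses output of [classify_families()].
#' @return list with elements `conserved` and `less_conserved`, a disjoint
#'   partition of the records with non-empty family.
#' @export
partition_records <- function(records, statuses) {
  rec <- records[nzchar(records$family), , drop = FALSE]
  cons <- statuses$family[statuses$status == "conserved"]
  list(conserved = rec[rec$family %in% cons, , drop = FALSE],
       less_conserved = rec[!rec$family %in% cons, , drop = FALSE])
}
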