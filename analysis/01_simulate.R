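#!/usr/bin/env Rscript
# Generate every synthetic input used by the downstream analysis scripts:
# signature-bearing and null 21-nt miRNA populations, a multi-species mature
# set for the conservation analysis, hairpin precursors, the four-stem
# artificial construct with its dicing read pool, and mRNAs with planted
# target sites. Everything is seeded; re-running reproduces byte-identical
# fixtures.

suppressPackageStartupMessages(library(mirsig))
SEED <- 101
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- default_signature_model()

## 21-nt populations: signature-bearing vs uniform null
sig_set <- gen_mirnas(signature_pfm(model), 2000, seed = SEED + 1)
null_set <- gen_mirnas(uniform_pfm(), 2000, seed = SEED + 2)
write_fasta(data.frame(id = sprintf("sig-%04d", seq_along(sig_set)),
                       sequence = sig_set), file.path(out, "mirnas_signature.fa"))
write_fasta(data.frame(id = sprintf("null-%04d", seq_along(null_set)),
                       sequence = null_set), file.path(out, "mirnas_null.fa"))

## multi-species mature set for the conservation analysis: families seen in
## both clades, one clade only, or one species only
species_sets <- list(
  miR156 = c("ath", "osa", "zma", "vvi"),   # both clades -> conserved
  miR528 = c("osa", "zma", "sbi"),          # monocot-specific
  miR828 = c("vvi", "ath"),                 # dicot-specific
  miR9001 = "ath"                           # species-specific
)
fam_records <- do.call(rbind, lapply(names(species_sets), function(fam) {
  sp <- species_sets[[fam]]
  data.frame(id = paste0(sp, "-", fam, "a"),
             sequence = gen_mirnas(signature_pfm(model), length(sp),
                                   seed = SEED + which(names(species_sets) == fam)),
             stringsAsFactors = FALSE)
}))
write_fasta(fam_records, file.path(out, "mirnas_by_species.fa"))

## precursors around signature matures (for the segment-GC analysis)
matures <- gen_conditioned_mirnas(200, seed = SEED + 10, model = model)
precursors <- lapply(seq_along(matures), function(i)
  gen_precursor(matures[i], arm_gc = 0.30, loop_gc = 0.30,
                seed = SEED + 100 + i, id = sprintf("prec-%03d", i)))
write_fasta(data.frame(id = vapply(precursors, `[[`, character(1), "id"),
                       sequence = vapply(precursors, `[[`, character(1), "sequence")),
            file.path(out, "precursors.fa"))
spans <- do.call(rbind, lapply(precursors, function(p)
  data.frame(id = p$id, m5_start = p$mature5p_span[1], m5_end = p$mature5p_span[2],
             m3_start = p$mature3p_span[1], m3_end = p$mature3p_span[2])))
write.table(spans, file.path(out, "precursor_spans.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## four-stem artificial construct + its dicing read pool
cs <- gen_four_stem_construct(seed = SEED + 20)
write_fasta(data.frame(id = "four-stem-construct", sequence = cs$construct),
            file.path(out, "construct.fa"))
write.table(cs$matures, file.path(out, "construct_matures.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
# per-stem pools: processing fidelity scales with signature + band status,
# emulating preferential dicing of the signature stem
fidelities <- c(gc28 = 0.15, gc52_signature = 0.8, gc52_scrambled = 0.35,
                gc71 = 0.15)
pool <- do.call(rbind, lapply(names(fidelities), function(nm) {
  gen_dicing_reads(cs$stems[[nm]], fidelity = fidelities[[nm]], n = 2500,
                   seed = SEED + 30 + match(nm, names(fidelities)))[
                     , c("sequence", "count")]
}))
pool <- aggregate(count ~ sequence, pool, sum)
write.table(pool, file.path(out, "construct_reads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

## mRNAs with planted target sites for 150 signature miRNAs
site_mirnas <- gen_conditioned_mirnas(150, seed = SEED + 40, model = model)
pieces <- lapply(seq_along(site_mirnas), function(i)
  gen_target_mrna(site_mirnas[i], mrna_length = 200, background_gc = 0.42,
                  site_position = 90, seed = SEED + 200 + i,
                  id = sprintf("mrna-%03d", i)))
write_fasta(do.call(rbind, lapply(pieces, `[[`, "mrna")),
            file.path(out, "target_mrnas.fa"))
write.table(do.call(rbind, lapply(pieces, `[[`, "site")),
            file.path(out, "target_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(data.frame(id = sprintf("site-mirna-%03d", seq_along(site_mirnas)),
                       sequence = site_mirnas),
            file.path(out, "site_mirnas.fa"))

cat("Fixtures written to", out, ":",
    paste(list.files(out), collapse = ", "), "\n")
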