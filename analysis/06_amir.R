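#!/usr/bin/env Rscript
# Signature-aware amiR workflow: rank a WMD3-style candidate list, design
# star strands, embed the best candidate in a precursor backbone, and apply
# the anthocyanin readout formula to example absorbances.

suppressPackageStartupMessages(library(mirsig))
out <- "results/amir"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- default_signature_model()

## a synthetic WMD3-style candidate list spanning GC content and signature
## status (names record the GC percentage, as designer outputs usually do)
cands <- local({
  low <- random_seq_exact_gc(21, 7, seed = 601)    # 33% GC
  mid_nosig <- NULL
  attempt <- 0
  repeat {
    cand <- random_seq_exact_gc(21, 10, seed = 610 + attempt)
    if (!evaluate_signature(cand, model)$has_signature) { mid_nosig <- cand; break }
    attempt <- attempt + 1
  }
  sig52 <- gen_conditioned_mirnas(1, seed = 602, model = model)
  high <- random_seq_exact_gc(21, 13, seed = 603)  # 62% GC
  data.frame(name = c("amiR33", "amiR47", "amiR52sig", "amiR62"),
             sequence = c(low, mid_nosig, sig52, high),
             stringsAsFactors = FALSE)
})

ranked <- rank_amirs(cands, model)
write.table(ranked, file.path(out, "ranked_candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ranked candidates:\n")
print(ranked[, c("rank", "name", "gc", "score", "in_band", "has_signature")])

## duplex + backbone embedding for the top candidate
best <- ranked$sequence[1]
duplex <- design_star(best)
backbone <- gen_precursor(gen_conditioned_mirnas(1, seed = 604, model = model),
                          seed = 605, id = "backbone")
designed <- embed_in_backbone(backbone, duplex$guide, duplex$star)
write_fasta(data.frame(id = c("amir-guide", "amir-star", designed$id),
                       sequence = c(duplex$guide, duplex$star, designed$sequence)),
            file.path(out, "designed_precursor.fa"))
cat(sprintf("embedded %s into the backbone (%d nt, 19-bp duplex, 2-nt overhangs)\n",
            ranked$name[1], designed$length))

## anthocyanin readout for example infiltration absorbances
readout <- data.frame(
  sample = c("target-alone", "plus-top-amiR", "plus-weak-amiR"),
  abs530 = c(1.10, 0.32, 0.85), abs657 = c(0.30, 0.12, 0.25),
  fresh_weight_g = 0.5)
readout$anthocyanin <- anthocyanin_content(readout$abs530, readout$abs657,
                                           readout$fresh_weight_g)
write.table(readout, file.path(out, "anthocyanin_readout.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("anthocyanin readout (per g fresh weight):\n")
print(readout)
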