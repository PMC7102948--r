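---
title: "Methods: the positional GC signature of plant miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the positional GC signature of plant miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
```

## The model

Plant DCL1 excises a ~21-nt miRNA/miRNA\* duplex from a hairpin precursor,
leaving a 19-bp paired duplex with 2-nt 3′ overhangs. Which 21-nt window of
the long hairpin becomes the miRNA is not random: abundantly processed plant
miRNAs maintain an overall GC content near 50% and a *positional* signature —
pockets of G/C at positions 8–9 and 18–19, A/U at positions 5, 7, 10 and 15,
with weaker ("loose") preferences for G/C at 2–4, 6 and 21 and A/U at 17 and
20. The HYL1/DCL1 machinery preferentially binds and processes substrates
with this composition, the star strand carries the complementary signature
shifted by the 2-nt duplex register, and the mRNA motifs targeted by
conserved miRNAs carry the reverse-complementary signature in the target
window only. `mirsig` encodes this model and the analyses around it.

The signature is **flexible**: no position is obligatory in real miRNA sets,
so the model scores matches rather than applying a consensus. A position
matches when it holds G or C at a G/C-preference position, or A or U at an
A/U-preference position. The score is

$$ s = n_\text{core} + w \cdot n_\text{loose}, \qquad w = 0.5, $$

and the boolean `has_signature` is, under the default *strict* policy, "all
8 core positions match". The strict reading is a deliberate choice: the
minimal-signature statement behind the model names exactly the 8 core
positions, but the boolean rule used to color read classes in the source
experiments is not printed, so the policy is exposed as a configuration
(`strict` or `at_least_k`) rather than hard-coded. Two further modeling
choices were genuinely open and are handled the same way:

- **Positions 2–4** show a common G/C preference but it is explicitly "not
  stringent", so they sit in the loose set (weight 0.5), not the core.
- **Position 15** appears in the canonical A/U list but not in the mutational
  series conclusion; it stays in the core by default and
  `default_signature_model(include_15_in_core = FALSE)` demotes it.

Only 21-nt sequences are in the signature's domain; other lengths are
rejected, never truncated or padded, because every positional statement is
tied to the 21-nt register. The GC band is the closed interval [0.40, 0.60].

## Composition statistics

GC content is `(#G + #C) / length` on RNA-normalized sequences (T→U, case
folded; ambiguity codes are an error rather than silently dropped, since a
skipped base would bias positional counts). Positional matrices divide the
count of each nucleotide at each position by the number of sequences
(`unique` weighting) or by total read count (`abundance` weighting —
"redundant reads"); columns sum to 1 within 1e-9. Segment GC splits a
precursor by its annotated mature spans into 5′ arm, 5p mature, loop, 3p
mature and 3′ arm; a zero-length segment reports `NA`, never 0, so segment
means are not dragged down by degenerate loops. Distribution comparisons use
the two-sided Mann–Whitney U test with tie correction via
`stats::wilcox.test`; the null distribution is not re-derived here.

## Null constructions and their caveats

Two controls distinguish a genuine positional preference from base
composition:

1. **Random subsampling** (`random_sample_control`): a uniform subset of a
   biased set keeps the bias.
2. **Dinucleotide-preserving shuffle** (`dinucleotide_shuffle`): each
   sequence is rewritten as a uniformly random Eulerian path over its
   dinucleotide multigraph (random last-edge arborescence + uniform
   permutation of remaining out-edges, which by the BEST theorem gives a
   uniform draw over all dinucleotide-preserving arrangements). This
   preserves mononucleotide and dinucleotide composition exactly, so any
   surviving positional structure would indicate the statistic is driven by
   composition, not position.

A property of *any* dinucleotide-preserving shuffle worth stating explicitly:
the first and last nucleotide are fixed (they are the endpoints of the Euler
path), and the composition of positions 2 and L−1 is pinned by the preserved
multiset — position 2 is a uniform draw from the successors of the fixed
first base. When position 1 is U-biased and U-successors are G/C-rich, the
shuffled position 2 stays G/C-rich *by construction*. The positional-null
check (`shuffle_null_track`) therefore evaluates interior positions 3..L−2
against their own mean, with a binomial standard error at the set size; the
terminal margin carries no information about the null and is excluded. On a
signature-bearing set of 5,000 sequences the interior track stays within 3
SE of flat while the unshuffled set deviates by tens of SE at core positions.

## Target-site analysis

Under antiparallel pairing of two 21-mers, miRNA position $i$ faces target
position $22 - i$ (an involution; miRNA 12 ↔ target 10). Site GC tracks are
normalized by a background of random 21-nt cDNA windows, drawn uniformly
over all (sequence, start) pairs — 10,000 windows by default, with a
recorded seed, since the appropriate n is not prescribed anywhere. The
normalization is a plain per-position ratio (no log transform), matching the
"divide by position-specific GC of random cDNA windows" definition. Adjacent
windows (spans shifted ±21 nt) are computed alongside as the no-signal
control; sites too close to an mRNA end simply drop out of the adjacent
window denominators. The naive site finder is plumbing for pipelines without
psRNATarget/Tapir exports: it maximizes Watson–Crick matches with G:U wobble
scoring 0.5 (common plant-target practice, configurable) and breaks ties at
the smallest start. It makes no claim to reproduce dedicated predictors'
expectation scores or energy models.

## Read quantification

Mapping is exact (no mismatches or gaps), forward-strand by default (reads
derive from the expressed hairpin), reporting *every* occurrence, including
overlapping ones; reads are pre-filtered to 16–35 nt. The RPM display filter
is strictly greater than 5. Class summaries count each read once per class
by sequence even when it has several placements, so shared-backbone reads
are not double-counted across repeated stems. The classes nest by
construction: band∧signature (21-nt only, since the signature domain is
21 nt) ⊆ GC band (any length) and 21-nt ⊆ 21–24-nt; per-size RPM over
21–24 nt sums to the all-class total. Both RPM-weighted and unique-sequence
counts are emitted, since bar-level summaries can be read either way.

## amiR design

`design_star` applies the canonical duplex geometry: star positions 1..19
are the reverse complement of guide positions 1..19 (pairing map guide $i$ ↔
star $20 - i$), positions 20–21 of both strands are the 2-nt 3′ overhangs.
The star overhang defaults to `"UU"`; in real designer output the unpaired
bases come from backbone context, so the parameter is exposed. Embedding
replaces the two annotated mature spans of a backbone byte-for-byte (no
indel surgery). The ranking — GC band first, then signature score, then
|GC − 0.5|, then 5′-U (AGO1 loading), then lexicographic — is this package's
own synthesis of the qualitative conclusions that band and signature
dominate amiR accumulation; the source experiments rank candidates by
inspection, so the keys are documented and every key column is returned for
users who weight differently. Secondary-structure verification of designed
precursors is out of scope. The anthocyanin readout implements
$[A_{530} - 0.25 A_{657}] \times 5$ per gram fresh weight.

## What the generators emulate — and what they do not

The synthetic module supplies every input at desk scale:

- `gen_mirnas` samples positions independently from a positional matrix;
  `signature_pfm` places 0.8 on the preferred pair at core positions, 0.65
  at loose positions, a 0.6 U-bias at position 1 and uniform elsewhere.
  The 0.8/0.65 levels mirror the observation that core positions in
  abundant conserved reads are G/C-enriched to ~80%, with loose pockets
  clearly weaker; 0.6 reflects the strong but not absolute 5′-U rule. The
  implied mean GC is ≈0.51, inside the band.
- `gen_precursor` builds arm5 + mature + loop + star + arm3 with i.i.d.
  arms/loop at 30% GC (plant precursor arms are AU-rich) and records spans
  exactly. Arm and loop lengths default to 40 nt, inside the short-loop
  regime associated with abundant processing.
- `gen_dicing_reads` mixes canonical mature/star reads (probability =
  `fidelity`) with isomiRs/sib-miRs (boundary-offset or uniform starts;
  lengths 20/21/22/24 at 0.15/0.55/0.15/0.15). Draws colliding with a
  canonical sequence are resampled so the planted fidelity is exact.
- `gen_target_mrna` plants the exact reverse complement (optionally broken
  at chosen positions with non-pairing, non-wobble bases) in an i.i.d.
  background at 42% GC, a typical cDNA level.
- `gen_four_stem_construct` rebuilds the four-stem reporter: one backbone,
  four inserts at 28%, 52%-with-signature, 52%-scrambled (same letters,
  core destroyed — the published construct's scramble rule is not printed,
  so a composition-preserving permutation is used) and 71% GC.

Deliberate simplifications: sampling is position-independent (no
dinucleotide model — the analyses measure positional marginals, and the
shuffle control exercises dinucleotide structure on real inputs); star
variants from asymmetric bulges are modeled only through the length
distribution, not structure; there is no folding, expression or
sequencing-error model. Consequently, passing tests demonstrate that the
*statistics* recover planted *compositional* structure at the stated sample
sizes — they do not validate secondary-structure-dependent claims, and real
miRBase/degradome data will show correlated positions and length
heterogeneity the generators do not produce.

## Numerical choices and problem sizes

All user-facing coordinates are 1-based inclusive. Degenerate inputs follow
one rule: undefined is reported as missing (`NA`), never as zero. Determinism
is everywhere: every stochastic function takes a seed and scopes it with
`withr::with_seed`, so a fixed master seed reproduces byte-identical outputs.
The standard analysis sizes — 10,000 sequences for matrix recovery (per-cell
binomial SE ≤ 0.005), 5,000 for the shuffle null (3 SE ≈ 0.021 on the GC
track), 500 precursors/sites for segment and ratio recovery, 100 random
pools for class-nesting checks — were chosen so each estimate's sampling
error sits comfortably inside the tolerance being asserted. The conservation
module ships a default clade map for common miRBase plant codes; it is a
convenience list, not a census, and analyses of figure-level species counts
from the original study are out of scope because the underlying species
lists are not published in the text.
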