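---
title: "Methods: prioritizing regulatory GWAS variants by cell-type-preferential chromatin"
author: "enhpro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing regulatory GWAS variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Most trait-associated SNPs from GWAS fall outside coding sequence, and at
any associated locus the lead ("index") SNP is statistically
interchangeable with its linkage-disequilibrium neighbours. `enhpro`
implements a prioritization cascade for the hypothesis that a causal
variant acts by altering transcription-factor binding in a *cis*-regulatory
element active in a disease-relevant ("focal") cell type — here
osteoblasts (`ostb`) for bone mineral density, though every cell-type name
is a parameter. The cascade is a conjunction of orthogonal evidence
filters:

1. **Association.** Index SNPs are read from a GWAS association table at
   genome-wide significance (`gwas_p_threshold`, default `5e-8`). Imputed
   summary-statistic SNPs enter later, at per-trait thresholds (default
   `6.6e-9` for the ultrasound-estimated-BMD trait), and only around genes
   that have already been prioritized.
2. **LD expansion.** Each index SNP is expanded to proxies with
   `r² ≥ 0.8` computed from a genotype panel (VCF). `r² = D²/(pA pa pB pb)`
   with `D = pAB − pA·pB`. For phased panels haplotype frequencies are
   exact counts; for unphased panels they are maximum-likelihood estimates
   from the standard two-locus EM in which only the double-heterozygote
   class is ambiguous.
3. **EnhPro chromatin filter.** A SNP is an *EnhPro SNP* when it (a) lies
   in strong promoter (state 1) or strong enhancer (states 3/8/9)
   chromatin of an 18-state segmentation in the focal cell type, shared by
   at most `state_max_other` (default 3) of the 12 comparison cell
   cultures; (b) overlaps a focal H3K27ac narrowPeak shared by at most
   `k27ac_max_other` comparison types (default 3; the *relaxed* protocol
   raises only this counter to 4); and (c) overlaps a focal DNaseI
   hypersensitive site. Preferential occupancy — not mere presence — is
   what restricts the signal to the focal lineage.
4. **Gene prioritization.** EnhPro SNPs are linked to their reported genes
   (nearest-TSS fallback). A linked gene becomes a candidate if it is
   preferentially expressed in the focal cell type (focal RPKM / median
   RPKM over 11 heterologous cultures `> 5`, focal RPKM `> 1`) or appears
   on a curated relevance list, which stands in for a gene-ontology
   screen.
5. **Allele-specific TFBS.** For each EnhPro SNP linked to a candidate
   gene, the 21-base window centred on the SNP is scanned on both strands
   against a PWM collection at every placement covering the SNP. A call is
   allele-specific when the PWM probability of the two allele bases at the
   SNP-aligned position differs more than fivefold, the favoured allele's
   sequence survives curation (below), and the matching TF is expressed in
   the focal cell type (RPKM `≥ 0.8`). SNPs with at least one surviving
   call are *Tier-1* — the final report mirrors the conventional
   per-gene table (source class, signed distance to TSS in kb, alleles,
   chromatin label, predicted TFs per allele).

### Curation rules

A placement passes curation iff (a) every *conserved* PWM position (top
base probability `≥ conserved_prob_min`, default 0.85) matches its top
base exactly; (b) at most one *partly conserved* position (top probability
`≥ 0.5`) carries a partial match — a non-top base with probability at
least `partial_match_min_frac` (default 0.2) of the position's top
probability; and (c) no position at all carries a base below that
fraction. The source protocol describes these rules qualitatively; the
clause structure above is one consistent formalization, and all three
thresholds are exposed in the configuration rather than asserted as the
only reading. Raising `partial_match_min_frac` is provably monotone (it
can only turn passes into failures), which the test suite asserts.

### Conventions and numerical choices

- **Coordinates.** BED tracks are 0-based half-open; variants are 1-based
  (VCF). A variant at position `p` overlaps `[s, e)` iff `s ≤ p−1 < e`.
- **SNVs only.** Indels and multi-allelic records are dropped with a
  logged count; the allele-swap scoring model is defined for single-base
  substitutions.
- **EM details.** Initialization at linkage equilibrium nudged towards
  positive `D` (a 1e-3-scaled perturbation), tolerance `1e-8`, at most
  1000 iterations, pairwise-complete deletion of missing calls. The nudge
  makes the estimator deterministic when the likelihood has two symmetric
  optima (e.g. a panel of double heterozygotes): the `D ≥ 0` solution is
  returned. Haplotype frequencies are always computable and returned; r²
  itself raises an undefined-LD error at fixed margins, and such pairs are
  skipped during proxy expansion.
- **Proxy bookkeeping.** A site proxying several index SNPs keeps the
  largest-r² link; sites that are themselves index SNPs stay index
  records. The proxy search window is ±500 kb, chosen to cover the
  largest observed SNP-to-TSS distances with margin.
- **PWM pseudocount.** 0.01 per count cell before normalization, so
  fold changes stay finite while near-delta columns still discriminate
  well beyond fivefold.
- **Ties in the scanner.** Placements are ordered by the favoured
  allele's log-probability sum; ties break to the `+` strand, then the
  smaller offset. Minus-strand offsets are expressed in
  reverse-complemented window coordinates; because windows are odd, the
  SNP stays at the centre.
- **Chromatin display label.** "Str enh/prom" is assigned when strong
  promoter and strong enhancer segments both occur within a 200-bp
  neighbourhood of the SNP (`state_label_window_bp`); otherwise the label
  reflects the single strong state family present.
- **Imputed-locus buffer.** Imputed SNPs are collected within ±500 kb of
  candidate gene spans (`imputed_locus_buffer_bp`).
- **Degenerate inputs.** Empty association tables produce an empty report
  and zero stage counts rather than an error; contigs absent from a track
  count as non-overlapping; expression rows with missing values are
  excluded with a logged count.

### Two sharing counters

The protocol text ties the "no more than three of the 12" rule to the
regulatory-chromatin overlap, and the relaxed variant raises a sharing
cap specifically for H3K27ac peaks. Whether the original strict pass also
capped H3K27ac sharing cannot be determined from the text, so the package
keeps two independent counters (`state_max_other`, `k27ac_max_other`),
both defaulting to 3, with the relaxed mode raising only the H3K27ac one
to 4. This single contract reproduces both the strict and the relaxed
behaviour. DHS is required in the focal cell type only; there is no DHS
sharing counter.

## The synthetic-data generator

`simulate_bundle()` writes a complete input bundle whose statistical
structure matches what the cascade assumes, at desk scale (defaults:
three 600-kb contigs, 60 phased samples, ~2,400 background panel SNPs, 13
cell types, 50 genes, 24 PWMs):

- **LD blocks.** Haplotypes follow a block-mosaic model: within each
  50-kb block every haplotype copies one of 4 founder haplotypes, and at
  each block boundary it redraws its founder with probability 0.9. This
  yields high within-block r² (so planted index SNPs attract proxies) and
  near-zero between-block r², which the test suite asserts as a ≥10-fold
  separation of mean r².
- **Chromatin.** Segmentations are quiescent filler (state 15) except for
  strong segments planted around signal SNPs, shared with a controlled
  number of comparison cell types; H3K27ac and DHS narrowPeaks are nested
  inside the focal strong segments. Comparison-only decoy segments are
  scattered away from planted SNPs.
- **Expression.** Log-normal background RPKM (`meanlog 0, sdlog 1.5`,
  a long-tailed shape typical of RPKM tables) with planted focal-enriched
  genes (focal 50 vs. comparison values in [0.5, 2], i.e. ratio safely
  above 5) and a non-preferential planted gene (ratio ≈ 3).
- **PWMs.** One engineered PWM per planted SNP: conserved flanks matching
  the genome, and a centre column realizing the intended fold change (10
  for true signals, 4.2 for the below-threshold decoy). Extra background
  PWMs have no planted target.
- **Planted truth.** Twelve defect-free SNPs must reach Tier-1; nine
  decoys each fail exactly one criterion (p-value above threshold, r²
  below threshold, missing DHS, over-shared chromatin, over-shared
  H3K27ac, non-preferential gene, sub-fivefold PWM column, unexpressed
  TF, curation failure) and carry the stage at which the pipeline must
  reject them. Truth labels are a sidecar TSV the pipeline never reads.

Because PWM collisions across planted windows are possible under an
arbitrary seed, the generator *verifies its own construction*: it scans
every planted SNP against the full PWM collection and re-rolls only that
SNP's flanking sequence (never the centre base, never a threshold) on the
rare collision, so the planted truth is realized exactly for any seed.
The low-LD decoy's genotype column is likewise checked against its index
partner and regenerated until r² < 0.3.

What the generator does **not** emulate: genome-scale SNP counts (tens of
thousands), realistic allele-frequency spectra or population structure,
segmentation-state grammar beyond strong-vs-quiescent, inter-gene
expression correlation, and TF motif families with overlapping binding
preferences. Passing the planted-recovery test therefore demonstrates
that the cascade's logic and bookkeeping are correct, not that its
thresholds are well-calibrated for real data.

## The benchmark fixture

`make_table1_fixture()` encodes the published 14-SNP / five-gene outcome
as a deterministic miniature genome: five 500-kb contigs carrying gene
models for BICC1, NPR3, LGR4, HMGA2 and DAAM2, with the 14 SNPs placed at
offsets reproducing the printed distance-to-TSS values and evidence
constructed to match each row — including HMGA2 entering via the curated
list rather than preferential expression, the three imputed-only SNPs
entering through imputed tables at their per-trait thresholds, and the
DAAM2 cluster sharing H3K27ac with exactly 4 comparison types so that it
appears only under the relaxed protocol. Decoy SNPs failing exactly one
criterion each are included and must never be reported. An internal fixed
seed makes repeated builds byte-identical.

## Problem sizes and determinism

The test suite and the acceptance script run the fixture (17 candidate
SNPs end to end) and the default synthetic genome (~2,400 panel SNPs, 21
planted signals); property checks use 200 random window/PWM pairs, 1,000
random interval queries, and 20-sample EM panels against a grid-search
likelihood oracle with step 1e-3. Identical inputs and configuration
produce byte-identical reports and stage-count JSON, which is asserted
directly.

## Known limitations

- The curation clauses are one formalization of a manually applied
  protocol; alternative readings would shift borderline calls.
- TRANSFAC's proprietary position-conservation classes are approximated
  by thresholds on the top-base probability (0.85 / 0.5), exposed in the
  configuration.
- The fivefold rule reads a single PWM position, not a full-window score
  difference; cooperative binding, DNA shape and methylation sensitivity
  are out of scope.
- Fine-mapping (posterior-probability integration over LD blocks) is
  intentionally not reimplemented; the package's scope ends at the Tier-1
  report.
- No liftover, remote fetching, or bigWig/bigBed support; inputs are
  plain-text standard formats.
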