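---
title: "riboquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboquant)
```

## What the package computes

`riboquant` quantifies translation from ribosome profiling (Ribo-Seq) of a
recombinant CHO cell line expressing an IgG (heavy chain, light chain) and a
NeoR selection marker, alongside matched RNA-Seq and batch-culture data. The
chain of computation is:

1. **End counting.** Every aligned footprint is reduced to the ribosome's 5'
   end in mRNA orientation: the lowest genomic coordinate of the alignment
   for genes on the plus strand, the highest for genes on the minus strand.
   The alignment's own strand flag is deliberately ignored — the *gene's*
   strand governs the rule. Counts are accumulated per nucleotide of each
   gene's representative transcript (the transcript with the longest CDS;
   ties break to the lexicographically smallest transcript id), separately
   per read length.
2. **A-site calibration.** Footprint length varies (default filter 25–35 nt,
   motivated by the ~30 nt protected fragment), and each length implies a
   different distance between the counted 5' end and the ribosomal A site.
   For each length the offset is the candidate `d` in a 12–18 nt window that
   maximises the summed end count at (start codon − d) across genes. This
   works because initiating ribosomes pile up on the start codon, so 5' ends
   of reads decoding the initiator sit exactly one offset upstream of it.
   Ties go to the smallest `d`; lengths with fewer than 10 end counts in the
   window inherit the modal offset and are flagged low-confidence.
3. **Periodicity.** After shifting each end by its offset, occupancy in the
   CDS is split by codon sub-position; `f0` is the fraction on the first
   nucleotide of codons (≈0.70 in this kind of data).
4. **Metagene profiles.** Per gene, the median codon coverage is computed
   after discarding the first 15 and last 10 codons (initiation/termination
   pile-ups would otherwise inflate it); genes need > 25 codons and a
   positive median in at least one replicate. Coverage near the start or
   stop codon is divided by one third of that median, so a uniformly
   translated CDS sits at 1, and the across-gene median is reported per
   position. Positions outside a gene's transcript are absent (`NA`), never
   zero — zero-filling would deflate the median for genes with short UTRs.
5. **Quantification.** Gene counts are occupancy sums over the CDS (Ribo)
   or the spliced transcript (RNA). `rpm` divides by the retained library
   size; `tpm` length-normalises (CDS length for Ribo, transcript length
   for RNA) and rescales to a million. Translation efficiency is the
   Ribo/RNA tpm ratio, flagged undefined (not zeroed) when RNA tpm is 0.
6. **Category occupancy.** For treemap-style summaries, each gene's rpm is
   split *evenly* across its homolog ids and summed by functional category;
   unmapped genes go to an explicit `unmapped` bucket so the total is
   conserved exactly.
7. **Statistics.** Log2 fold changes with a 0.5 rpm pseudocount; classical
   two-tailed two-sample t tests for category fractions; a deviation test
   for single-gene TE against the endogenous distribution; BH FDR; weighted
   pre-ranked gene-set enrichment with a random-set permutation null; and
   ∆∆Ct fold changes for qPCR validation.
8. **Bioprocess metrics.** Specific growth rate µ is the slope of ln(VCD)
   versus time in a phase window; specific productivity q~p~ is the slope
   of titer versus integral viable cell density (trapezoidal), × 10^6^ to
   convert µg/cell/day to pg/cell/day. Both a pooled-replicate regression
   and per-replicate slopes (mean ± SD) are available, since either
   convention is common.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| footprint length filter | 25–35 nt | ribosomes protect ~30 nt |
| offset candidate window | 12–18 nt | standard 5'-end-to-A-site geometry for ~30 nt fragments |
| calibration signal floor | 10 end counts | below this the per-length argmax is noise |
| metagene codon trim | 15 start / 10 stop codons | excludes initiation/termination pile-ups from the normaliser |
| metagene windows | −30..+60 (start), −60..+30 (stop) nt | covers the visible UTR/CDS transition |
| fold-change pseudocount | 0.5 rpm | keeps zeros finite without dominating expressed genes |
| GSEA weight | 1 | classic weighted statistic; 0 gives the unweighted KS form |
| GSEA FDR flag | 0.25 | conventional exploratory threshold for permutation FDR |
| TE floor | 0 (RNA tpm > 0) | raise to suppress ratio instability at low expression |

Anchor conventions: metagene position 0 is the first nucleotide of the CDS
at the start anchor and the *last* nucleotide of the CDS at the stop anchor,
so positions > 0 at the stop anchor are 3'UTR. Whether the CDS includes the
stop codon is taken from the annotation file and recorded
(`attr(ann, "stop_codon_convention")`); both GTF dialects parse.

## The synthetic world

The generator (`sim_config()`, `simulate_*()`) emulates the study design so
every stage is testable without external data: a small genome with 5
endogenous genes (both strands) plus the three transgenes on a dedicated
vector contig; footprints with per-length offsets (12–16 nt for lengths
28–32), frame probabilities (0.70, 0.15, 0.15), and recombinant mRNAs at
~20% of truth tpm (heavy/light/NeoR split 0.50/0.20/0.30, matching the
regime where recombinant message dominates the transcriptome); RNA-Seq
coverage uniform over the whole transcript; and a two-phase batch culture
seeded at 3×10^5^ cells/mL with µ = 0.65 → 0.10 day^−1^ and q~p~ = 16 → 5.5
pg/cell/day, sampled daily over 7 days in triplicate with 3% multiplicative
noise.

Choices the generator makes that real data would not hand you:

* **Initiation peak.** 8% of a gene's footprints decode the initiator codon
  (`start_peak`). Without it, the end count at (start − d) is a handful of
  reads per length at desk-scale depth and exact offset recovery is not
  robust; the peak is also what start-anchored calibration exploits in real
  cycloheximide-arrested libraries.
* **5'UTR boost.** Transgenes receive an extra 10% of reads with A sites
  uniform in the 5'UTR, reproducing the elevated 5'UTR occupancy seen on
  recombinant messages; endogenous genes get none, and no simulated
  footprint ever touches a 3'UTR.
* **Titer integration.** Titer accumulates as q~p~ × the trapezoidal IVCD
  increment of the *sampled daily grid*, with the phase's q~p~ applied per
  daily increment. This makes "zero noise → exact q~p~ recovery" an
  algebraic identity of the estimator, which is the correct oracle for a
  regression-based definition of q~p~.
* **Expression truth** is a flat Dirichlet draw over endogenous genes —
  heavy-tailed like a real transcriptome. A consequence worth knowing: at
  low sequencing depth the minimum-expression gene receives very few reads,
  and rank correlations of TE against truth degrade for sampling (not
  estimator) reasons. The quantification-fidelity acceptance check is
  therefore run at ~4300 reads/gene average, well above its 200/gene floor.

What a green test does **not** establish: the generator has no sequencing
errors, no rRNA contamination, no codon-level dwell heterogeneity, no
multimapping ambiguity and no isoform mixture, so passing tests certify the
estimators' correctness on clean geometry, not robustness to those
artefacts.

## Numerical and design choices

* Internal coordinates are 0-based half-open; GTF/GFF3 (1-based closed) are
  converted on read. All medians are `stats::median` (even counts → mean of
  the two midpoints).
* `apply_offsets` conserves mass exactly except for ends shifted past the
  transcript boundary, which are dropped and counted in `attr(x,
  "dropped")`.
* Reads are assigned by their single counted end; a read whose end lies in
  two overlapping genes counts once for each, reported as ambiguous —
  transparency over silent loss.
* The rpm denominator is all retained reads (post length filter, pre gene
  assignment).
* The TE deviation test standardises log2 TE against the endogenous sample
  and uses a t reference with n−1 df. It is a one-value-versus-sample test;
  with n ≥ 30 the neglected √(1+1/n) inflation shifts the level by < 0.3%,
  verified by null simulation in the test suite.
* The weighted pre-ranked ES null is *not* centred at zero: with
  expression-like (positive, heavy-tailed) scores the random-set null mean
  measured +0.42 here. This is inherent to the weighted statistic and is why
  the reference implementation reports a sign-normalised NES. The
  null-centring acceptance check therefore uses the unweighted statistic
  (`weight = 0`), whose null is location-free; `weight = 1` stays the
  analysis default and its permutation p values are computed two-sided
  against |ES|.
* Degenerate t-test inputs (zero variance on both sides) are answered
  explicitly: p = 1 when the means agree, a flagged p = 0 otherwise, rather
  than propagating an error from the generic t machinery.
* q~p~ regression: pooled replicates by default; per-replicate slopes
  averaged as the alternative, since published figures are frequently one
  or the other and the package does not guess.

## Known limitations

* Offsets are aggregated across genes (one offset per length), which is the
  standard and what the data support at desk scale; per-gene offsets are out
  of scope.
* Multi-mapping resolution, UMI deduplication, and isoform-level TE are out
  of scope; the aligner is trusted upstream.
* `category_occupancy` is quadratic in gene count in its current form;
  adequate for the ~10^1^–10^4^ genes it is used with here.
* The enrichment module permutes gene sets, not phenotypes, which is the
  correct null for a pre-ranked list but cannot capture inter-gene
  correlation within samples.
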