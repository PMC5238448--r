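# riboquant

Ribosome-profiling quantification for recombinant CHO cell lines.

## The problem

Industrial CHO cell lines divert a large share of their translation
machinery to recombinant messages — the product (IgG heavy and light chain)
and leftover selection markers such as NeoR. Ribosome profiling (Ribo-Seq)
sequences the ~30 nt mRNA fragments protected by translating ribosomes and,
combined with RNA-Seq, answers questions RNA abundance alone cannot: how
efficiently is each message translated, how is ribosomal occupancy
distributed across cellular processes, and how do those quantities track
bioprocess performance (growth rate, specific productivity) across culture
phases?

`riboquant` implements that analysis as a tested, reusable R pipeline, for
bioprocess and translatomics groups working with aligned reads (SAM/BAM), a
transcript annotation (GTF/GFF3), a gene→homolog→category table, gene sets
(GMT), and daily culture records.

## The method in brief

* **Strand-aware end counting.** Each footprint is reduced to the
  ribosome's 5' end in mRNA orientation: the read's 5' genomic end for
  plus-strand genes, its 3' genomic end for minus-strand genes. Counts land
  on the representative transcript (longest CDS) of each gene, per read
  length.
* **A-site calibration.** For each read length *L* the offset
  *d(L)* ∈ [12, 18] maximises end counts at (start codon − *d*), exploiting
  the initiation pile-up; occupancy is then shifted so each count sits on
  the first nucleotide of the A-site codon.
* **Codon periodicity.** *f*ₖ = (coverage at CDS positions ≡ *k* mod 3) /
  (total CDS coverage).
* **Metagene profiles.** Per-gene coverage around the start/stop codon is
  normalized by ⅓ of the gene's median codon coverage (codons 16..*N*−10),
  and the across-gene median is reported per position.
* **Quantification.** rpm = count × 10⁶ / library size;
  tpm = 10⁶ · (countᵍ/lengthᵍ) / Σ(count/length); translation efficiency
  TE = ribo-tpm / RNA-tpm. Category occupancy splits each gene's rpm evenly
  across homologs before summing by category.
* **Statistics.** log₂ fold changes (pseudocount 0.5 rpm), two-tailed t
  tests, a TE deviation test (standardised log₂ TE against the endogenous
  distribution, t with *n*−1 df), BH FDR, weighted pre-ranked gene-set
  enrichment with a permutation null, ∆∆Ct.
* **Bioprocess.** µ = slope of ln VCD vs time; qₚ = slope of titer vs
  integral viable cell density (pg/cell/day).

A synthetic-data module (`sim_config()`, `simulate_transcriptome()`,
`simulate_ribo_reads()`, `simulate_rna_reads()`, `simulate_culture()`,
`simulate_category_map()`) generates a toy genome with the three
transgenes, read libraries with a known truth table, and two-phase culture
series, so the whole pipeline is testable offline. See
`vignettes/riboquant-methods.Rmd` for the full methods account.

## Worked example

```r
library(riboquant)

cfg  <- sim_config(seed = 1)                       # the default simulated world
sim  <- simulate_transcriptome(cfg, dir = tempfile())
ribo <- simulate_ribo_reads(sim)
rna  <- simulate_rna_reads(sim)

prof <- build_end_profiles(read_alignments(ribo$sam), sim$annotation, c(25, 35))
(off <- estimate_offsets(prof, sim$annotation))
#>   length offset confidence window_count
#> 1     28     12         ok          128
#> 2     29     13         ok          263
#> 3     30     14         ok          662
#> 4     31     15         ok          353
#> 5     32     16         ok          171
```

The estimated offset per read length equals the simulator's truth (12–16 nt
for lengths 28–32). Shifted occupancy shows the expected reading-frame bias:

```r
tracks <- apply_offsets(prof, off)
round(pooled_periodicity(tracks, sim$annotation), 3)
#>    f0    f1    f2
#> 0.696 0.151 0.153
```

≈70% of calibrated footprints sit on the first codon nucleotide, as
configured. Gene-level quantification and translation efficiency:

```r
nprof   <- build_end_profiles(read_alignments(rna$sam), sim$annotation, NULL)
ntracks <- apply_offsets(nprof, data.frame(length = 36L, offset = 0L))
qr <- quantify_genes(tracks,  sim$annotation, library_stats(prof)$retained_reads,  "ribo")
qn <- quantify_genes(ntracks, sim$annotation, library_stats(nprof)$retained_reads, "rna")
qr$te <- translation_efficiency(qr$tpm, qn$tpm[match(qr$gene_id, qn$gene_id)])$te
qr[order(-qr$rpm), c("gene_id", "count", "rpm", "tpm", "te")]
#>  gene_id count    rpm    tpm   te
#>   gene01  6606 323253 336838 1.00
#>   gene02  4849 237277 285134 0.97
#>   gene03  2843 139117 106580 1.16
#>   IgG_HC  2370 115972  73536 0.74
#>     NeoR  1355  66305  74008 1.23
#>   gene05   867  42425  61978 1.32
#>   gene04   483  23635  23018 0.83
```

The three transgenes hold 21.8% of the footprint rpm in this draw (the
simulator places recombinant mRNA at ~20% of the transcriptome), and their
TE sits inside the endogenous range — the recombinant messages are
translated about as efficiently as the host's. Bioprocess metrics from the
matching culture simulation:

```r
cs <- simulate_culture(cfg)
specific_growth_rate(cs, c(1, 4), replicate = 1)   # 0.669 /day (truth 0.65)
specific_productivity(cs, c(1, 4))$qp              # 15.5 pg/cell/day (truth 16)
specific_productivity(cs, c(5, 7))$qp              #  5.6 pg/cell/day (truth 5.5)
```

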