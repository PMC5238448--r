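# Shared fixtures, memoised so expensive simulations run once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# the default simulated world: 5 endogenous genes + 3 transgenes, 20k RPFs
default_sim <- function() memo("default_sim", {
  cfg <- sim_config(seed = 42L)
  sim <- simulate_transcriptome(cfg, dir = file.path(tempdir(), "fix_sim"))
  ribo <- simulate_ribo_reads(sim)
  rna <- simulate_rna_reads(sim)
  list(cfg = cfg, sim = sim, ribo = ribo, rna = rna)
})

# ribo end profiles + calibrated tracks for the default world
default_tracks <- function() memo("default_tracks", {
  fx <- default_sim()
  reads <- read_alignments(fx$ribo$sam)
  prof <- build_end_profiles(reads, fx$sim$annotation, c(25L, 35L))
  off <- estimate_offsets(prof, fx$sim$annotation)
  list(reads = reads, prof = prof, off = off,
       tracks = apply_offsets(prof, off))
})

default_rna_tracks <- function() memo("default_rna_tracks", {
  fx <- default_sim()
  reads <- read_alignments(fx$rna$sam)
  prof <- build_end_profiles(reads, fx$sim$annotation, NULL)
  lens <- sort(unique(unlist(lapply(prof, function(p) as.integer(names(p$counts))))))
  list(reads = reads, prof = prof,
       tracks = apply_offsets(prof, data.frame(length = lens, offset = 0L)))
})

transgenes <- c("IgG_HC", "IgG_LC", "NeoR")

# single-exon toy transcript: utr5 | cds | utr3 on either strand
toy_tx <- function(utr5 = 6L, n_codons = 4L, utr3 = 6L, strand = "+",
                   gstart = 100L, id = "t1", gene = "g1") {
  len <- utr5 + 3L * n_codons + utr3
  if (strand == "+")
    transcript_model(id, gene, "chr", "+", gstart, gstart + len,
                     gstart + utr5, gstart + utr5 + 3L * n_codons)
  else
    transcript_model(id, gene, "chr", "-", gstart, gstart + len,
                     gstart + utr3, gstart + utr3 + 3L * n_codons)
}

# a bare occupancy track for a transcript model
toy_track <- function(t, counts) {
  stopifnot(length(counts) == t$tx_length)
  list(transcript_id = t$transcript_id, gene_id = t$gene_id,
       tx_length = t$tx_length, counts = counts)
}

# write a one-or-more-gene toy GTF; genes: list of lists with fields
# gene, tx, contig, strand, exons (matrix 1-based closed), cds (same)
write_toy_gtf <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- character(0)
  for (g in genes) {
    att <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene, g$tx)
    for (i in seq_len(nrow(g$exons)))
      lines <- c(lines, sprintf("%s\tsrc\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$contig, g$exons[i, 1], g$exons[i, 2],
                                g$strand, att))
    if (!is.null(g$cds))
      for (i in seq_len(nrow(g$cds)))
        lines <- c(lines, sprintf("%s\tsrc\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  g$contig, g$cds[i, 1], g$cds[i, 2],
                                  g$strand, att))
  }
  writeLines(lines, path)
  path
}

# Independent brute-force oracles -----------------------------------------

# per-gene CDS count straight from the simulator's per-read truth table
oracle_cds_count <- function(truth_reads, gene) {
  sum(truth_reads$gene_id == gene & truth_reads$region == "cds")
}

# frame fractions from the truth A-site coordinates of one gene
oracle_frame <- function(truth_reads, gene, utr5 = 60L) {
  a <- truth_reads$a_site[truth_reads$gene_id == gene &
                          truth_reads$region == "cds"]
  f <- (a - utr5) %% 3L
  c(f0 = mean(f == 0L), f1 = mean(f == 1L), f2 = mean(f == 2L))
}
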