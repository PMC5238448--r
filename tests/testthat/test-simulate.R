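test_that("transcriptome simulation is deterministic and well formed", {
  cfg <- sim_config(seed = 101L)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_transcriptome(cfg, d1)
  s2 <- simulate_transcriptome(cfg, d2)
  expect_identical(readLines(s1$fasta), readLines(s2$fasta))
  expect_identical(readLines(s1$gtf), readLines(s2$gtf))
  # annotation round trip: n_genes + 3 transgenes, all CDS codon multiples
  expect_length(s1$annotation, cfg$n_genes + 3L)
  for (t in representative_transcripts(s1$annotation)) {
    expect_equal(t$cds_length %% 3L, 0L)
    expect_true(t$codon_ok)
  }
  expect_setequal(s1$genes$gene_id[s1$genes$is_transgene], transgenes)
  expect_equal(sum(s1$genes$true_tpm), 1e6)
})

test_that("simulated read files are byte-identical under one seed", {
  cfg <- sim_config(seed = 55L, ribo_depth = 2000L, rna_depth = 2000L)
  s1 <- simulate_transcriptome(cfg, tempfile())
  s2 <- simulate_transcriptome(cfg, tempfile())
  r1 <- simulate_ribo_reads(s1); r2 <- simulate_ribo_reads(s2)
  expect_identical(readLines(r1$sam), readLines(r2$sam))
  m1 <- simulate_rna_reads(s1); m2 <- simulate_rna_reads(s2)
  expect_identical(readLines(m1$sam), readLines(m2$sam))
  expect_identical(r1$truth_reads, r2$truth_reads)
})

test_that("degenerate frame model (1,0,0) gives perfect periodicity", {
  cfg <- sim_config(seed = 17L, ribo_depth = 3000L,
                    frame_probs = c(1, 0, 0), utr5_boost_frac = 0)
  sim <- simulate_transcriptome(cfg, tempfile())
  rr <- simulate_ribo_reads(sim)
  prof <- build_end_profiles(read_alignments(rr$sam), sim$annotation,
                             c(25L, 35L))
  tracks <- apply_offsets(prof, estimate_offsets(prof, sim$annotation))
  f <- pooled_periodicity(tracks, sim$annotation)
  expect_equal(unname(f), c(1, 0, 0))
})

test_that("footprints never cover the 3'UTR; RNA reads cover it", {
  fx <- default_sim()
  reps <- representative_transcripts(fx$sim$annotation)
  tr <- default_tracks()$tracks
  for (g in names(tr)) {
    t <- reps[[g]]
    utr3 <- tr[[g]]$counts[(t$utr5_length + t$cds_length + 1L):t$tx_length]
    expect_equal(sum(utr3), 0)
  }
  rn <- default_rna_tracks()$tracks
  utr3_rna <- vapply(names(rn), function(g) {
    t <- reps[[g]]
    sum(rn[[g]]$counts[(t$utr5_length + t$cds_length + 1L):t$tx_length])
  }, numeric(1))
  expect_gt(sum(utr3_rna), 0)
})

test_that("RNA read totals follow expression x length within the binomial CI", {
  cfg <- sim_config(n_genes = 2L, seed = 23L, rna_depth = 10000L)
  sim <- simulate_transcriptome(cfg, tempfile())
  # collapse to a 4:1 two-gene world with equal lengths: rebuild truth
  sim$genes$true_tpm <- c(8e5, 2e5, 0, 0, 0)
  sim$genes$tx_length[2] <- sim$genes$tx_length[1]
  rn <- simulate_rna_reads(sim)
  n1 <- rn$truth_genes$true_rna_count[1]
  n <- sum(rn$truth_genes$true_rna_count)
  ci <- 2.576 * sqrt(0.8 * 0.2 / n)
  expect_lt(abs(n1 / n - 0.8), ci)
})

test_that("multi-exon mode round trips through the whole pipeline", {
  cfg <- sim_config(seed = 31L, ribo_depth = 8000L, multi_exon = TRUE)
  sim <- simulate_transcriptome(cfg, tempfile())
  expect_true(any(vapply(representative_transcripts(sim$annotation),
                         function(t) length(t$exon_start) > 1L, logical(1))))
  rr <- simulate_ribo_reads(sim)
  reads <- read_alignments(rr$sam)
  prof <- build_end_profiles(reads, sim$annotation, c(25L, 35L))
  off <- estimate_offsets(prof, sim$annotation)
  expect_equal(stats::setNames(off$offset, off$length),
               stats::setNames(as.integer(cfg$offsets), names(cfg$offsets)))
  st <- library_stats(prof)
  expect_equal(st$unassigned_reads, 0L)
})

test_that("culture simulation is deterministic, two-phase, noise-controlled", {
  cfg0 <- sim_config(seed = 12L, culture = list(noise = 0))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  simulate_culture(cfg0, p1); simulate_culture(cfg0, p2)
  expect_identical(readLines(p1), readLines(p2))
  s <- read_culture(p1)
  cl <- cfg0$culture
  # zero noise: vcd doubles daily when mu = log(2)
  cfg2 <- sim_config(seed = 12L,
                     culture = list(noise = 0, mu_early = log(2)))
  s2 <- simulate_culture(cfg2)
  r1 <- s2[s2$replicate == 1L, ]
  expect_equal(r1$vcd_per_ml[r1$time_d <= 4] / r1$vcd_per_ml[1], 2^(0:4))
  # exact recovery of configured mu and qp per phase
  expect_equal(specific_growth_rate(s, c(1, 4), replicate = 1L), cl$mu_early)
  expect_equal(specific_growth_rate(s, c(5, 7), replicate = 1L), cl$mu_late)
  expect_equal(specific_productivity(s, c(1, 4))$qp, cl$qp_early)
  expect_equal(specific_productivity(s, c(5, 7))$qp, cl$qp_late)
})

test_that("simulated category map exercises multi-homolog and unmapped genes", {
  cfg <- sim_config(n_genes = 40L, seed = 2L)
  sim <- simulate_transcriptome(cfg, tempfile())
  cm <- simulate_category_map(sim)
  expect_true(any(table(cm$gene_id) > 1L))
  expect_true(length(setdiff(sim$genes$gene_id, cm$gene_id)) > 0L)
  expect_setequal(cm$category[cm$gene_id %in% transgenes], "Recombinant")
})
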