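test_that("offsets are recovered exactly from the default simulation", {
  fx <- default_sim()
  dt <- default_tracks()
  truth <- fx$cfg$offsets
  expect_equal(stats::setNames(dt$off$offset, dt$off$length),
               stats::setNames(as.integer(truth), names(truth)))
  expect_true(all(dt$off$confidence == "ok"))
})

test_that("two-length simulation with offsets {29:12, 31:13} is recovered", {
  cfg <- sim_config(seed = 5L, read_lengths = c(29L, 31L),
                    length_probs = c(0.5, 0.5),
                    offsets = c(`29` = 12L, `31` = 13L))
  sim <- simulate_transcriptome(cfg, dir = tempfile())
  rr <- simulate_ribo_reads(sim)
  prof <- build_end_profiles(read_alignments(rr$sam), sim$annotation,
                             c(25L, 35L))
  off <- estimate_offsets(prof, sim$annotation)
  expect_equal(off$offset[off$length == 29L], 12L)
  expect_equal(off$offset[off$length == 31L], 13L)
})

test_that("lengths without signal inherit the modal offset, flagged low", {
  fx <- default_sim()
  dt <- default_tracks()
  prof <- dt$prof
  # inject a sparse length-27 profile with ends far from any start codon
  g1 <- names(prof)[1]
  fake <- integer(prof[[g1]]$tx_length)
  fake[prof[[g1]]$tx_length - 5L] <- 3L
  prof[[g1]]$counts[["27"]] <- fake
  off <- estimate_offsets(prof, fx$sim$annotation)
  row <- off[off$length == 27L, ]
  expect_equal(row$confidence, "low")
  modal <- as.integer(names(which.max(table(off$offset[off$confidence == "ok"]))))
  expect_equal(row$offset, modal)
})

test_that("no calibratable signal at all is an error", {
  ann <- load_annotation(write_toy_gtf(list(list(
    gene = "g1", tx = "t1", contig = "chr", strand = "+",
    exons = matrix(c(101, 280), 1), cds = matrix(c(131, 250), 1)))))
  reads <- data.frame(contig = "chr", start = 200L, end = 230L, length = 30L)
  prof <- build_end_profiles(reads, ann, c(25L, 35L))
  expect_error(estimate_offsets(prof, ann), "insufficient calibration signal")
})

test_that("apply_offsets shifts, drops at the boundary, conserves mass", {
  t <- toy_tx(utr5 = 0L, n_codons = 10L, utr3 = 0L, gstart = 0L)
  prof <- list(g1 = list(transcript_id = "t1", gene_id = "g1",
                         tx_length = 30L,
                         counts = list(`30` = {
                           v <- integer(30L); v[1] <- 1L; v })))
  off <- data.frame(length = 30L, offset = 12L)
  tr <- apply_offsets(prof, off)
  expect_equal(which(tr$g1$counts == 1) - 1L, 12L)
  expect_equal(attr(tr, "dropped"), 0)
  # an end on the last nucleotide is shifted off and logged
  prof$g1$counts[["30"]] <- { v <- integer(30L); v[30] <- 1L; v }
  tr2 <- apply_offsets(prof, off)
  expect_equal(sum(tr2$g1$counts), 0)
  expect_equal(attr(tr2, "dropped"), 1)
  # a length missing from the table errors
  expect_error(apply_offsets(prof, data.frame(length = 28L, offset = 12L)),
               "no offset")
})

test_that("mass is conserved up to logged drops on the default library", {
  dt <- default_tracks()
  in_mass <- sum(vapply(dt$prof, function(p)
    sum(vapply(p$counts, sum, numeric(1))), numeric(1)))
  out_mass <- sum(vapply(dt$tracks, function(tr) sum(tr$counts), numeric(1)))
  expect_equal(out_mass + attr(dt$tracks, "dropped"), in_mass)
})

test_that("frame periodicity matches hand-computed fractions", {
  t <- toy_tx(utr5 = 0L, n_codons = 3L, utr3 = 0L, gstart = 0L)
  tr <- toy_track(t, c(3, 0, 0, 3, 0, 0, 3, 0, 0))
  expect_equal(frame_periodicity(tr, t), c(f0 = 1, f1 = 0, f2 = 0))
  t2 <- toy_tx(utr5 = 0L, n_codons = 2L, utr3 = 0L, gstart = 0L)
  tr2 <- toy_track(t2, c(2, 1, 1, 2, 1, 1))
  expect_equal(frame_periodicity(tr2, t2), c(f0 = 0.5, f1 = 0.25, f2 = 0.25))
  tr0 <- toy_track(t2, rep(0, 6))
  expect_error(frame_periodicity(tr0, t2), class = "no_coverage")
})

test_that("fractions sum to one and UTR coverage is ignored", {
  t <- toy_tx(utr5 = 6L, n_codons = 4L, utr3 = 6L)
  set.seed(3)
  tr <- toy_track(t, c(5, 5, 5, 5, 5, 5, runif(12, 0, 9), 0, 0, 0, 0, 0, 0))
  f <- frame_periodicity(tr, t)
  expect_equal(sum(f), 1)
  # doubling the UTR coverage changes nothing
  tr2 <- tr; tr2$counts[1:6] <- 10
  expect_equal(frame_periodicity(tr2, t), f)
})

test_that("pooled periodicity equals the coverage-weighted mean of per-gene ones", {
  fx <- default_sim()
  dt <- default_tracks()
  reps <- representative_transcripts(fx$sim$annotation)
  per <- lapply(names(dt$tracks), function(g)
    frame_periodicity(dt$tracks[[g]], reps[[g]]))
  w <- vapply(names(dt$tracks), function(g) {
    t <- reps[[g]]
    sum(dt$tracks[[g]]$counts[(t$utr5_length + 1):(t$utr5_length + t$cds_length)])
  }, numeric(1))
  weighted <- Reduce(`+`, Map(`*`, per, w)) / sum(w)
  expect_equal(pooled_periodicity(dt$tracks, fx$sim$annotation), weighted)
})

test_that("estimated global frame fractions recover the simulated probabilities", {
  fx <- default_sim()
  dt <- default_tracks()
  f <- pooled_periodicity(dt$tracks, fx$sim$annotation)
  n <- sum(fx$ribo$truth_reads$region == "cds")
  ci <- 2.576 * sqrt(0.70 * 0.30 / n)
  expect_lt(abs(f[["f0"]] - 0.70), ci)
})
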