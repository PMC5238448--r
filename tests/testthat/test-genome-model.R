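test_that("a minimal one-gene GTF loads into one GeneModel", {
  path <- write_toy_gtf(list(list(
    gene = "g1", tx = "t1", contig = "chr1", strand = "+",
    exons = matrix(c(101, 200), 1), cds = matrix(c(111, 170), 1))))
  ann <- load_annotation(path)
  expect_s3_class(ann, "RiboAnnotation")
  expect_length(ann, 1L)
  t <- ann$g1$transcripts$t1
  expect_equal(t$tx_length, 100L)
  expect_equal(t$cds_length, 60L)
  expect_equal(t$utr5_length, 10L)
  expect_equal(t$utr3_length, 30L)
  expect_true(t$codon_ok)
})

test_that("GFF3 input with ID/Parent attributes parses too", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=t1",
    "chr1\tsrc\tCDS\t111\t170\t.\t+\t0\tID=c1;Parent=t1"), path)
  ann <- load_annotation(path)
  tx <- representative_transcripts(ann)
  expect_length(tx, 1L)
  expect_equal(tx[[1]]$cds_length, 60L)
})

test_that("representative transcript is the longest CDS, ties lexicographic", {
  mk <- function(id, cds_len)
    transcript_model(id, "g", "chr", "+", 0L, 2000L, 100L, 100L + cds_len)
  g <- list(gene_id = "g",
            transcripts = list(ta = mk("ta", 300L), tb = mk("tb", 450L)),
            representative = NA, coding = TRUE)
  expect_equal(select_representative(g)$transcript_id, "tb")
  expect_equal(select_representative(g)$cds_length, 450L)
  # tie on length: lexicographically smallest id wins, regardless of order
  g$transcripts <- list(tB = mk("tB", 300L), tA = mk("tA", 300L))
  expect_equal(select_representative(g)$transcript_id, "tA")
  # no coding transcript signals non_coding_gene
  g$transcripts <- list(tn = transcript_model("tn", "g", "chr", "+", 0L, 500L))
  expect_error(select_representative(g), class = "non_coding_gene")
})

test_that("longest-CDS rule holds through load_annotation", {
  path <- write_toy_gtf(list(
    list(gene = "g1", tx = "tS", contig = "c", strand = "+",
         exons = matrix(c(1, 1000), 1), cds = matrix(c(101, 400), 1)),
    list(gene = "g1", tx = "tL", contig = "c", strand = "+",
         exons = matrix(c(1, 1000), 1), cds = matrix(c(101, 550), 1))))
  ann <- load_annotation(path)
  expect_equal(ann$g1$representative, "tL")
  expect_equal(representative_transcripts(ann)$g1$cds_length, 450L)
})

test_that("CDS length not divisible by 3 is flagged, CDS outside exons excluded", {
  t <- transcript_model("t", "g", "chr", "+", 0L, 1000L, 100L, 401L)
  expect_true(t$coding)
  expect_false(t$codon_ok)
  expect_warning(
    ann <- load_annotation(write_toy_gtf(list(list(
      gene = "g1", tx = "t1", contig = "c", strand = "+",
      exons = matrix(c(101, 200), 1), cds = matrix(c(150, 250), 1))))),
    "excluded")
  expect_false(ann$g1$coding)
})

test_that("coordinate mapping follows strand and signals unmapped positions", {
  tp <- transcript_model("t", "g", "chr", "+", 100L, 200L)
  expect_equal(genomic_to_transcript(100L, tp), 0L)
  tm <- transcript_model("t", "g", "chr", "-", 100L, 130L)
  expect_equal(genomic_to_transcript(129L, tm), 0L)
  expect_equal(genomic_to_transcript(100L, tm), 29L)
  expect_error(genomic_to_transcript(50L, tp), class = "unmapped_position")
  expect_error(genomic_to_transcript(250L, tp), class = "unmapped_position")
  # intronic position of a spliced transcript
  ts <- transcript_model("t", "g", "chr", "+", c(100L, 300L), c(200L, 400L))
  expect_error(genomic_to_transcript(250L, ts), class = "unmapped_position")
})

test_that("genomic<->transcript round trip is exact on exonic positions", {
  models <- list(
    transcript_model("p1", "g", "chr", "+", c(10L, 50L, 200L),
                     c(30L, 90L, 260L)),
    transcript_model("m1", "g", "chr", "-", c(10L, 50L, 200L),
                     c(30L, 90L, 260L)))
  for (t in models) {
    exonic <- unlist(mapply(function(s, e) s:(e - 1L), t$exon_start,
                            t$exon_end, SIMPLIFY = FALSE))
    expect_equal(transcript_to_genomic(genomic_to_transcript(exonic, t), t),
                 exonic)
    # transcript coordinates run 5'->3' without gaps
    expect_setequal(genomic_to_transcript(exonic, t), 0:(t$tx_length - 1L))
  }
})

test_that("spliced length decomposes as utr5 + cds + utr3", {
  fx <- default_sim()
  for (t in representative_transcripts(fx$sim$annotation)) {
    expect_equal(sum(t$exon_end - t$exon_start), t$tx_length)
    expect_equal(t$utr5_length + t$cds_length + t$utr3_length, t$tx_length)
  }
})

test_that("stop-codon convention is recorded from the file's dialect", {
  base <- list(gene = "g1", tx = "t1", contig = "c", strand = "+",
               exons = matrix(c(1, 300), 1), cds = matrix(c(31, 120), 1))
  expect_equal(attr(load_annotation(write_toy_gtf(list(base))),
                    "stop_codon_convention"), "included")
  path <- write_toy_gtf(list(base))
  cat('c\tsrc\tstop_codon\t121\t123\t.\t+\t0\tgene_id "g1"; transcript_id "t1";\n',
      file = path, append = TRUE)
  expect_equal(attr(load_annotation(path), "stop_codon_convention"),
               "excluded")
})
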