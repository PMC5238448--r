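#' Simulation configuration
#'
#' The stated world of the synthetic fixtures: a small genome of endogenous
#' genes plus three transgenes (IgG heavy chain, IgG light chain, NeoR), a
#' footprint read model with per-length A-site offsets and strong frame-0
#' bias, an RNA-Seq model with uniform full-transcript coverage, and a
#' two-phase batch-culture model. Defaults mirror the regime of an
#' IgG-producing CHO batch culture: ~30 nt footprints, ~70% frame-0
#' periodicity, recombinant mRNAs at ~20% of the transcriptome, specific
#' productivity 16 -> 5.5 pg/cell/day across the growth phases.
#'
#' @param n_genes number of endogenous genes (default 5).
#' @param seed RNG seed recorded in all outputs.
#' @param codon_range endogenous CDS lengths in codons, sampled uniformly
#'   (default 120-400; transgenes use fixed realistic lengths).
#' @param utr5_length,utr3_length UTR lengths in nt (default 60 each).
#' @param transgene_tpm_share total truth-tpm fraction of the three
#'   transgenes (default 0.20), split heavy/light/NeoR 0.50/0.20/0.30.
#' @param read_lengths,length_probs footprint length distribution over
#'   28-32 nt (default probabilities 0.1/0.2/0.4/0.2/0.1).
#' @param offsets named integer vector, true A-site offset per read length
#'   (defaults 12-16 nt, distinct per length).
#' @param frame_probs within-codon nucleotide probabilities (p0, p1, p2),
#'   default (0.70, 0.15, 0.15).
#' @param start_peak fraction of a gene's footprints decoding the initiator
#'   codon (default 0.08) — the initiation pile-up that anchors offset
#'   calibration.
#' @param utr5_boost_frac extra transgene reads with A sites in the 5'UTR,
#'   as a fraction of the gene's CDS footprints (default 0.10; endogenous
#'   genes get none).
#' @param ribo_depth,rna_depth total reads per assay (default 20000 each).
#' @param rna_read_length RNA-Seq read length (default 36 nt).
#' @param te_log2_sd spread of truth log2 translation efficiency (default 0.5).
#' @param multi_exon split genes into 2-3 exons with 80 nt introns to
#'   exercise spliced coordinate mapping (default FALSE).
#' @param culture list of batch-culture parameters: `v0` (seed density,
#'   cells/mL), `mu_early`/`mu_late` (1/day), `phase_boundary` (day),
#'   `qp_early`/`qp_late` (pg/cell/day), `noise` (multiplicative CV),
#'   `days`, `n_replicates`.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 5L, seed = 1L,
                       codon_range = c(120L, 400L),
                       utr5_length = 60L, utr3_length = 60L,
                       transgene_tpm_share = 0.20,
                       read_lengths = 28:32,
                       length_probs = c(0.1, 0.2, 0.4, 0.2, 0.1),
                       offsets = c(`28` = 12L, `29` = 13L, `30` = 14L,
                                   `31` = 15L, `32` = 16L),
                       frame_probs = c(0.70, 0.15, 0.15),
                       start_peak = 0.08,
                       utr5_boost_frac = 0.10,
                       ribo_depth = 20000L, rna_depth = 20000L,
                       rna_read_length = 36L,
                       te_log2_sd = 0.5,
                       multi_exon = FALSE,
                       culture = list()) {
  stopifnot(abs(sum(length_probs) - 1) < 1e-9,
            abs(sum(frame_probs) - 1) < 1e-9,
            length(read_lengths) == length(length_probs),
            all(as.character(read_lengths) %in% names(offsets)))
  cult <- utils::modifyList(list(
    v0 = 3e5, mu_early = 0.65, mu_late = 0.10, phase_boundary = 4,
    qp_early = 16, qp_late = 5.5, noise = 0.03,
    days = 0:7, n_replicates = 3L), culture)
  structure(list(
    n_genes = n_genes, seed = as.integer(seed), codon_range = codon_range,
    utr5_length = utr5_length, utr3_length = utr3_length,
    transgene_tpm_share = transgene_tpm_share,
    read_lengths = as.integer(read_lengths), length_probs = length_probs,
    offsets = offsets, frame_probs = frame_probs, start_peak = start_peak,
    utr5_boost_frac = utr5_boost_frac,
    ribo_depth = as.integer(ribo_depth), rna_depth = as.integer(rna_depth),
    rna_read_length = as.integer(rna_read_length),
    te_log2_sd = te_log2_sd, multi_exon = multi_exon, culture = cult),
    class = "SimConfig")
}

# genomic alignment blocks of transcript interval [p5, p5+len-1]; returns
# list(pos1 = 1-based leftmost position, cigar = cigar string)
.tx_read_to_sam <- function(t, p5, len) {
  g <- sort(transcript_to_genomic(p5:(p5 + len - 1L), t))
  brk <- which(diff(g) != 1L)
  starts <- g[c(1L, brk + 1L)]
  ends <- g[c(brk, length(g))]
  cig <- paste0(ends[1] - starts[1] + 1L, "M")
  if (length(starts) > 1L)
    for (i in 2:length(starts))
      cig <- paste0(cig, starts[i] - ends[i - 1L] - 1L, "N",
                    ends[i] - starts[i] + 1L, "M")
  list(pos1 = starts[1] + 1L, cigar = cig)
}

# vectorised SAM fields for reads [p5, p5+len-1] on transcript t; fast path
# for single-exon transcripts, per-read block computation otherwise
.reads_to_sam <- function(t, p5, len) {
  if (length(t$exon_start) == 1L) {
    pos1 <- if (t$strand == "+") t$exon_start + p5 + 1L
            else t$exon_start + t$tx_length - p5 - len + 1L
    return(list(pos1 = as.integer(pos1), cigar = paste0(len, "M")))
  }
  rec <- lapply(seq_along(p5), function(j) .tx_read_to_sam(t, p5[j], len[j]))
  list(pos1 = as.integer(vapply(rec, `[[`, numeric(1), "pos1")),
       cigar = vapply(rec, `[[`, character(1), "cigar"))
}

.write_sam <- function(records, contig_lengths, path) {
  # records: data.frame(qname, flag, contig, pos1, cigar); sorted by
  # coordinate so downstream BAM conversion is clean
  o <- order(match(records$contig, names(contig_lengths)), records$pos1)
  records <- records[o, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  records$qname, as.integer(records$flag), records$contig,
                  as.integer(records$pos1), records$cigar)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.rand_cds <- function(n_codons) {
  # ATG + random non-stop codons + TAA
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste0,
                         collapse = ""),
                   c("TAA", "TAG", "TGA", "ATG"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Simulate a toy genome, annotation and expression truth
#'
#' Writes a genome FASTA and a GTF with `n_genes` endogenous genes (contig
#' `chr1`, alternating strands) plus the three transgenes on a dedicated
#' `vector` contig, and draws the per-gene truth: tpm, translation
#' efficiency. CDS features include the stop codon. The annotation
#' round-trips through [load_annotation()].
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return A `RiboSim` list: `config`, `fasta`, `gtf`, `annotation`
#'   (loaded), and `genes` — the truth table stub (`gene_id`,
#'   `transcript_id`, `contig`, `strand`, `n_codons`, `cds_length`,
#'   `tx_length`, `true_tpm`, `true_te`, `is_transgene`).
#' @export
simulate_transcriptome <- function(config, dir = tempfile("riboSim")) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  tg <- data.frame(gene_id = c("IgG_HC", "IgG_LC", "NeoR"),
                   n_codons = c(470L, 235L, 267L),
                   strand = c("+", "-", "+"),
                   contig = "vector", stringsAsFactors = FALSE)
  en <- data.frame(gene_id = sprintf("gene%02d", seq_len(config$n_genes)),
                   n_codons = sample(config$codon_range[1]:config$codon_range[2],
                                     config$n_genes, replace = TRUE),
                   strand = rep(c("+", "-"), length.out = config$n_genes),
                   contig = "chr1", stringsAsFactors = FALSE)
  genes <- rbind(en, tg)
  genes$transcript_id <- paste0(genes$gene_id, "_t1")
  genes$is_transgene <- genes$contig == "vector"

  u5 <- config$utr5_length; u3 <- config$utr3_length
  genes$cds_length <- genes$n_codons * 3L
  genes$tx_length <- u5 + genes$cds_length + u3

  # truth expression: transgene share split HC/LC/NeoR = 0.50/0.20/0.30,
  # endogenous remainder by a flat Dirichlet draw
  share <- config$transgene_tpm_share
  w_en <- stats::rgamma(config$n_genes, shape = 1)
  tpm <- c(w_en / sum(w_en) * (1 - share) * 1e6,
           share * c(0.50, 0.20, 0.30) * 1e6)
  genes$true_tpm <- tpm
  genes$true_te <- 2^stats::rnorm(nrow(genes), 0, config$te_log2_sd)

  # genomic layout with 200 nt gaps; optional 2-3 exons with 80 nt introns
  gap <- 200L; intron <- 80L
  gtf <- character(0)
  seqs <- list(chr1 = character(0), vector = character(0))
  cursor <- c(chr1 = 0L, vector = 0L)
  exon_tbl <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n_ex <- if (config$multi_exon) sample(2:3, 1) else 1L
    # split the spliced transcript into n_ex chunks (each >= 40 nt)
    if (n_ex > 1L) {
      cuts <- sort(sample(seq(40L, g$tx_length - 40L), n_ex - 1L))
      chunk <- diff(c(0L, cuts, g$tx_length))
    } else chunk <- g$tx_length
    gstart <- cursor[[g$contig]] + gap
    ex_s <- integer(n_ex); ex_e <- integer(n_ex)
    pos <- gstart
    for (k in seq_len(n_ex)) {
      ex_s[k] <- pos; ex_e[k] <- pos + chunk[k]
      pos <- ex_e[k] + intron
    }
    cursor[[g$contig]] <- ex_e[n_ex]
    exon_tbl[[g$gene_id]] <- list(start = ex_s, end = ex_e)

    # transcript sequence: UTR5 + CDS + UTR3 (sense orientation)
    tx_seq <- paste0(paste(sample(c("A","C","G","T"), u5, replace = TRUE),
                           collapse = ""),
                     .rand_cds(g$n_codons),
                     paste(sample(c("A","C","G","T"), u3, replace = TRUE),
                           collapse = ""))
    seqs[[g$contig]] <- c(seqs[[g$contig]],
                          list(list(start = ex_s, end = ex_e,
                                    strand = g$strand, seq = tx_seq)))

    # CDS genomic sub-intervals via a temporary model
    tmp <- transcript_model(g$transcript_id, g$gene_id, g$contig, g$strand,
                            ex_s, ex_e)
    cds_tx <- u5:(u5 + g$cds_length - 1L)
    cds_g <- sort(transcript_to_genomic(cds_tx, tmp))
    brk <- which(diff(cds_g) != 1L)
    cds_s <- cds_g[c(1L, brk + 1L)]; cds_e <- cds_g[c(brk, length(cds_g))]

    att <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id,
                   g$transcript_id)
    gtf <- c(gtf,
             sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s", g$contig,
                     ex_s + 1L, ex_e, g$strand, att),
             sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s", g$contig,
                     cds_s + 1L, cds_e + 1L, g$strand, att))
  }

  # assemble contig sequences: random background, transcribed regions pasted
  contig_lengths <- cursor + gap
  fa <- lapply(names(contig_lengths), function(ctg) {
    s <- sample(c("A", "C", "G", "T"), contig_lengths[[ctg]], replace = TRUE)
    for (tx in seqs[[ctg]]) {
      nt <- strsplit(tx$seq, "")[[1]]
      if (tx$strand == "-")
        nt <- rev(c(A = "T", C = "G", G = "C", T = "A")[nt])
      off <- 0L
      for (k in seq_along(tx$start)) {
        w <- tx$end[k] - tx$start[k]
        s[(tx$start[k] + 1L):tx$end[k]] <- nt[(off + 1L):(off + w)]
        off <- off + w
      }
    }
    paste(s, collapse = "")
  })
  names(fa) <- names(contig_lengths)
  fasta_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(fa)), fasta_path)
  gtf_path <- file.path(dir, "annotation.gtf")
  writeLines(gtf, gtf_path)

  ann <- load_annotation(gtf_path)
  structure(list(config = config, fasta = fasta_path, gtf = gtf_path,
                 annotation = ann, contig_lengths = contig_lengths,
                 genes = genes[, c("gene_id", "transcript_id", "contig",
                                   "strand", "n_codons", "cds_length",
                                   "tx_length", "true_tpm", "true_te",
                                   "is_transgene")]),
            class = "RiboSim")
}

#' Simulate a ribosome-footprint library (SAM + truth table)
#'
#' Gene totals are drawn multinomially with weights
#' `true_tpm x true_te x cds_length`. For each footprint an A-site codon is
#' drawn (uniform over elongating codons, with a `start_peak` chance of the
#' initiator codon), the within-codon nucleotide from `frame_probs`, the
#' read length from the length distribution, and the 5' end is placed at
#' (A site - offset(length)). Transgenes additionally receive
#' `utr5_boost_frac` extra reads with A sites uniform in the 5'UTR. No read
#' ever covers the 3'UTR. Alignments are written as coordinate-sorted SAM
#' (minus-strand genes yield flag-16 records).
#'
#' @param sim a `RiboSim` from [simulate_transcriptome()].
#' @param path output SAM path (default inside the sim directory).
#' @return list with `sam` (path), `truth_reads` (per-read `data.frame`:
#'   `gene_id`, `length`, `a_site` transcript coordinate, `region`), and
#'   `truth_genes` (per-gene `true_ribo_count`, plus the truth stub
#'   columns).
#' @export
simulate_ribo_reads <- function(sim, path = file.path(dirname(sim$gtf),
                                                      "ribo.sam")) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  g <- sim$genes
  reps <- representative_transcripts(sim$annotation)
  w <- g$true_tpm * g$true_te * g$cds_length
  n_cds <- as.integer(stats::rmultinom(1, cfg$ribo_depth, w))
  off <- cfg$offsets

  rows <- vector("list", nrow(g))
  truth <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    t <- reps[[g$gene_id[i]]]
    n <- n_cds[i]
    n_utr <- if (g$is_transgene[i]) round(cfg$utr5_boost_frac * n) else 0L
    if (n + n_utr == 0L) next
    # CDS footprints
    codon <- ifelse(stats::runif(n) < cfg$start_peak, 0L,
                    sample(0:(g$n_codons[i] - 2L), n, replace = TRUE))
    frame <- sample(0:2, n, replace = TRUE, prob = cfg$frame_probs)
    a_cds <- cfg$utr5_length + 3L * codon + frame
    region <- rep("cds", n)
    # 5'UTR pile for transgenes: A sites uniform in [max offset, utr5)
    if (n_utr > 0L) {
      a_utr <- sample(max(off):(cfg$utr5_length - 1L), n_utr, replace = TRUE)
      a_cds <- c(a_cds, a_utr)
      region <- c(region, rep("utr5", n_utr))
    }
    len <- sample(cfg$read_lengths, n + n_utr, replace = TRUE,
                  prob = cfg$length_probs)
    p5 <- as.integer(a_cds - off[as.character(len)])
    samrec <- .reads_to_sam(t, p5, len)
    rows[[i]] <- data.frame(
      qname = sprintf("%s_r%d", g$gene_id[i], seq_along(p5)),
      flag = if (t$strand == "+") 0L else 16L,
      contig = t$contig,
      pos1 = samrec$pos1, cigar = samrec$cigar,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(gene_id = g$gene_id[i], length = len,
                             a_site = a_cds, region = region,
                             stringsAsFactors = FALSE)
  }
  .write_sam(do.call(rbind, rows), sim$contig_lengths, path)
  truth_reads <- do.call(rbind, truth)
  tg <- g
  tg$true_ribo_count <- n_cds
  list(sam = path, truth_reads = truth_reads, truth_genes = tg)
}

#' Simulate an RNA-Seq library (SAM + truth table)
#'
#' Gene totals are multinomial with weights `true_tpm x tx_length`; read
#' start positions are uniform along the spliced transcript (UTRs
#' included).
#'
#' @param sim a `RiboSim`.
#' @param path output SAM path.
#' @return list with `sam`, `truth_genes` (adds `true_rna_count`).
#' @export
simulate_rna_reads <- function(sim, path = file.path(dirname(sim$gtf),
                                                     "rna.sam")) {
  cfg <- sim$config
  set.seed(cfg$seed + 2L)
  g <- sim$genes
  reps <- representative_transcripts(sim$annotation)
  n_g <- as.integer(stats::rmultinom(1, cfg$rna_depth, g$true_tpm * g$tx_length))
  L <- cfg$rna_read_length
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    if (n_g[i] == 0L) next
    t <- reps[[g$gene_id[i]]]
    p5 <- sample(0:(g$tx_length[i] - L), n_g[i], replace = TRUE)
    samrec <- .reads_to_sam(t, p5, rep(L, n_g[i]))
    rows[[i]] <- data.frame(
      qname = sprintf("%s_m%d", g$gene_id[i], seq_along(p5)),
      flag = if (t$strand == "+") 0L else 16L,
      contig = t$contig,
      pos1 = samrec$pos1, cigar = samrec$cigar,
      stringsAsFactors = FALSE)
  }
  .write_sam(do.call(rbind, rows), sim$contig_lengths, path)
  tg <- g
  tg$true_rna_count <- n_g
  list(sam = path, truth_genes = tg)
}

#' Simulate a two-phase batch-culture time series
#'
#' VCD grows exponentially at `mu_early` until the phase boundary and at
#' `mu_late` after it; titer accumulates as q_p times the trapezoidal IVCD
#' increment of the sampled daily grid, with the phase's q_p applied to each
#' day's increment. Multiplicative log-normal noise at the configured level
#' is applied to VCD and titer per observation.
#'
#' @param config a [sim_config()] (its `culture` block is used).
#' @param path optional CSV output path.
#' @return A `CultureSeries` `data.frame` (`time_d`, `vcd_per_ml`,
#'   `viability_pct`, `titer_ug_ml`, `glucose_g_l`, `lactate_g_l`,
#'   `replicate`).
#' @export
simulate_culture <- function(config, path = NULL) {
  cl <- config$culture
  set.seed(config$seed + 3L)
  days <- cl$days
  clean_vcd <- cl$v0 * exp(cl$mu_early * pmin(days, cl$phase_boundary) +
                           cl$mu_late * pmax(0, days - cl$phase_boundary))
  dI <- diff(days) * (utils::head(clean_vcd, -1) + utils::tail(clean_vcd, -1)) / 2
  qp <- ifelse(utils::tail(days, -1) <= cl$phase_boundary, cl$qp_early,
               cl$qp_late)
  clean_titer <- c(0, cumsum(qp * dI)) * 1e-6   # pg/cell/day * cell.day/mL -> ug/mL
  viability <- pmax(70, 99 - 0.4 * days - 1.5 * pmax(0, days - cl$phase_boundary)^1.5)
  glucose <- pmax(0, 6 - 0.9 * days)
  lactate <- pmin(2.5, 0.6 * days) - pmax(0, 0.5 * (days - cl$phase_boundary - 1))
  out <- do.call(rbind, lapply(seq_len(cl$n_replicates), function(r) {
    data.frame(
      time_d = days,
      vcd_per_ml = clean_vcd * exp(stats::rnorm(length(days), 0, cl$noise)),
      viability_pct = viability,
      titer_ug_ml = clean_titer * exp(stats::rnorm(length(days), 0, cl$noise)),
      glucose_g_l = glucose, lactate_g_l = pmax(0, lactate),
      replicate = r)
  }))
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  structure(out, class = c("CultureSeries", "data.frame"))
}

#' Simulate a gene -> homolog -> category map
#'
#' Assigns every simulated gene to one of `categories`; a `multi_frac`
#' share of genes additionally maps to a second homolog in another
#' category, exercising the even-allocation rule. Transgenes map to the
#' "Recombinant" category with a single homolog.
#'
#' @param sim a `RiboSim`.
#' @param categories endogenous category labels.
#' @param multi_frac fraction of endogenous genes with two homologs.
#' @param unmapped_frac fraction of endogenous genes left out of the map.
#' @return A `CategoryMap` `data.frame` (`gene_id`, `homolog_id`,
#'   `category`).
#' @export
simulate_category_map <- function(sim,
                                  categories = c("Translation", "Folding",
                                                 "Metabolism", "Cell cycle"),
                                  multi_frac = 0.3, unmapped_frac = 0.1) {
  set.seed(sim$config$seed + 4L)
  g <- sim$genes
  rows <- list()
  hom <- 0L
  for (i in seq_len(nrow(g))) {
    if (g$is_transgene[i]) {
      hom <- hom + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], homolog_id = sprintf("mmu%05d", hom),
        category = "Recombinant", stringsAsFactors = FALSE)
      next
    }
    if (stats::runif(1) < unmapped_frac) next
    cats <- sample(categories, if (stats::runif(1) < multi_frac) 2L else 1L)
    for (cat in cats) {
      hom <- hom + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], homolog_id = sprintf("mmu%05d", hom),
        category = cat, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("CategoryMap", "data.frame"))
}
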