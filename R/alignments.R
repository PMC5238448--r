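#' Read aligned reads from SAM/BAM
#'
#' Loads single-end alignments and reduces them to the fields the end-rule
#' needs: contig, 0-based half-open aligned span on the reference, and the
#' aligned read length (query width after soft clipping — soft-clipped bases
#' never count). The alignment strand flag is ignored downstream: the gene's
#' strand governs which end is counted.
#'
#' @param path SAM or BAM file.
#' @return `data.frame` with columns `contig`, `start` (0-based), `end`
#'   (exclusive), `length` (nt), `flag`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(what = "flag"))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(aln)),
    start = BiocGenerics::start(aln) - 1L,
    end = BiocGenerics::end(aln),
    length = GenomicAlignments::cigarWidthAlongQuerySpace(
      GenomicAlignments::cigar(aln), after.soft.clipping = TRUE),
    flag = S4Vectors::mcols(aln)$flag,
    stringsAsFactors = FALSE)
}

#' Strand-dependent ribosome end rule
#'
#' The counted position is the ribosome's 5' end in mRNA orientation: the 5'
#' (lowest) genomic end of the read for genes on the plus strand, and the 3'
#' (highest) genomic end for genes on the minus strand.
#'
#' @param read list/data.frame with `start` (0-based) and `end` (exclusive);
#'   vectorised.
#' @param gene_strand `"+"` or `"-"`.
#' @return 0-based genomic position(s) of the counted end.
#' @export
assign_ribosome_end <- function(read, gene_strand) {
  stopifnot(gene_strand %in% c("+", "-"))
  if (gene_strand == "+") as.integer(read$start) else as.integer(read$end) - 1L
}

#' Build per-read-length end profiles along representative transcripts
#'
#' Applies the read-length filter, assigns each retained read's counted end
#' (see [assign_ribosome_end()]) and, for every gene whose representative
#' transcript's exons contain that genomic position, adds one count at the
#' corresponding spliced-transcript position in that gene's per-length
#' profile. Reads whose end overlaps several genes count once for each
#' (tallied as `ambiguous` in the stats); reads whose end lands in no exon
#' are `unassigned`.
#'
#' @param reads `data.frame` from [read_alignments()].
#' @param annotation a `RiboAnnotation`.
#' @param length_range `c(min, max)` aligned-length filter in nt, or `NULL`
#'   for no filter (RNA-Seq ingest).
#' @return An `EndProfileSet`: named list (by gene) of lists with
#'   `transcript_id`, `tx_length` and `counts` — a named list mapping read
#'   length to an integer vector over transcript positions. The
#'   `"library_stats"` attribute holds the bookkeeping
#'   (`total_input_reads`, `retained_reads`, `assigned_reads`,
#'   `unassigned_reads`, `ambiguous_assignments`, `length_histogram`).
#' @export
build_end_profiles <- function(reads, annotation, length_range = c(25L, 35L)) {
  if (!length(annotation)) stop("empty annotation")
  if (!is.null(length_range) && length_range[1] > length_range[2])
    stop("invalid length_range")
  total <- nrow(reads)
  if (!is.null(length_range))
    reads <- reads[reads$length >= length_range[1] &
                   reads$length <= length_range[2], , drop = FALSE]
  retained <- nrow(reads)
  if (retained == 0L) warning("no reads retained after length filter")

  reps <- representative_transcripts(annotation)
  profiles <- lapply(reps, function(t) {
    list(transcript_id = t$transcript_id, gene_id = t$gene_id,
         tx_length = t$tx_length, counts = list())
  })

  # counted genomic end under each strand convention, computed once
  end_plus <- reads$start
  end_minus <- reads$end - 1L
  n_hits <- integer(retained)

  for (gid in names(reps)) {
    t <- reps[[gid]]
    ends <- if (t$strand == "+") end_plus else end_minus
    on_contig <- reads$contig == t$contig
    # membership in any exon of the representative transcript
    idx <- which(on_contig)
    if (!length(idx)) next
    e <- ends[idx]
    exi <- findInterval(e, t$exon_start)
    inside <- exi >= 1L & exi <= length(t$exon_start)
    inside[inside] <- e[inside] < t$exon_end[exi[inside]]
    idx <- idx[inside]
    if (!length(idx)) next
    tpos <- genomic_to_transcript(ends[idx], t)
    n_hits[idx] <- n_hits[idx] + 1L
    df <- data.frame(len = reads$length[idx], pos = tpos)
    for (L in sort(unique(df$len))) {
      key <- as.character(L)
      v <- profiles[[gid]]$counts[[key]]
      if (is.null(v)) v <- integer(t$tx_length)
      tb <- tabulate(df$pos[df$len == L] + 1L, nbins = t$tx_length)
      profiles[[gid]]$counts[[key]] <- v + tb
    }
  }

  assigned <- sum(n_hits > 0L)
  stats <- list(
    total_input_reads = total,
    retained_reads = retained,
    assigned_reads = assigned,
    unassigned_reads = retained - assigned,
    ambiguous_assignments = sum(n_hits > 1L),
    length_histogram = if (retained) table(reads$length) else table(integer(0)))
  structure(profiles, class = "EndProfileSet", library_stats = stats)
}

#' Library bookkeeping of an `EndProfileSet`
#' @param profiles an `EndProfileSet`.
#' @return The stats list recorded at ingest.
#' @export
library_stats <- function(profiles) attr(profiles, "library_stats")

#' Write end profiles as a long-format TSV
#'
#' One row per (gene, read length, position) with a non-zero count.
#'
#' @param profiles an `EndProfileSet`.
#' @param path output file.
#' @export
write_end_profiles <- function(profiles, path) {
  rows <- list()
  for (gid in names(profiles)) {
    p <- profiles[[gid]]
    for (L in names(p$counts)) {
      nz <- which(p$counts[[L]] > 0L)
      if (!length(nz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = p$transcript_id, position = nz - 1L,
        length = as.integer(L), count = p$counts[[L]][nz])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), position = integer(0),
               length = integer(0), count = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
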