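#' Build a transcript model
#'
#' A `TranscriptModel` describes the exon/CDS structure of one transcript in
#' 0-based half-open genomic coordinates and carries the derived spliced
#' lengths (5'UTR, CDS, 3'UTR). Exons must be sorted and non-overlapping and
#' every CDS interval must lie inside an exon.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end integer vectors, 0-based half-open.
#' @param cds_start,cds_end integer vectors, 0-based half-open; may be empty
#'   for non-coding transcripts.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand,
                             exon_start, exon_end,
                             cds_start = integer(0), cds_end = integer(0)) {
  stopifnot(strand %in% c("+", "-"), length(exon_start) == length(exon_end),
            length(cds_start) == length(cds_end))
  o <- order(exon_start)
  exon_start <- as.integer(exon_start[o]); exon_end <- as.integer(exon_end[o])
  if (any(exon_end <= exon_start)) stop("exon end must exceed exon start")
  if (length(exon_start) > 1 &&
      any(exon_start[-1] < exon_end[-length(exon_end)]))
    stop("exons overlap in transcript ", transcript_id)
  o <- order(cds_start)
  cds_start <- as.integer(cds_start[o]); cds_end <- as.integer(cds_end[o])
  # every CDS interval must be contained in a single exon
  if (length(cds_start)) {
    hit <- vapply(seq_along(cds_start), function(i) {
      any(exon_start <= cds_start[i] & cds_end[i] <= exon_end)
    }, logical(1))
    if (!all(hit)) stop("CDS outside exons in transcript ", transcript_id)
  }
  tx_length <- sum(exon_end - exon_start)
  cds_length <- sum(cds_end - cds_start)
  t <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    contig = contig, strand = strand,
    exon_start = exon_start, exon_end = exon_end,
    cds_start = cds_start, cds_end = cds_end,
    tx_length = tx_length, cds_length = cds_length,
    utr5_length = NA_integer_, utr3_length = NA_integer_,
    coding = cds_length > 0L,
    codon_ok = cds_length > 0L && cds_length %% 3L == 0L
  ), class = "TranscriptModel")
  if (t$coding) {
    # 5'UTR length = transcript coordinate of the first CDS nucleotide
    first_cds <- if (strand == "+") cds_start[1] else cds_end[length(cds_end)] - 1L
    t$utr5_length <- genomic_to_transcript(first_cds, t)
    t$utr3_length <- t$tx_length - t$utr5_length - t$cds_length
  }
  t
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s%s  exons:%d  length:%d  CDS:%d (utr5:%s utr3:%s)%s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              length(x$exon_start), x$tx_length, x$cds_length,
              x$utr5_length, x$utr3_length,
              if (x$coding && !x$codon_ok) "  [CDS not a codon multiple]" else ""))
  invisible(x)
}

#' Map a genomic position to spliced transcript coordinates
#'
#' Returns the 0-based position along the spliced transcript in 5'->3' mRNA
#' orientation: on the minus strand the highest genomic exon coordinate maps
#' to 0. Vectorised over `pos`.
#'
#' @param pos integer vector of 0-based genomic positions.
#' @param t a [transcript_model()].
#' @param nomatch what to return for intronic/outside positions: `"error"`
#'   (default) signals an `unmapped_position` condition; `"na"` yields `NA`.
#' @return Integer vector of transcript coordinates.
#' @export
genomic_to_transcript <- function(pos, t, nomatch = c("error", "na")) {
  nomatch <- match.arg(nomatch)
  pos <- as.integer(pos)
  n_ex <- length(t$exon_start)
  idx <- findInterval(pos, t$exon_start)          # candidate exon (1-based)
  ok <- idx >= 1L & idx <= n_ex
  ok[ok] <- pos[ok] < t$exon_end[idx[ok]]
  if (!all(ok)) {
    if (nomatch == "error")
      stop(structure(class = c("unmapped_position", "error", "condition"),
                     list(message = sprintf(
                       "position(s) %s not exonic in transcript %s",
                       paste(pos[!ok], collapse = ","), t$transcript_id),
                       call = sys.call(-1))))
  }
  cum <- cumsum(c(0L, t$exon_end - t$exon_start))  # offset of each exon
  out <- rep(NA_integer_, length(pos))
  out[ok] <- cum[idx[ok]] + (pos[ok] - t$exon_start[idx[ok]])
  if (t$strand == "-") out[ok] <- t$tx_length - 1L - out[ok]
  out
}

#' Map a spliced transcript coordinate back to the genome
#'
#' Inverse of [genomic_to_transcript()]. Vectorised over `p`.
#'
#' @param p integer vector of 0-based transcript coordinates.
#' @param t a [transcript_model()].
#' @return Integer vector of 0-based genomic positions.
#' @export
transcript_to_genomic <- function(p, t) {
  p <- as.integer(p)
  if (any(p < 0L | p >= t$tx_length))
    stop("transcript coordinate out of range for ", t$transcript_id)
  q <- if (t$strand == "-") t$tx_length - 1L - p else p
  cum <- cumsum(c(0L, t$exon_end - t$exon_start))
  idx <- findInterval(q, cum)   # exon i holds q in [cum[i], cum[i+1])
  t$exon_start[idx] + (q - cum[idx])
}

#' Select the representative transcript of a gene
#'
#' The representative is the coding transcript with the longest CDS; ties are
#' broken by the lexicographically smallest `transcript_id`.
#'
#' @param gene a `GeneModel` as returned by [load_annotation()].
#' @return The representative `TranscriptModel`.
#' @export
select_representative <- function(gene) {
  coding <- Filter(function(t) t$coding, gene$transcripts)
  if (!length(coding))
    stop(structure(class = c("non_coding_gene", "error", "condition"),
                   list(message = paste0("gene ", gene$gene_id,
                                         " has no coding transcript"),
                        call = sys.call(-1))))
  len <- vapply(coding, `[[`, integer(1), "cds_length")
  ids <- vapply(coding, `[[`, character(1), "transcript_id")
  best <- which(len == max(len))
  coding[[best[order(ids[best])[1]]]]
}

#' Load a GTF/GFF3 annotation into gene models
#'
#' Parses `exon` and `CDS` features (via `rtracklayer`), builds a
#' [transcript_model()] per transcript and groups them into `GeneModel`s.
#' Internal coordinates are 0-based half-open; the 1-based closed convention
#' of GTF/GFF3 is converted on read. Genes without any coding transcript are
#' retained but flagged non-coding. Transcripts whose CDS falls outside their
#' exons are flagged and excluded. Whether the CDS includes the stop codon is
#' recorded from the presence of separate `stop_codon` features
#' (`attr(ann, "stop_codon_convention")`).
#'
#' @param path a GTF2.2 or GFF3 file.
#' @return A named list of `GeneModel`s (class `RiboAnnotation`). Each
#'   `GeneModel` has `gene_id`, `transcripts`, `representative` (id or `NA`),
#'   `coding`.
#' @export
load_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("cannot parse annotation '", path,
                                          "': ", conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  if (!is.null(mc$transcript_id)) {          # GTF
    tx_id <- as.character(mc$transcript_id)
    gene_id <- as.character(mc$gene_id)
  } else if (!is.null(mc$Parent)) {          # GFF3: exon/CDS Parent = transcript
    tx_id <- as.character(S4Vectors::unstrsplit(mc$Parent, ","))
    par_of <- stats::setNames(as.character(S4Vectors::unstrsplit(mc$Parent, ",")),
                              as.character(mc$ID))
    gene_id <- ifelse(tx_id %in% names(par_of), unname(par_of[tx_id]), tx_id)
  } else stop("annotation carries neither gene_id/transcript_id nor ID/Parent")

  keep <- type %in% c("exon", "CDS")
  has_stop_feature <- any(type == "stop_codon")
  gr <- gr[keep]; type <- type[keep]; tx_id <- tx_id[keep]; gene_id <- gene_id[keep]
  if (!length(gr)) stop("no exon/CDS features found in ", path)

  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))

  genes <- list()
  excluded <- character(0)
  for (tid in unique(tx_id)) {
    i <- tx_id == tid
    gid <- gene_id[i][1]
    if (is.null(genes[[gid]]))
      genes[[gid]] <- list(gene_id = gid, transcripts = list(),
                           representative = NA_character_, coding = FALSE)
    ex <- i & type == "exon"; cd <- i & type == "CDS"
    t <- tryCatch(
      transcript_model(tid, gid, contig[i][1], strand[i][1],
                       start0[ex], end0[ex], start0[cd], end0[cd]),
      error = function(e) {
        warning("transcript ", tid, " excluded: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(t)) { excluded <- c(excluded, tid); next }
    genes[[gid]]$transcripts[[tid]] <- t
  }
  for (gid in names(genes)) {
    g <- genes[[gid]]
    g$coding <- length(g$transcripts) > 0L &&
      any(vapply(g$transcripts, `[[`, logical(1), "coding"))
    if (g$coding)
      g$representative <- select_representative(g)$transcript_id
    class(g) <- "GeneModel"
    genes[[gid]] <- g
  }
  structure(genes, class = "RiboAnnotation",
            stop_codon_convention = if (has_stop_feature) "excluded" else "included",
            excluded_transcripts = excluded)
}

#' @export
print.RiboAnnotation <- function(x, ...) {
  n_cod <- sum(vapply(x, `[[`, logical(1), "coding"))
  cat(sprintf("RiboAnnotation: %d genes (%d coding), stop codon %s in CDS\n",
              length(x), n_cod,
              if (identical(attr(x, "stop_codon_convention"), "included"))
                "included" else "not included"))
  invisible(x)
}

#' Representative transcripts of an annotation
#'
#' @param annotation a `RiboAnnotation`.
#' @return Named list of `TranscriptModel`s, one per coding gene.
#' @export
representative_transcripts <- function(annotation) {
  out <- list()
  for (g in annotation) {
    if (!g$coding) next
    out[[g$gene_id]] <- g$transcripts[[g$representative]]
  }
  out
}
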