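#' Median codon coverage of a CDS
#'
#' Codon coverage is the sum of the three nucleotide values of each codon.
#' Returns the median over internal codons, excluding the first 15 and last
#' 10 codons of the CDS; requires more than 25 codons.
#'
#' @param track one element of an `OccupancyTrackSet`.
#' @param t the matching [transcript_model()].
#' @param exclude_first,exclude_last codons trimmed at each CDS end
#'   (defaults 15 and 10).
#' @return Median codon coverage (numeric scalar).
#' @export
median_codon_coverage <- function(track, t, exclude_first = 15L,
                                  exclude_last = 10L) {
  stopifnot(t$coding, t$codon_ok)
  n_codons <- t$cds_length %/% 3L
  if (n_codons <= exclude_first + exclude_last)
    stop(structure(class = c("cds_too_short", "error", "condition"),
                   list(message = sprintf("CDS of %s has %d codons (need > %d)",
                                          t$transcript_id, n_codons,
                                          exclude_first + exclude_last),
                        call = sys.call(-1))))
  cds <- track$counts[(t$utr5_length + 1L):(t$utr5_length + t$cds_length)]
  codon_cov <- colSums(matrix(cds, nrow = 3L))
  stats::median(codon_cov[(exclude_first + 1L):(n_codons - exclude_last)])
}

#' Filter genes by expressed median codon coverage
#'
#' A gene is kept iff its median codon coverage is greater than zero in at
#' least one replicate.
#'
#' @param medians matrix or data.frame, genes in rows (rownames = gene ids),
#'   replicates in columns.
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(medians) {
  m <- as.matrix(medians)
  if (ncol(m) < 1L) stop("need at least one replicate")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  rownames(m)[apply(m, 1L, max) > 0]
}

#' Normalized metagene profile around the start or stop codon
#'
#' Per gene, coverage at each nucleotide of the window is normalized by one
#' third of the gene's median codon coverage, so a uniformly covered CDS
#' sits at 1. The summary is the across-gene median at each position.
#' Position 0 is the first nucleotide of the CDS for `anchor = "start"` and
#' the last nucleotide of the CDS for `anchor = "stop"` (positions > 0 are
#' then 3'UTR). Window positions outside a gene's transcript are absent
#' (`NA`) and excluded from that position's median, not zero-filled.
#'
#' @param tracks an `OccupancyTrackSet` (one sample).
#' @param annotation a `RiboAnnotation`.
#' @param anchor `"start"` or `"stop"`.
#' @param window `c(a, b)` nt offsets relative to the anchor; defaults
#'   `c(-30, 60)` for start and `c(-60, 30)` for stop.
#' @param genes optional character vector restricting the gene set (e.g. the
#'   output of [filter_expressed_genes()] across replicates). Genes with
#'   zero median codon coverage in *this* sample are dropped with a message
#'   (their normalization is undefined).
#' @return A `MetageneProfile`: list with `anchor`, `positions`, `per_gene`
#'   (genes x positions matrix of normalized coverage), `summary`
#'   (per-position median), `n_genes`.
#' @export
metagene_profile <- function(tracks, annotation, anchor = c("start", "stop"),
                             window = NULL, genes = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window))
    window <- if (anchor == "start") c(-30L, 60L) else c(-60L, 30L)
  reps <- representative_transcripts(annotation)
  use <- names(tracks)
  if (!is.null(genes)) use <- intersect(use, genes)
  use <- Filter(function(g) !is.null(reps[[g]]) && reps[[g]]$codon_ok, use)
  if (!length(use)) stop("empty gene list for metagene profile")

  positions <- window[1]:window[2]
  rows <- list()
  for (gid in use) {
    t <- reps[[gid]]
    n_codons <- t$cds_length %/% 3L
    if (n_codons <= 25L) next
    mcc <- median_codon_coverage(tracks[[gid]], t)
    if (mcc == 0) { message("gene ", gid, " has zero median codon coverage; dropped"); next }
    a <- if (anchor == "start") t$utr5_length else t$utr5_length + t$cds_length - 1L
    p <- a + positions
    v <- rep(NA_real_, length(positions))
    ok <- p >= 0L & p < t$tx_length
    v[ok] <- tracks[[gid]]$counts[p[ok] + 1L] / (mcc / 3)
    rows[[gid]] <- v
  }
  if (!length(rows)) stop("no gene passed the metagene filters")
  per_gene <- do.call(rbind, rows)
  colnames(per_gene) <- positions
  structure(list(anchor = anchor, positions = positions, per_gene = per_gene,
                 summary = apply(per_gene, 2L, stats::median, na.rm = TRUE),
                 n_genes = nrow(per_gene)),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile (%s anchor): %d genes, positions %d..%d\n",
              x$anchor, x$n_genes, min(x$positions), max(x$positions)))
  invisible(x)
}

#' Write a metagene profile as TSV
#'
#' Long format: per-gene normalized values plus a `.summary` row.
#'
#' @param profile a `MetageneProfile`.
#' @param path output file.
#' @export
write_metagene <- function(profile, path) {
  m <- rbind(profile$per_gene, .summary = profile$summary)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
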