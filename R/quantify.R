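#' Gene-level count from an occupancy track
#'
#' Sums calibrated occupancy over the coding sequence (`"cds"`, the default
#' for ribosome footprints, which are confined to the CDS) or over the whole
#' spliced transcript (`"exonic"`, the default for RNA-Seq).
#'
#' @param track one element of an `OccupancyTrackSet`.
#' @param t the matching [transcript_model()].
#' @param region `"cds"` or `"exonic"`.
#' @return Numeric count.
#' @export
count_gene <- function(track, t, region = c("cds", "exonic")) {
  region <- match.arg(region)
  if (region == "exonic" || !t$coding) return(sum(track$counts))
  sum(track$counts[(t$utr5_length + 1L):(t$utr5_length + t$cds_length)])
}

#' Reads per million
#'
#' @param count gene-level count(s).
#' @param library_total library size (all retained reads in the sample).
#' @return `count * 1e6 / library_total`.
#' @export
rpm <- function(count, library_total) {
  if (library_total <= 0) stop("library_total must be positive")
  count * 1e6 / library_total
}

#' Transcripts per million
#'
#' Length-normalized abundance: per-gene rate = count/length, scaled so the
#' rates sum to 1e6 across genes.
#'
#' @param counts numeric vector of gene counts.
#' @param lengths matching vector of effective lengths (nt), all positive.
#' @return Numeric vector of tpm values summing to 1e6 (all zero, with a
#'   warning, when every count is zero).
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("lengths must be positive")
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) {
    warning("all counts are zero; tpm undefined, returning zeros")
    return(rep(0, length(counts)))
  }
  rate * 1e6 / s
}

#' Translation efficiency
#'
#' TE = ribo_tpm / rna_tpm per gene; undefined (flagged, not zero) where
#' rna_tpm is zero or below `min_rna_tpm`.
#'
#' @param ribo_tpm,rna_tpm matched numeric vectors.
#' @param min_rna_tpm floor below which TE is marked undefined (default 0,
#'   i.e. only exact zeros are undefined).
#' @return `data.frame` with `te` and logical `defined`.
#' @export
translation_efficiency <- function(ribo_tpm, rna_tpm, min_rna_tpm = 0) {
  stopifnot(length(ribo_tpm) == length(rna_tpm))
  defined <- rna_tpm > min_rna_tpm & rna_tpm > 0
  te <- ifelse(defined, ribo_tpm / rna_tpm, NA_real_)
  data.frame(te = te, defined = defined)
}

#' Full gene quantification table for one sample/assay
#'
#' Convenience wrapper building the per-gene `count`, `rpm` and `tpm`
#' columns from an `OccupancyTrackSet`. The rpm denominator is the sample's
#' retained library size (pass `library_total` from [library_stats()]); tpm
#' lengths are CDS length for `assay = "ribo"` and spliced transcript length
#' for `assay = "rna"` (recorded in `length_used`).
#'
#' @param tracks an `OccupancyTrackSet`.
#' @param annotation a `RiboAnnotation`.
#' @param library_total retained reads in this library.
#' @param assay `"ribo"` or `"rna"`.
#' @param sample_id label stored in the table.
#' @return `data.frame` with `gene_id`, `sample_id`, `assay`, `count`,
#'   `rpm`, `tpm`, `length_used`.
#' @export
quantify_genes <- function(tracks, annotation, library_total,
                           assay = c("ribo", "rna"), sample_id = "sample") {
  assay <- match.arg(assay)
  reps <- representative_transcripts(annotation)
  gids <- intersect(names(tracks), names(reps))
  counts <- vapply(gids, function(g)
    count_gene(tracks[[g]], reps[[g]],
               region = if (assay == "ribo") "cds" else "exonic"),
    numeric(1))
  lens <- vapply(gids, function(g)
    if (assay == "ribo") reps[[g]]$cds_length else reps[[g]]$tx_length,
    numeric(1))
  data.frame(gene_id = gids, sample_id = sample_id, assay = assay,
             count = counts, rpm = rpm(counts, library_total),
             tpm = tpm(counts, lens), length_used = lens, row.names = NULL)
}

#' Read a gene -> homolog -> category map
#'
#' Three-column TSV (`gene_id`, `homolog_id`, `category`), one row per
#' homolog assignment; a gene may map to several homolog ids.
#'
#' @param path TSV file.
#' @return `data.frame` (class `CategoryMap`).
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "homolog_id", "category") %in% names(df)))
  structure(df, class = c("CategoryMap", "data.frame"))
}

#' Category-level ribosome occupancy with even homolog allocation
#'
#' Each gene's rpm is split evenly across its homolog ids (a gene mapped to
#' k homologs contributes rpm/k to each homolog's category), then summed by
#' category. Genes absent from the map accumulate in the `"unmapped"`
#' bucket, so total mass is conserved exactly.
#'
#' @param gene_rpm `data.frame` with `gene_id` and `rpm`.
#' @param map a `CategoryMap` (`gene_id`, `homolog_id`, `category`).
#' @return `data.frame` with `category`, `rpm_total`, `percent` (of the
#'   summed input rpm).
#' @export
category_occupancy <- function(gene_rpm, map) {
  total <- sum(gene_rpm$rpm)
  n_hom <- table(map$gene_id)
  acc <- list()
  add <- function(cat, x) acc[[cat]] <<- (if (is.null(acc[[cat]])) 0 else acc[[cat]]) + x
  for (i in seq_len(nrow(gene_rpm))) {
    g <- gene_rpm$gene_id[i]; r <- gene_rpm$rpm[i]
    rows <- which(map$gene_id == g)
    if (!length(rows)) { add("unmapped", r); next }
    share <- r / length(rows)
    for (j in rows) add(map$category[j], share)
  }
  cats <- names(acc)
  out <- data.frame(category = cats,
                    rpm_total = unlist(acc, use.names = FALSE))
  out$percent <- if (total > 0) out$rpm_total / total * 100 else 0
  out[order(-out$rpm_total), , drop = FALSE]
}
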