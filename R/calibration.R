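#' Estimate per-read-length A-site offsets
#'
#' For each read length L present in the profiles, scans candidate offsets
#' d in `candidate_window` and picks the d maximising the summed end count
#' at position (start codon - d), aggregated over all representative coding
#' transcripts. This exploits the initiation pile-up at the start codon:
#' 5' ends of footprints decoding the initiator codon sit exactly one
#' offset upstream of it. Ties go to the smallest d. Lengths whose total
#' end count inside the candidate window is below `min_signal` inherit the
#' modal offset of the confident lengths and are flagged low-confidence.
#'
#' @param profiles an `EndProfileSet` (Ribo-Seq).
#' @param annotation a `RiboAnnotation`.
#' @param candidate_window `c(lo, hi)` candidate offsets in nt; default
#'   `c(12, 18)`, standard footprint geometry around a ~30 nt fragment.
#' @param min_signal minimum window end count for a confident per-length
#'   estimate (default 10).
#' @return An `OffsetTable`: `data.frame` with `length`, `offset`,
#'   `confidence` (`"ok"` or `"low"`), `window_count`.
#' @export
estimate_offsets <- function(profiles, annotation,
                             candidate_window = c(12L, 18L),
                             min_signal = 10L) {
  lo <- candidate_window[1]; hi <- candidate_window[2]
  stopifnot(lo <= hi)
  reps <- representative_transcripts(annotation)
  lengths <- sort(unique(unlist(lapply(profiles, function(p)
    as.integer(names(p$counts))))))
  if (!length(lengths)) stop("insufficient calibration signal: no end counts")

  cand <- lo:hi
  score <- matrix(0, nrow = length(lengths), ncol = length(cand),
                  dimnames = list(lengths, cand))
  for (gid in names(profiles)) {
    t <- reps[[gid]]
    if (is.null(t) || !t$coding) next
    anchor <- t$utr5_length          # transcript coord of the start codon
    pos <- anchor - cand             # candidate end positions
    ok <- pos >= 0L & pos < t$tx_length
    if (!any(ok)) next
    cnts <- profiles[[gid]]$counts
    for (L in names(cnts)) {
      if (!L %in% rownames(score)) next
      score[L, ok] <- score[L, ok] + cnts[[L]][pos[ok] + 1L]
    }
  }

  window_count <- rowSums(score)
  best <- cand[apply(score, 1L, which.max)]   # which.max: first max = smallest d
  confident <- window_count >= min_signal
  if (!any(confident)) stop("insufficient calibration signal")
  # modal offset among confident lengths for the fallback
  tb <- table(best[confident])
  modal <- as.integer(names(tb)[which.max(tb)])
  offset <- ifelse(confident, best, modal)
  data.frame(length = lengths, offset = as.integer(offset),
             confidence = ifelse(confident, "ok", "low"),
             window_count = as.numeric(window_count), row.names = NULL)
}

#' Shift end profiles to calibrated A-site occupancy
#'
#' Each end count at transcript position p with read length L contributes
#' one unit of occupancy at p + offset(L). Counts shifted beyond the
#' transcript end are dropped and tallied in the `"dropped"` attribute;
#' total occupancy mass equals input mass minus dropped.
#'
#' @param profiles an `EndProfileSet`.
#' @param offsets an `OffsetTable` from [estimate_offsets()] covering every
#'   read length present.
#' @return An `OccupancyTrackSet`: named list (by gene) of lists with
#'   `transcript_id`, `tx_length`, `counts` (numeric vector over transcript
#'   positions); attribute `dropped` = total counts shifted off transcripts.
#' @export
apply_offsets <- function(profiles, offsets) {
  off <- stats::setNames(offsets$offset, as.character(offsets$length))
  dropped <- 0
  tracks <- lapply(profiles, function(p) {
    occ <- numeric(p$tx_length)
    for (L in names(p$counts)) {
      if (is.na(off[L])) stop("no offset for read length ", L)
      d <- off[[L]]
      v <- p$counts[[L]]
      nz <- which(v > 0L)
      if (!length(nz)) next
      newpos <- nz - 1L + d
      keep <- newpos < p$tx_length & newpos >= 0L
      dropped <<- dropped + sum(v[nz[!keep]])
      occ[newpos[keep] + 1L] <- occ[newpos[keep] + 1L] + v[nz[keep]]
    }
    list(transcript_id = p$transcript_id, gene_id = p$gene_id,
         tx_length = p$tx_length, counts = occ)
  })
  structure(tracks, class = "OccupancyTrackSet", dropped = dropped)
}

#' Reading-frame (codon) periodicity of an occupancy track
#'
#' Fraction of CDS occupancy falling on each codon sub-position: f_k is the
#' summed coverage at CDS positions congruent to k (mod 3) divided by the
#' total CDS coverage.
#'
#' @param track one element of an `OccupancyTrackSet`.
#' @param t the matching [transcript_model()]; must be coding with a CDS
#'   length divisible by 3.
#' @return Named numeric vector `c(f0 = , f1 = , f2 = )`.
#' @export
frame_periodicity <- function(track, t) {
  stopifnot(t$coding)
  if (!t$codon_ok) stop("CDS of ", t$transcript_id, " is not a codon multiple")
  cds <- track$counts[(t$utr5_length + 1L):(t$utr5_length + t$cds_length)]
  tot <- sum(cds)
  if (tot == 0)
    stop(structure(class = c("no_coverage", "error", "condition"),
                   list(message = paste0("no CDS coverage on ", t$transcript_id),
                        call = sys.call(-1))))
  k <- (seq_along(cds) - 1L) %% 3L
  c(f0 = sum(cds[k == 0L]), f1 = sum(cds[k == 1L]), f2 = sum(cds[k == 2L])) / tot
}

#' Pooled reading-frame periodicity across genes
#'
#' Coverage-weighted aggregate: total per-frame CDS coverage over all coding
#' genes, divided by total CDS coverage. Algebraically the coverage-weighted
#' mean of the per-transcript fractions.
#'
#' @param tracks an `OccupancyTrackSet`.
#' @param annotation a `RiboAnnotation`.
#' @return Named numeric vector `c(f0, f1, f2)`.
#' @export
pooled_periodicity <- function(tracks, annotation) {
  reps <- representative_transcripts(annotation)
  acc <- c(f0 = 0, f1 = 0, f2 = 0)
  for (gid in names(tracks)) {
    t <- reps[[gid]]
    if (is.null(t) || !t$codon_ok) next
    cds <- tracks[[gid]]$counts[(t$utr5_length + 1L):(t$utr5_length + t$cds_length)]
    k <- (seq_along(cds) - 1L) %% 3L
    acc <- acc + c(sum(cds[k == 0L]), sum(cds[k == 1L]), sum(cds[k == 2L]))
  }
  if (sum(acc) == 0) stop("no CDS coverage in any gene")
  acc / sum(acc)
}

#' Write an offset table as TSV
#' @param offsets an `OffsetTable`.
#' @param path output file.
#' @export
write_offsets <- function(offsets, path) {
  utils::write.table(offsets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(offsets)
}

#' Read an offset table from TSV
#' @param path file written by [write_offsets()].
#' @return An `OffsetTable` data.frame.
#' @export
read_offsets <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
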