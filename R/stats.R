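#' Log2 fold change with pseudocount
#'
#' log2((mean_b + eps) / (mean_a + eps)); the pseudocount guards zeros.
#'
#' @param mean_a,mean_b condition means (e.g. rpm), vectorised.
#' @param pseudocount eps, default 0.5.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Two-sample two-tailed Student's t test for category fractions
#'
#' Classical equal-variance t by default (Welch optional). Degenerate
#' zero-variance inputs are handled explicitly: equal means give p = 1, and
#' different means with no variance are flagged degenerate with p = 0.
#'
#' @param a,b numeric replicate vectors (>= 2 each).
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return list with `p`, `t`, `df`, `degenerate`.
#' @export
category_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 replicates per side")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(b) - mean(a)
  if (va == 0 && vb == 0) {
    if (d == 0) return(list(p = 1, t = 0, df = na + nb - 2L, degenerate = TRUE))
    return(list(p = 0, t = sign(d) * Inf, df = na + nb - 2L, degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- d / se
  list(p = 2 * stats::pt(-abs(tstat), df), t = tstat, df = df,
       degenerate = FALSE)
}

#' Deviation test of one gene's TE against the endogenous distribution
#'
#' Standardizes log2(TE) of the gene against the mean and standard deviation
#' of the endogenous log2-TE sample and returns a two-tailed p from the t
#' distribution with n - 1 degrees of freedom. Under the hypothesis that
#' recombinant and endogenous genes share the same translation-efficiency
#' distribution the test is calibrated at its nominal level.
#'
#' @param te_gene the gene's TE (linear scale, > 0).
#' @param endo_log2_te numeric vector of endogenous log2 TE values
#'   (length >= 30).
#' @return list with `p`, `z` (standardized deviate), `df`.
#' @export
te_deviation_test <- function(te_gene, endo_log2_te) {
  if (is.na(te_gene) || te_gene <= 0) stop("TE undefined or non-positive")
  n <- length(endo_log2_te)
  if (n < 30L) stop("endogenous sample too small (need >= 30)")
  z <- (log2(te_gene) - mean(endo_log2_te)) / stats::sd(endo_log2_te)
  list(p = 2 * stats::pt(-abs(z), df = n - 1L), z = z, df = n - 1L)
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p numeric vector of p values in [0, 1].
#' @return q values in the input order; monotone non-decreasing in p rank.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

# Weighted running-sum enrichment score for hit positions `hits` (sorted
# indices into the ranked list) with weights w (|score|^weight at the hits).
# The running sum only attains extremes immediately before/after hits, so it
# is evaluated there in O(|hits|).
.es_from_hits <- function(hits, w, n) {
  k <- length(hits)
  miss_dec <- 1 / (n - k)
  wsum <- sum(w)
  if (wsum == 0) { w <- rep(1 / k, k); wsum <- 1 } else w <- w / wsum
  cw <- cumsum(w)
  after <- cw - (hits - seq_len(k)) * miss_dec          # just after each hit
  before <- c(0, cw[-k]) - (hits - 1 - (seq_len(k) - 1)) * miss_dec
  ext <- c(after, before)
  ext[which.max(abs(ext))]
}

#' Pre-ranked gene-set enrichment with a permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic over a ranked gene
#' list: walking down the ranking, set members ("hits") increment the sum
#' proportionally to |score|^weight (normalized over hits) and non-members
#' decrement it by 1/(N - Nh). The enrichment score (ES) is the extremum of
#' maximal absolute deviation. The null distribution comes from random gene
#' sets of the same size; p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1).
#'
#' @param scores named numeric vector of per-gene ranking scores (any
#'   order; ranked internally, decreasing).
#' @param gene_set character vector; must be a non-empty strict subset of
#'   the ranked genes (members outside the ranking are ignored).
#' @param weight exponent on |score| for hit increments; 0 gives the
#'   classical unweighted KS statistic, 1 (default) the weighted one.
#' @param n_perm number of random-set permutations (default 1000).
#' @param seed RNG seed, mandatory for reproducibility.
#' @return An `EnrichmentResult` list: `es`, `p_perm`, `n_perm`, `size`,
#'   `null_es` (vector), `seed`.
#' @export
preranked_enrichment <- function(scores, gene_set, weight = 1,
                                 n_perm = 1000L, seed) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  o <- order(scores, decreasing = TRUE)
  ranked <- scores[o]
  genes <- names(ranked)
  hits <- which(genes %in% gene_set)
  n <- length(genes)
  if (length(hits) == 0L || length(hits) >= n)
    stop("gene set must be a non-empty strict subset of the ranked genes")
  wabs <- abs(ranked)^weight
  es <- .es_from_hits(hits, wabs[hits], n)
  set.seed(seed)
  k <- length(hits)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- sort(sample.int(n, k))
    .es_from_hits(h, wabs[h], n)
  }, numeric(1))
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  structure(list(es = es, p_perm = p, n_perm = n_perm, size = k,
                 null_es = null_es, seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: ES = %.3f, p = %.4g (%d permutations, set size %d)\n",
              x$es, x$p_perm, x$n_perm, x$size))
  invisible(x)
}

#' Enrichment over a collection of gene sets, with BH FDR
#'
#' Runs [preranked_enrichment()] per set (seeds derived deterministically
#' from `seed`) and adjusts the permutation p values with [bh_fdr()].
#'
#' @param scores named numeric vector of ranking scores.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param weight,n_perm as in [preranked_enrichment()].
#' @param seed base RNG seed.
#' @param fdr_threshold significance flag threshold (default 0.25).
#' @return `data.frame` with `set_id`, `size`, `es`, `p_perm`, `fdr`,
#'   `significant`.
#' @export
gsea_preranked <- function(scores, gene_sets, weight = 1, n_perm = 1000L,
                           seed, fdr_threshold = 0.25) {
  if (missing(seed)) stop("a seed is required")
  res <- lapply(seq_along(gene_sets), function(i)
    preranked_enrichment(scores, gene_sets[[i]], weight = weight,
                         n_perm = n_perm, seed = seed + i))
  out <- data.frame(
    set_id = names(gene_sets),
    size = vapply(res, `[[`, numeric(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
    row.names = NULL)
  out$fdr <- bh_fdr(out$p_perm)
  out$significant <- out$fdr < fdr_threshold
  out
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control); fold change = 2^(-ddCt).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (finite).
#' @return list with `ddct`, `fold` and `percent_knockdown`
#'   ((1 - fold) x 100).
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  fold <- 2^(-dd)
  list(ddct = dd, fold = fold, percent_knockdown = (1 - fold) * 100)
}
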