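#' Read a batch-culture time series
#'
#' CSV with columns `time_d`, `vcd_per_ml`, `viability_pct`, `titer_ug_ml`,
#' optional `glucose_g_l`, `lactate_g_l`, and `replicate`.
#'
#' @param path CSV file.
#' @return `data.frame` (class `CultureSeries`), sorted by replicate and
#'   time.
#' @export
read_culture <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_d", "vcd_per_ml", "titer_ug_ml")
  if (!all(need %in% names(df)))
    stop("culture CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(df$replicate)) df$replicate <- 1L
  df <- df[order(df$replicate, df$time_d), , drop = FALSE]
  for (r in unique(df$replicate)) {
    tt <- df$time_d[df$replicate == r]
    if (any(diff(tt) <= 0)) stop("time must be strictly increasing per replicate")
  }
  structure(df, class = c("CultureSeries", "data.frame"))
}

.window_rows <- function(series, window, replicate = NULL) {
  i <- series$time_d >= window[1] & series$time_d <= window[2]
  if (!is.null(replicate)) i <- i & series$replicate == replicate
  which(i)
}

#' Specific growth rate over a phase window
#'
#' Least-squares slope of ln(VCD) versus time over the window (1/day).
#'
#' @param series a [read_culture()] `CultureSeries` (one replicate, or pass
#'   `replicate`).
#' @param window `c(t_start, t_end)` in days.
#' @param replicate optional replicate id to subset.
#' @return Growth rate mu in 1/day.
#' @export
specific_growth_rate <- function(series, window, replicate = NULL) {
  i <- .window_rows(series, window, replicate)
  if (length(i) < 2L) stop("window must contain >= 2 samples")
  if (any(series$vcd_per_ml[i] <= 0)) stop("non-positive VCD in window")
  unname(stats::coef(stats::lm(log(series$vcd_per_ml[i]) ~ series$time_d[i]))[2])
}

#' Integral viable cell density
#'
#' Cumulative trapezoidal integral of VCD over time, in cell.day/mL, at
#' each time point (starting at 0).
#'
#' @param series a `CultureSeries` restricted to one replicate (or pass
#'   `replicate`).
#' @param replicate optional replicate id to subset.
#' @return Numeric vector of cumulative IVCD, same length as the series.
#' @export
ivcd <- function(series, replicate = NULL) {
  i <- if (is.null(replicate)) seq_len(nrow(series)) else
    which(series$replicate == replicate)
  if (length(i) < 2L) stop("need >= 2 points")
  tt <- series$time_d[i]; v <- series$vcd_per_ml[i]
  c(0, cumsum(diff(tt) * (utils::head(v, -1) + utils::tail(v, -1)) / 2))
}

#' Specific productivity by regression of titer on IVCD
#'
#' q_p is the least-squares slope of titer (ug/mL) versus integral viable
#' cell density (cell.day/mL) over the phase window, converted to
#' pg/cell/day (x 1e6). With `mode = "pooled"` all replicates' points enter
#' one regression; with `mode = "per_replicate"` slopes are fitted per
#' replicate and averaged (mean, with SD reported).
#'
#' @param series a `CultureSeries`.
#' @param window `c(t_start, t_end)` days.
#' @param mode `"pooled"` or `"per_replicate"`.
#' @return list with `qp` (pg/cell/day), `intercept`, `r_squared`, and for
#'   per-replicate mode `qp_sd` and `qp_by_replicate`.
#' @export
specific_productivity <- function(series, window,
                                  mode = c("pooled", "per_replicate")) {
  mode <- match.arg(mode)
  reps <- unique(series$replicate)
  per_rep <- lapply(reps, function(r) {
    i <- which(series$replicate == r)
    I <- ivcd(series, replicate = r)
    w <- series$time_d[i] >= window[1] & series$time_d[i] <= window[2]
    if (sum(w) < 2L) stop("window must contain >= 2 samples per replicate")
    data.frame(ivcd = I[w], titer = series$titer_ug_ml[i][w])
  })
  fit1 <- function(df) {
    if (diff(range(df$ivcd)) == 0) stop("degenerate IVCD: no growth and no time span")
    fit <- stats::lm(titer ~ ivcd, data = df)
    # summary.lm warns on exact fits (noise-free simulations); harmless
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = suppressWarnings(summary(fit)$r.squared))
  }
  if (mode == "pooled") {
    f <- fit1(do.call(rbind, per_rep))
    list(qp = f$slope * 1e6, intercept = f$intercept, r_squared = f$r2)
  } else {
    fits <- lapply(per_rep, fit1)
    qps <- vapply(fits, function(f) f$slope * 1e6, numeric(1))
    list(qp = mean(qps), qp_sd = stats::sd(qps),
         qp_by_replicate = stats::setNames(qps, reps),
         intercept = mean(vapply(fits, `[[`, numeric(1), "intercept")),
         r_squared = mean(vapply(fits, `[[`, numeric(1), "r2")))
  }
}
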