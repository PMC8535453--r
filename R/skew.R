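# Sliding-window CG- and AT-skew along CDSs, anchored at the 5'-end, with
# cross-CDS aggregation and least-squares trend slopes. Positive CG-skew
# means C is enriched over G; positive AT-skew means A over T.

.base_cumsums <- function(seq) {
  b <- strsplit(seq, "")[[1L]]
  list(a = cumsum(b == "A"), t = cumsum(b == "T"),
       g = cumsum(b == "G"), c = cumsum(b == "C"))
}

.window_counts <- function(cs, starts, window) {
  ends <- starts + window - 1L
  f <- function(v) v[ends] - c(0L, v)[starts]
  list(a = f(cs$a), t = f(cs$t), g = f(cs$g), c = f(cs$c))
}

#' Sliding-window skews of one sequence
#'
#' Windows of `window` bp are slid along the sequence in steps of `step`
#' bp, anchored at the 5'-end; a window at start s covers bases
#' s..s+window-1 and is emitted while it fits entirely. `cg_skew` is
#' (C-G)/(C+G) and `at_skew` is (A-T)/(A+T) over the window's base
#' counts; a skew with zero denominator is `NA`.
#'
#' @param seq A single nucleotide sequence of length >= `window`.
#' @param window Window size in bp (default 100).
#' @param step Step size in bp (default 1).
#' @return Data frame with columns `start`, `a`, `t`, `g`, `c`,
#'   `cg_skew`, `at_skew`.
#' @examples
#' window_skews(strrep("C", 120))[1, "cg_skew"]
#' @export
window_skews <- function(seq, window = 100L, step = 1L) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (window < 1L || step < 1L) stop("'window' and 'step' must be >= 1")
  n <- nchar(seq)
  if (n < window) stop("sequence shorter than the window")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT symbols")
  starts <- seq.int(1L, n - window + 1L, by = step)
  cs <- .base_cumsums(seq)
  w <- .window_counts(cs, starts, window)
  cg_den <- w$c + w$g
  at_den <- w$a + w$t
  data.frame(
    start = starts, a = w$a, t = w$t, g = w$g, c = w$c,
    cg_skew = ifelse(cg_den > 0, (w$c - w$g) / cg_den, NA_real_),
    at_skew = ifelse(at_den > 0, (w$a - w$t) / at_den, NA_real_)
  )
}

.ols_slope <- function(x, y) {
  ok <- !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cov(x[ok], y[ok]) / stats::var(x[ok])
}

#' Aggregate skew profile of a CDS set
#'
#' Per-CDS sliding-window skews ([window_skews()]) are averaged across
#' CDSs at each 5'-anchored window start (unweighted mean over the CDSs
#' long enough to contain the window and whose skew is defined). Trend
#' slopes of the mean skews versus window start are estimated by ordinary
#' least squares over the reported positions; optionally their standard
#' errors are estimated by bootstrap resampling of CDSs.
#'
#' @param x A [cds_set()].
#' @param max_len Last window start reported, in bp (default 1000).
#' @param window,step Passed to [window_skews()].
#' @param min_coverage Minimum contributing CDSs per reported position
#'   (default 30).
#' @param n_boot Bootstrap replicates for slope standard errors
#'   (default 0 = none).
#' @param seed Optional RNG seed for the bootstrap.
#' @return List of class `skew_profile`: `profile` (data frame `position`,
#'   `n_cds`, `n_cg`, `n_at`, `mean_cg_skew`, `mean_at_skew`),
#'   `slope_cg`, `slope_at` (per bp) and, when `n_boot > 0`, `se_cg`,
#'   `se_at`.
#' @export
aggregate_skew_profile <- function(x, max_len = 1000L, window = 100L,
                                   step = 1L, min_coverage = 30L,
                                   n_boot = 0L, seed = NULL) {
  stopifnot(inherits(x, "cds_set"))
  if (length(x$id) == 0L) stop("empty CDS set")
  if (!is.null(seed)) set.seed(seed)
  starts <- seq.int(1L, max_len, by = step)
  n_pos <- length(starts)
  n <- length(x$id)
  CG <- matrix(NA_real_, n, n_pos)
  AT <- matrix(NA_real_, n, n_pos)
  for (i in seq_len(n)) {
    if (x$length[i] < window) next
    ws <- window_skews(x$seq[i], window = window, step = step)
    k <- min(nrow(ws), n_pos)
    CG[i, seq_len(k)] <- ws$cg_skew[seq_len(k)]
    AT[i, seq_len(k)] <- ws$at_skew[seq_len(k)]
  }
  covering <- outer(x$length, starts + window - 1L, ">=")
  n_cds <- colSums(covering)
  n_cg <- colSums(!is.na(CG))
  n_at <- colSums(!is.na(AT))
  keep <- n_cds >= min_coverage
  if (!any(keep)) {
    warning("no position meets the coverage requirement")
  }
  mean_cg <- colMeans(CG, na.rm = TRUE)
  mean_at <- colMeans(AT, na.rm = TRUE)
  mean_cg[n_cg == 0L] <- NA_real_
  mean_at[n_at == 0L] <- NA_real_

  prof <- data.frame(
    position = starts[keep], n_cds = n_cds[keep],
    n_cg = n_cg[keep], n_at = n_at[keep],
    mean_cg_skew = mean_cg[keep], mean_at_skew = mean_at[keep]
  )
  rownames(prof) <- NULL
  slope_cg <- .ols_slope(prof$position, prof$mean_cg_skew)
  slope_at <- .ols_slope(prof$position, prof$mean_at_skew)

  out <- list(profile = prof, slope_cg = slope_cg, slope_at = slope_at,
              window = window, step = step)
  if (n_boot > 0L) {
    CG0 <- CG; CG0[is.na(CG)] <- 0
    AT0 <- AT; AT0[is.na(AT)] <- 0
    MCG <- (!is.na(CG)) + 0
    MAT <- (!is.na(AT)) + 0
    W <- stats::rmultinom(n_boot, size = n, prob = rep(1 / n, n))
    bm_cg <- crossprod(CG0, W) / crossprod(MCG, W)
    bm_at <- crossprod(AT0, W) / crossprod(MAT, W)
    pos <- prof$position
    sl_cg <- apply(bm_cg[keep, , drop = FALSE], 2L, .ols_slope, x = pos)
    sl_at <- apply(bm_at[keep, , drop = FALSE], 2L, .ols_slope, x = pos)
    out$se_cg <- stats::sd(sl_cg, na.rm = TRUE)
    out$se_at <- stats::sd(sl_at, na.rm = TRUE)
    out$n_boot <- n_boot
  }
  class(out) <- "skew_profile"
  out
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("Skew profile: %d positions (window %d bp, step %d bp)\n",
              nrow(x$profile), x$window, x$step))
  cat(sprintf("  CG-skew slope: %.3g per bp", x$slope_cg))
  if (!is.null(x$se_cg)) cat(sprintf(" (bootstrap SE %.3g)", x$se_cg))
  cat("\n")
  cat(sprintf("  AT-skew slope: %.3g per bp", x$slope_at))
  if (!is.null(x$se_at)) cat(sprintf(" (bootstrap SE %.3g)", x$se_at))
  cat("\n")
  invisible(x)
}

#' @export
plot.skew_profile <- function(x, ...) {
  p <- x$profile
  rng <- range(c(p$mean_cg_skew, p$mean_at_skew), na.rm = TRUE)
  graphics::plot(p$position, p$mean_cg_skew, type = "l", lwd = 2,
                 col = "firebrick", ylim = rng,
                 xlab = "window start (bp from 5' end)",
                 ylab = "mean skew", ...)
  graphics::lines(p$position, p$mean_at_skew, lwd = 2, col = "steelblue")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = c("CG-skew", "AT-skew"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}
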