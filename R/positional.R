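# Left-aligned positional analysis: CDSs as rows, codon positions as
# columns (terminal stop excluded), hydrogen bonds per codon, bootstrap
# confidence bands over CDS resamples, and the cheap/expensive crossing.

# genes x max_pos matrix of hydrogen bonds (NA beyond each CDS's length);
# a terminal stop codon is excluded from the matrix
.hbond_matrix <- function(x, max_pos) {
  n_codons <- x$length %/% 3L
  has_stop <- substring(x$seq, x$length - 2L, x$length) %in% STOP_CODONS
  n_codons <- n_codons - as.integer(has_stop)
  H <- matrix(NA_real_, nrow = length(x$id), ncol = max_pos,
              dimnames = list(x$id, NULL))
  for (i in seq_along(x$id)) {
    k <- min(n_codons[i], max_pos)
    if (k < 1L) next
    cod <- .split_codons(substring(x$seq[i], 1L, 3L * k))
    H[i, seq_len(k)] <- hbonds_per_codon(cod)
  }
  H
}

#' Positional hydrogen-bond profile
#'
#' CDSs are left-aligned from the start codon and arranged as a matrix
#' with codon positions as columns (the terminal stop excluded). For every
#' position covered by at least `min_coverage` CDSs the profile reports
#' the mean number of hydrogen bonds, a percentile bootstrap confidence
#' interval obtained by resampling whole CDSs (rows) with replacement, and
#' the fraction of expensive codons (8-9 bonds).
#'
#' @param x A [cds_set()].
#' @param max_pos Last codon position profiled (default 500).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param min_coverage Minimum CDSs covering a reported position
#'   (default 30).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Data frame of class `positional_profile` with columns
#'   `position`, `n_cds`, `mean_hbonds`, `ci_low`, `ci_high`,
#'   `expensive_fraction`.
#' @export
positional_profile <- function(x, max_pos = 500L, n_boot = 1000L,
                               min_coverage = 30L, conf = 0.95,
                               seed = NULL) {
  stopifnot(inherits(x, "cds_set"))
  if (max_pos < 1L) stop("'max_pos' must be at least 1")
  if (length(x$id) == 0L) stop("empty CDS set")
  if (!is.null(seed)) set.seed(seed)

  H <- .hbond_matrix(x, max_pos)
  covered <- !is.na(H)
  n_cds <- colSums(covered)
  keep <- n_cds >= min_coverage
  if (!any(keep)) stop("no position meets the coverage requirement")

  H0 <- H
  H0[!covered] <- 0
  mean_hb <- colSums(H0) / n_cds
  exp_frac <- colSums((H >= 8) & covered, na.rm = TRUE) / n_cds

  # multinomial-weight bootstrap == resampling CDS rows with replacement
  n <- nrow(H)
  W <- stats::rmultinom(n_boot, size = n, prob = rep(1 / n, n))
  boot_means <- crossprod(H0, W) / crossprod(covered + 0, W)
  alpha <- (1 - conf) / 2
  ci <- apply(boot_means, 1L, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)

  out <- data.frame(
    position = which(keep),
    n_cds = n_cds[keep],
    mean_hbonds = mean_hb[keep],
    ci_low = ci[1L, keep],
    ci_high = ci[2L, keep],
    expensive_fraction = exp_frac[keep]
  )
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "conf") <- conf
  class(out) <- c("positional_profile", "data.frame")
  out
}

#' @export
plot.positional_profile <- function(x, ...) {
  graphics::plot(x$position, x$mean_hbonds, type = "l", lwd = 2,
                 col = "steelblue", xlab = "codon position",
                 ylab = "mean hydrogen bonds", ...)
  graphics::polygon(c(x$position, rev(x$position)),
                    c(x$ci_low, rev(x$ci_high)), border = NA,
                    col = grDevices::adjustcolor("steelblue", 0.25))
  graphics::lines(x$position, x$mean_hbonds, lwd = 2, col = "steelblue")
  invisible(x)
}

#' Cheap/expensive crossing position
#'
#' The smallest codon position at which the expensive-codon fraction first
#' drops to at most `threshold` and remains there for `run_length`
#' consecutive reported positions (a run that extends to the end of the
#' profile also qualifies). Returns `NA` if the fraction never settles
#' below the threshold.
#'
#' @param profile A [positional_profile()] data frame.
#' @param threshold Crossing threshold (default 0.5).
#' @param run_length Required run of positions at or below the threshold
#'   (default 10).
#' @return Integer position or `NA`.
#' @export
crossing_position <- function(profile, threshold = 0.5, run_length = 10L) {
  stopifnot(is.data.frame(profile))
  below <- profile$expensive_fraction <= threshold
  if (!any(below)) return(NA_integer_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths >= run_length | ends == length(below))
  if (!any(ok)) return(NA_integer_)
  profile$position[starts[which(ok)[1L]]]
}
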