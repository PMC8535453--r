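# Optimal-codon identification: pool codon counts of the genes at the two
# extremes of CA axis 1 and test each of the 59 candidate codons with a
# 2x2 Pearson chi-square (codon vs other synonyms, high vs low set).

#' Construct pooled high/low bias datasets
#'
#' Low-level constructor used by [select_extreme_genes()] and directly in
#' simulations: pooled codon counts of a high-bias and a low-bias gene
#' set.
#'
#' @param counts_high,counts_low Named count vectors over the 61 sense
#'   codons (pooled over the genes of each set).
#' @param high_ids,low_ids Optional gene id vectors (must be disjoint).
#' @param noninformative Logical flag set when the ranking that produced
#'   the sets carried no information.
#' @return List of class `bias_datasets`.
#' @export
bias_datasets <- function(counts_high, counts_low,
                          high_ids = NULL, low_ids = NULL,
                          noninformative = FALSE) {
  counts_high <- counts_high[SENSE_CODONS]
  counts_low <- counts_low[SENSE_CODONS]
  if (anyNA(counts_high) || anyNA(counts_low)) {
    stop("counts must cover the 61 sense codons")
  }
  if (!is.null(high_ids) && !is.null(low_ids) &&
      length(intersect(high_ids, low_ids))) {
    stop("high and low gene sets must be disjoint")
  }
  structure(
    list(counts_high = counts_high, counts_low = counts_low,
         high_ids = high_ids, low_ids = low_ids,
         gc3s_high = composition_indices(counts_high)$gc3s,
         gc3s_low = composition_indices(counts_low)$gc3s,
         noninformative = noninformative),
    class = "bias_datasets"
  )
}

#' Select the axis-1 extreme gene sets
#'
#' Ranks genes by their axis-1 CA coordinate and takes the
#' `ceiling(fraction * N)` genes from each end as putative high- and
#' low-bias (expression proxy) datasets. Because the CA axis sign is
#' arbitrary, the end whose pooled GC3s is larger is labelled the
#' high-bias set (override with `high_end`). If all coordinates are equal
#' the selection is flagged non-informative.
#'
#' @param coa A [run_coa()] result on the gene RSCU matrix.
#' @param counts Genes x 61 codon count matrix ([codon_count_matrix()] or
#'   the `counts` attribute of [gene_profiles()]), rows matched to the CA
#'   by gene id.
#' @param fraction Fraction of genes per extreme (default 0.05).
#' @param high_end Either `"gc3s"` (orient by pooled GC3s, the default),
#'   `"right"` or `"left"` (force an end).
#' @return A [bias_datasets()] object.
#' @export
select_extreme_genes <- function(coa, counts, fraction = 0.05,
                                 high_end = c("gc3s", "right", "left")) {
  stopifnot(inherits(coa, "coa"))
  high_end <- match.arg(high_end)
  if (inherits(counts, "gene_profiles")) counts <- attr(counts, "counts")
  ax1 <- if (ncol(coa$row_coords) < 1L) {
    # degenerate CA (zero inertia): every gene sits at the origin
    stats::setNames(rep(0, nrow(coa$row_coords)),
                    rownames(coa$row_coords))
  } else {
    coa$row_coords[, 1L]
  }
  n <- length(ax1)
  n_sel <- ceiling(fraction * n)
  if (2L * n_sel > n) stop("too few genes for fraction ", fraction)
  idx <- match(names(ax1), rownames(counts))
  if (anyNA(idx)) stop("CA rows not found in count matrix")
  counts <- counts[idx, , drop = FALSE]

  ord <- order(ax1)
  left_ids <- names(ax1)[ord[seq_len(n_sel)]]
  right_ids <- names(ax1)[ord[seq.int(n - n_sel + 1L, n)]]
  noninf <- stats::sd(ax1) == 0
  if (noninf) warning("all axis-1 coordinates identical; selection is non-informative")

  pool <- function(ids) colSums(counts[ids, , drop = FALSE])
  cl <- pool(left_ids)
  cr <- pool(right_ids)
  gc3s_l <- composition_indices(cl)$gc3s
  gc3s_r <- composition_indices(cr)$gc3s
  right_is_high <- switch(high_end,
    gc3s = isTRUE(gc3s_r >= gc3s_l),
    right = TRUE,
    left = FALSE
  )
  if (right_is_high) {
    bias_datasets(cr, cl, right_ids, left_ids, noninformative = noninf)
  } else {
    bias_datasets(cl, cr, left_ids, right_ids, noninformative = noninf)
  }
}

# 2x2 table for one codon: count vs other synonyms, high vs low set
.codon_table <- function(b, codon) {
  aa <- AA_OF_CODON[codon]
  fam <- SENSE_CODONS[AA_OF_CODON == aa]
  others <- setdiff(fam, codon)
  matrix(c(b$counts_high[codon], sum(b$counts_high[others]),
           b$counts_low[codon], sum(b$counts_low[others])),
         nrow = 2L,
         dimnames = list(c("codon", "other_synonyms"), c("high", "low")))
}

#' Two-way chi-square test for one codon
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' codon count versus the count of its other synonyms, in the high-bias
#' versus low-bias set. Tables with an empty margin are not testable and
#' return `NA` with a `reason` attribute. A warning is attached when an
#' expected cell count falls below 5.
#'
#' @param b A [bias_datasets()] object.
#' @param codon A single codon from a family of size >= 2.
#' @return Named numeric vector `c(chi2, p)` with attribute `table`.
#' @examples
#' # identical usage in both sets: no association
#' cts <- count_codons(paste(c(rep(c("TTT", "TTC"), 20), "TAA"), collapse = ""))
#' b <- bias_datasets(cts, cts)
#' chi_square_codon_test(b, "TTC")
#' @export
chi_square_codon_test <- function(b, codon) {
  stopifnot(inherits(b, "bias_datasets"), length(codon) == 1L)
  if (!codon %in% SYN_CODONS) {
    stop("codon ", codon, " is not in a synonymous family of size >= 2")
  }
  tab <- .codon_table(b, codon)
  rm_ <- rowSums(tab)
  cm_ <- colSums(tab)
  if (any(rm_ == 0) || any(cm_ == 0)) {
    out <- c(chi2 = NA_real_, p = NA_real_)
    attr(out, "table") <- tab
    attr(out, "reason") <- "empty margin"
    return(out)
  }
  n <- sum(tab)
  chi2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rm_, cm_)
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  out <- c(chi2 = chi2, p = p)
  attr(out, "table") <- tab
  expected <- outer(rm_, cm_) / n
  if (any(expected < 5)) attr(out, "small_expected") <- TRUE
  out
}

#' Call optimal codons
#'
#' A codon is optimal when its chi-square p-value is below `alpha` and its
#' within-family relative frequency is higher in the high-bias set. All 59
#' candidate codons are reported; untestable codons carry `NA` statistics.
#' No multiple-testing correction is applied by default, matching the raw
#' p < 0.01 convention; `correction = "bonferroni"` adjusts over the
#' testable codons.
#'
#' @param b A [bias_datasets()] object.
#' @param alpha Significance level (default 0.01).
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return Data frame of class `optimal_codons`, one row per candidate
#'   codon: amino acid, the 2x2 table entries, `chi2`, `p`, within-family
#'   frequencies and RSCU in both sets, and the `optimal` flag.
#' @export
call_optimal_codons <- function(b, alpha = 0.01,
                                correction = c("none", "bonferroni")) {
  stopifnot(inherits(b, "bias_datasets"))
  correction <- match.arg(correction)
  rscu_high <- rscu(b$counts_high)
  rscu_low <- rscu(b$counts_low)
  rows <- lapply(SYN_CODONS, function(cod) {
    res <- chi_square_codon_test(b, cod)
    tab <- attr(res, "table")
    fh <- if (sum(tab[, "high"]) > 0) tab[1, "high"] / sum(tab[, "high"]) else NA_real_
    fl <- if (sum(tab[, "low"]) > 0) tab[1, "low"] / sum(tab[, "low"]) else NA_real_
    data.frame(
      codon = cod, aa = unname(AA_OF_CODON[cod]),
      count_high = tab[1, "high"], rest_high = tab[2, "high"],
      count_low = tab[1, "low"], rest_low = tab[2, "low"],
      chi2 = unname(res["chi2"]), p = unname(res["p"]),
      freq_high = fh, freq_low = fl,
      rscu_high = unname(rscu_high[cod]), rscu_low = unname(rscu_low[cod]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  p_use <- out$p
  if (correction == "bonferroni") {
    p_use <- stats::p.adjust(out$p, method = "bonferroni")
  }
  out$p_adj <- p_use
  out$optimal <- !is.na(p_use) & p_use < alpha &
    !is.na(out$freq_high) & !is.na(out$freq_low) &
    out$freq_high > out$freq_low
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  class(out) <- c("optimal_codons", "data.frame")
  out
}

#' @export
print.optimal_codons <- function(x, ...) {
  opt <- x$codon[x$optimal]
  cat(sprintf("Optimal codons (p < %g, higher usage in high-bias set): %d\n",
              attr(x, "alpha"), length(opt)))
  if (length(opt)) cat(" ", paste(sort(opt), collapse = " "), "\n")
  invisible(x)
}
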