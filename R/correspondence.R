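# Correspondence analysis of the genes x 59-codon RSCU matrix: SVD of the
# standardized residuals of the matrix treated as a contingency-style
# table, principal coordinates for genes (rows) and codons (columns), and
# per-axis inertia fractions.

#' Build the genes x 59 RSCU matrix
#'
#' Rows are genes, columns the 59 codons of synonymous families (ATG, TGG
#' and the three stop codons excluded), in the fixed package codon order.
#' Codons of families absent from a gene carry 0. Genes observing fewer
#' than `min_families` synonymous families are flagged via the
#' `low_coverage` attribute but retained.
#'
#' @param x A [gene_profiles()] object (its `counts` attribute is used) or
#'   a genes x 61 codon count matrix.
#' @param min_families Minimum number of observed synonymous families below
#'   which a gene is flagged (default 2).
#' @return Numeric matrix of class `rscu_matrix` (genes x 59) with
#'   attribute `low_coverage` (character vector of flagged gene ids).
#' @export
build_rscu_matrix <- function(x, min_families = 2L) {
  m <- if (inherits(x, "gene_profiles")) attr(x, "counts") else x
  if (is.null(m) || !is.matrix(m)) {
    stop("'x' must be a gene_profiles object or a codon count matrix")
  }
  if (nrow(m) == 0L) stop("empty profile collection")
  m <- m[, SENSE_CODONS, drop = FALSE]
  r <- t(apply(m, 1L, function(cts) rscu(cts)[SYN_CODONS]))
  dimnames(r) <- list(rownames(m), SYN_CODONS)
  syn_aa <- AA_OF_CODON[SYN_CODONS]
  n_fam <- apply(m[, SYN_CODONS, drop = FALSE], 1L, function(cts) {
    length(unique(syn_aa[cts > 0]))
  })
  attr(r, "low_coverage") <- rownames(m)[n_fam < min_families]
  class(r) <- c("rscu_matrix", class(r))
  r
}

#' Correspondence analysis of a non-negative matrix
#'
#' Classical CA: the matrix is scaled to a correspondence table P summing
#' to one, the standardized residuals
#' `S = D_r^-1/2 (P - r c') D_c^-1/2` are decomposed by SVD, and principal
#' coordinates are returned for rows (`D_r^-1/2 U D`) and columns
#' (`D_c^-1/2 V D`). The inertia fraction of an axis is its squared
#' singular value over the total inertia. Axis signs are arbitrary. Rows
#' or columns with zero sums are dropped and reported; if the matrix has
#' lower rank than `k`, fewer axes are returned.
#'
#' @param m Non-negative matrix (e.g. a [build_rscu_matrix()] result).
#' @param k Number of axes to return (default 4).
#' @return List of class `coa`: `row_coords`, `col_coords` (principal
#'   coordinates, k columns), `inertia_fraction` (per returned axis),
#'   `sv` (all singular values), `total_inertia`, `dropped_rows`,
#'   `dropped_cols`.
#' @examples
#' m <- matrix(rpois(80, 5), 10, 8)
#' res <- run_coa(m, k = 2)
#' res$inertia_fraction
#' @export
run_coa <- function(m, k = 4L) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("matrix must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  rs <- rowSums(m)
  cs <- colSums(m)
  dropped_rows <- rownames(m)[rs == 0]
  dropped_cols <- colnames(m)[cs == 0]
  m <- m[rs > 0, cs > 0, drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 rows with positive sums")

  P <- m / sum(m)
  r <- rowSums(P)
  c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S)
  # relative tolerance with an absolute floor: S is scale-free (P sums to
  # one), so near-zero singular values are numerical noise
  tol <- max(max(dim(S)) * max(sv$d) * 1e-12, 1e-10)
  pos <- sv$d > tol
  total_inertia <- sum(sv$d^2)
  k_eff <- min(k, sum(pos))
  if (k_eff == 0L) {
    row_coords <- matrix(0, nrow(m), 0L, dimnames = list(rownames(m), NULL))
    col_coords <- matrix(0, ncol(m), 0L, dimnames = list(colnames(m), NULL))
    inertia <- numeric(0L)
  } else {
    d <- sv$d[seq_len(k_eff)]
    row_coords <- sweep(sv$u[, seq_len(k_eff), drop = FALSE] %*% diag(d, k_eff),
                        1L, sqrt(r), "/")
    col_coords <- sweep(sv$v[, seq_len(k_eff), drop = FALSE] %*% diag(d, k_eff),
                        1L, sqrt(c), "/")
    dimnames(row_coords) <- list(rownames(m), paste0("axis", seq_len(k_eff)))
    dimnames(col_coords) <- list(colnames(m), paste0("axis", seq_len(k_eff)))
    inertia <- d^2 / total_inertia
  }
  structure(
    list(row_coords = row_coords, col_coords = col_coords,
         inertia_fraction = inertia, sv = sv$d[pos],
         total_inertia = total_inertia,
         dropped_rows = dropped_rows, dropped_cols = dropped_cols,
         k_requested = k),
    class = "coa"
  )
}

#' @export
print.coa <- function(x, ...) {
  cat(sprintf("Correspondence analysis: %d rows x %d cols, %d axis(es)\n",
              nrow(x$row_coords), nrow(x$col_coords),
              ncol(x$row_coords)))
  if (length(x$inertia_fraction)) {
    cat("  inertia fractions:",
        paste(sprintf("%.2f%%", 100 * x$inertia_fraction), collapse = ", "),
        "\n")
  } else {
    cat("  no informative axes (total inertia ",
        format(x$total_inertia), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.coa <- function(x, bands = NULL, axes = c(1L, 2L), ...) {
  rc <- x$row_coords
  if (ncol(rc) < max(axes)) stop("not enough axes to plot")
  col <- "grey40"
  if (!is.null(bands)) {
    pal <- c(low = "firebrick", mid = "steelblue", high = "forestgreen")
    col <- pal[as.character(bands)]
  }
  graphics::plot(rc[, axes[1L]], rc[, axes[2L]], pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor(col, 0.6),
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1L],
                                100 * x$inertia_fraction[axes[1L]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2L],
                                100 * x$inertia_fraction[axes[2L]]),
                 ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Correlation of axis-1 position with usage indices
#'
#' Pearson correlation (and its square) between the axis-1 gene coordinate
#' of a correspondence analysis and per-gene indices, by default GC, GC3s
#' and ENC. Axis signs are arbitrary, so only `|r|` is meaningful across
#' runs. Zero-variance indices yield `NA` with a warning.
#'
#' @param coa A [run_coa()] result on the gene RSCU matrix.
#' @param profiles A [gene_profiles()] data frame (matched to the CA rows
#'   by gene id).
#' @param indices Character vector of profile columns to correlate.
#' @return Data frame with columns `index`, `r`, `r2`, `n`.
#' @export
axis_correlations <- function(coa, profiles,
                              indices = c("gc", "gc3s", "enc")) {
  stopifnot(inherits(coa, "coa"), is.data.frame(profiles))
  if (ncol(coa$row_coords) < 1L) stop("CA has no axes")
  ax1 <- coa$row_coords[, 1L]
  idx <- match(rownames(coa$row_coords), profiles$id)
  if (anyNA(idx)) stop("CA rows not found in profiles")
  rows <- lapply(indices, function(v) {
    vals <- profiles[[v]][idx]
    ok <- !is.na(vals)
    r <- if (sum(ok) > 2L && stats::sd(vals[ok]) > 0) {
      stats::cor(ax1[ok], vals[ok])
    } else {
      warning("index '", v, "' has zero variance or too few values")
      NA_real_
    }
    data.frame(index = v, r = r, r2 = r^2, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify genes into GC-content bands
#'
#' Bands partition genes by GC content: `low` (<= 40%), `mid` (40-60%) and
#' `high` (>= 60%); the boundary values 0.40 and 0.60 fall in the outer
#' bands.
#'
#' @param gc Numeric vector of per-gene GC fractions, or a
#'   [gene_profiles()] data frame (its `gc` column is used).
#' @return Factor with levels `low`, `mid`, `high` (named by gene id when
#'   profiles are supplied).
#' @examples
#' classify_gc_bands(c(0.30, 0.40, 0.50, 0.60))
#' @export
classify_gc_bands <- function(gc) {
  nm <- NULL
  if (is.data.frame(gc)) {
    nm <- gc$id
    gc <- gc$gc
  }
  band <- ifelse(gc <= 0.40, "low", ifelse(gc >= 0.60, "high", "mid"))
  out <- factor(band, levels = c("low", "mid", "high"))
  if (!is.null(nm)) names(out) <- nm
  out
}
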