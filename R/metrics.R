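# Per-gene codon counts and codon-usage indices: third-position base
# frequencies over synonymous codons, GC, Wright's effective number of
# codons, RSCU, GRAVY and aromaticity.

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

#' Count sense codons of a coding sequence
#'
#' Codons are read in the frame starting at the first base. A terminal stop
#' codon is excluded from the counts; any in-frame stop codon before the
#' last position (possible if filtering was bypassed) is excluded from the
#' sense counts and reported via the `n_internal_stop` attribute.
#'
#' @param seq A single nucleotide sequence (A/C/G/T), length divisible by 3.
#' @return Named integer vector over the 61 sense codons with attributes
#'   `total_codons` (sum of the counts) and `n_internal_stop`.
#' @examples
#' count_codons("ATGTTTTAA")
#' @export
count_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  if (nchar(seq) %% 3L != 0L) {
    stop("sequence length is not a multiple of 3")
  }
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains non-ACGT symbols")
  }
  cod <- .split_codons(seq)
  n <- length(cod)
  if (n > 0L && cod[n] %in% STOP_CODONS) {
    cod <- cod[-n]
  }
  internal <- cod %in% STOP_CODONS
  cod <- cod[!internal]
  counts <- table(factor(cod, levels = SENSE_CODONS))
  out <- stats::setNames(as.integer(counts), SENSE_CODONS)
  attr(out, "total_codons") <- sum(out)
  attr(out, "n_internal_stop") <- sum(internal)
  out
}

#' Codon count matrix of a CDS set
#'
#' @param x A [cds_set()].
#' @return Integer matrix, genes in rows (named by record id), the 61 sense
#'   codons in columns.
#' @export
codon_count_matrix <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  m <- t(vapply(x$seq, function(s) as.integer(count_codons(s)),
                integer(length(SENSE_CODONS))))
  dimnames(m) <- list(x$id, SENSE_CODONS)
  m
}

#' Composition indices of a codon count vector
#'
#' Third-position base frequencies (A3s, T3s, G3s, C3s) are computed over
#' the synonymous codons only, i.e. codons of families with two or more
#' members (Met, Trp and stops excluded); `gc3s = g3s + c3s`. `gc` is the
#' G+C fraction over all three positions of the counted codons, `l_sym`
#' the number of synonymous codons and `l_aa` the total number of encoded
#' amino acids. When no synonymous codon is present the third-position
#' indices are `NA`.
#'
#' @param counts Named count vector over the 61 sense codons (from
#'   [count_codons()] or a row of [codon_count_matrix()]).
#' @return Named list with `t3s`, `c3s`, `a3s`, `g3s`, `gc3s`, `gc`,
#'   `l_sym`, `l_aa`.
#' @examples
#' composition_indices(count_codons("ATGTTCAAATAA"))
#' @export
composition_indices <- function(counts) {
  counts <- counts[SENSE_CODONS]
  l_aa <- sum(counts)
  if (l_aa == 0L) stop("empty codon counts")
  syn <- counts[SYN_CODONS]
  l_sym <- sum(syn)
  third <- .THIRD_BASE[SYN_CODONS]
  x3s <- function(b) if (l_sym > 0L) sum(syn[third == b]) / l_sym else NA_real_
  gc <- sum(counts * .CODON_GC[SENSE_CODONS]) / (3 * l_aa)
  t3s <- x3s("T"); c3s <- x3s("C"); a3s <- x3s("A"); g3s <- x3s("G")
  list(t3s = t3s, c3s = c3s, a3s = a3s, g3s = g3s,
       gc3s = if (l_sym > 0L) g3s + c3s else NA_real_,
       gc = gc, l_sym = as.integer(l_sym), l_aa = as.integer(l_aa))
}

#' Relative synonymous codon usage
#'
#' For codon i of amino acid j with family size n, RSCU is the observed
#' count divided by the mean count of the family, so values above / below /
#' equal to 1 indicate positive / negative / no bias. Codons of families
#' that are entirely absent from the gene get the value 0 and the family's
#' amino acid is reported in the `absent_families` attribute.
#'
#' @param counts Named count vector over the 61 sense codons.
#' @return Named numeric vector of RSCU values over the 61 sense codons
#'   with attribute `absent_families`.
#' @examples
#' r <- rscu(count_codons("ATGTTTTTTTTTTTCTAA"))
#' r[c("TTT", "TTC")]
#' @export
rscu <- function(counts) {
  counts <- counts[SENSE_CODONS]
  fam_tot <- tapply(counts, AA_OF_CODON, sum)[AA_OF_CODON]
  expected <- fam_tot / FAMILY_SIZE_CODON
  out <- ifelse(fam_tot > 0, counts / expected, 0)
  out <- stats::setNames(as.numeric(out), SENSE_CODONS)
  attr(out, "absent_families") <-
    sort(unique(AA_OF_CODON[fam_tot == 0]))
  out
}

# Wright-style F-hat per synonymous family: (n * sum(p^2) - 1) / (n - 1),
# defined for families observed with n >= 2 codons.
.family_fhat <- function(counts) {
  aa_multi <- names(FAMILY_SIZE_AA)[FAMILY_SIZE_AA >= 2L]
  vapply(aa_multi, function(a) {
    cts <- counts[SENSE_CODONS[AA_OF_CODON == a]]
    n <- sum(cts)
    if (n < 2L) return(NA_real_)
    p <- cts / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1L))
}

#' Observed effective number of codons (ENC)
#'
#' Wright-style estimator: for each synonymous family observed with n >= 2
#' codons, `F = (n * sum(p^2) - 1) / (n - 1)`; the class means of F over
#' families of degeneracy 2, 3, 4 and 6 give
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. If the single three-fold family
#' (Ile) is missing, `1/F3` is taken as `(1/F2 + 1/F4)/2`; a missing 2-,
#' 4- or 6-fold class mean is replaced by the mean of the computed class
#' means. Values above 61 are capped at 61; the minimum attainable value
#' is 20 (one codon per amino acid). If a class mean is zero or no class
#' is computable the estimate is undefined (`NA`, with a `reason`
#' attribute).
#'
#' @param counts Named count vector over the 61 sense codons.
#' @param cap Cap the estimate at 61 (default TRUE). Disable to compare
#'   against the raw formula value.
#' @return A single numeric value (possibly `NA`).
#' @examples
#' g <- rep(SENSE_CODONS, 100L)
#' enc_observed(count_codons(paste(c(g, "TAA"), collapse = "")))
#' @export
enc_observed <- function(counts, cap = TRUE) {
  counts <- counts[SENSE_CODONS]
  fhat <- .family_fhat(counts)
  deg <- FAMILY_SIZE_AA[names(fhat)]
  cls_mean <- function(k) {
    v <- fhat[deg == k & !is.na(fhat)]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- cls_mean(2L); f3 <- cls_mean(3L)
  f4 <- cls_mean(4L); f6 <- cls_mean(6L)

  known <- c(f2, f4, f6)
  if (all(is.na(c(known, f3)))) {
    return(structure(NA_real_, reason = "no computable family"))
  }
  fill <- mean(known[!is.na(known)])
  if (is.nan(fill)) fill <- f3  # only Ile computable
  if (is.na(f2)) f2 <- fill
  if (is.na(f4)) f4 <- fill
  if (is.na(f6)) f6 <- fill
  inv3 <- if (!is.na(f3) && f3 > 0) {
    1 / f3
  } else if (!is.na(f3) && f3 == 0) {
    NA_real_
  } else if (f2 > 0 && f4 > 0) {
    (1 / f2 + 1 / f4) / 2
  } else {
    NA_real_
  }
  if (any(is.na(c(f2, f4, f6, inv3))) || any(c(f2, f4, f6) == 0)) {
    return(structure(NA_real_, reason = "degenerate family class"))
  }
  enc <- 2 + 9 / f2 + inv3 + 5 / f4 + 3 / f6
  if (cap) enc <- min(enc, 61)
  enc
}

#' GRAVY and aromaticity of the encoded protein
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy over all encoded residues
#' (the initiator Met included); aromaticity is the fraction of residues
#' that are Phe, Tyr or Trp.
#'
#' @param counts Named count vector over the 61 sense codons.
#' @return Named list with `gravy` and `aromo`.
#' @examples
#' gravy_aromo(count_codons("ATGATTATTTAA"))
#' @export
gravy_aromo <- function(counts) {
  counts <- counts[SENSE_CODONS]
  n <- sum(counts)
  if (n == 0L) stop("empty codon counts")
  aa <- AA_OF_CODON
  list(
    gravy = sum(counts * .KD_SCALE[aa]) / n,
    aromo = sum(counts[aa %in% .AROMATIC_AA]) / n
  )
}

#' Per-gene codon-usage profiles
#'
#' Computes, for every record of a CDS set, the codon counts and the full
#' panel of usage indices: L_aa, L_sym, third-position base frequencies,
#' GC3s, GC, observed ENC, GRAVY and aromaticity. The genes x 61 codon
#' count matrix is attached as attribute `counts`.
#'
#' @param x A [cds_set()] (normally the kept set from [filter_cds()]).
#' @return A data frame of class `gene_profiles`, one row per gene, with
#'   attribute `counts` (the codon count matrix).
#' @examples
#' prof <- gene_profiles(filter_cds(generate_fixture())$cds)
#' prof$enc
#' @export
gene_profiles <- function(x) {
  stopifnot(inherits(x, "cds_set"))
  m <- codon_count_matrix(x)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    cts <- m[i, ]
    ci <- composition_indices(cts)
    ga <- gravy_aromo(cts)
    data.frame(
      id = rownames(m)[i],
      l_aa = ci$l_aa, l_sym = ci$l_sym,
      t3s = ci$t3s, c3s = ci$c3s, a3s = ci$a3s, g3s = ci$g3s,
      gc3s = ci$gc3s, gc = ci$gc,
      enc = as.numeric(enc_observed(cts)),
      gravy = ga$gravy, aromo = ga$aromo,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- m
  class(out) <- c("gene_profiles", "data.frame")
  out
}
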