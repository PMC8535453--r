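# Independent oracles and small data builders for the test suite.

# Wright-style ENC computed directly from the family homozygosity
# definition; assumes every degeneracy class is observed (large genes).
# Shares no code with enc_observed().
oracle_enc <- function(counts) {
  tab <- genetic_code_table()
  tab <- tab[!is.na(tab$family_size) & tab$family_size >= 2L, ]
  fam <- split(tab$codon, tab$aa)
  f_by_deg <- list()
  for (a in names(fam)) {
    cts <- counts[fam[[a]]]
    n <- sum(cts)
    if (n < 2L) next
    fhat <- (n * sum((cts / n)^2) - 1) / (n - 1)
    deg <- as.character(length(fam[[a]]))
    f_by_deg[[deg]] <- c(f_by_deg[[deg]], fhat)
  }
  fbar <- vapply(f_by_deg, mean, numeric(1L))
  2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
}

# brute-force correspondence analysis via eigendecomposition of the
# residual cross-product matrix (independent of the svd-based route)
oracle_ca <- function(m, k = 4L) {
  P <- m / sum(m)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  E <- eigen(t(S) %*% S, symmetric = TRUE)
  lam <- pmax(E$values, 0)
  keep <- seq_len(min(k, sum(lam > 1e-12)))
  V <- E$vectors[, keep, drop = FALSE]
  d <- sqrt(lam[keep])
  list(
    row = diag(1 / sqrt(r)) %*% S %*% V,
    col = diag(1 / sqrt(cc)) %*% V %*% diag(d, length(keep)),
    inertia = (lam / sum(lam))[keep]
  )
}

# named count vector over the 61 sense codons from a codon list
make_counts <- function(codons) {
  tab <- genetic_code_table()
  sense <- tab$codon[tab$aa != "*"]
  counts <- table(factor(codons, levels = sense))
  stats::setNames(as.integer(counts), sense)
}

sense_codons <- function() {
  tab <- genetic_code_table()
  tab$codon[tab$aa != "*"]
}

# one deterministic codon per amino acid (first in table order)
one_codon_per_aa <- function() {
  tab <- genetic_code_table()
  tab <- tab[tab$aa != "*", ]
  tab$codon[!duplicated(tab$aa)]
}

# random gene as a codon count vector with family-level usage skew
random_gene_counts <- function(n_codons = 2000L) {
  sense <- sense_codons()
  wts <- stats::rgamma(length(sense), shape = 1)
  make_counts(sample(sense, n_codons, replace = TRUE, prob = wts))
}

# random valid CDS string (ATG ... stop, no internal stop)
random_cds <- function(n_codons = 120L) {
  sense <- setdiff(sense_codons(), "ATG")
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}
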