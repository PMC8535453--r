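# Synthetic CDS generator. Genes draw a GC3 target from a two-component
# mixture (bimodal per-gene GC, low mode heavier), interior codons are
# amino-acid-uniform over the 18 synonymous families, third positions are
# G/C with the gene's target probability, and the C-versus-G choice at
# third positions follows a linear 5'-to-3' decline, yielding a declining
# CG-skew. The codon distribution is linear in the GC3 target, which gives
# exact closed-form positional expectations used as test oracles.

# structure of the 18 multi-codon families, fixed at build time
.FAM18 <- local({
  aa18 <- names(FAMILY_SIZE_AA)[FAMILY_SIZE_AA >= 2L]
  out <- lapply(aa18, function(a) {
    cods <- SENSE_CODONS[AA_OF_CODON == a]
    third <- substring(cods, 3L, 3L)
    is_gc <- third %in% c("G", "C")
    list(codons = cods, is_gc = is_gc,
         ends_c = third == "C", ends_g = third == "G",
         split_cg = any(third == "C") && any(third == "G"))
  })
  names(out) <- aa18
  out
})

# k x M matrix of codon probabilities for one family; theta and p_c are
# per-slot vectors (recycled if length 1), w a named weight vector over
# the family's codons. Columns sum to 1.
.family_prob_matrix <- function(st, theta, p_c, w) {
  k <- length(st$codons)
  m <- max(length(theta), length(p_c))
  theta <- rep_len(theta, m)
  p_c <- rep_len(p_c, m)
  w <- w[st$codons]
  P <- matrix(0, k, m)
  z_at <- w * !st$is_gc
  z_at <- z_at / sum(z_at)
  if (st$split_cg) {
    z_c <- w * st$ends_c
    z_c <- z_c / sum(z_c)
    z_g <- w * st$ends_g
    z_g <- z_g / sum(z_g)
    for (i in seq_len(k)) {
      P[i, ] <- if (st$ends_c[i]) {
        theta * p_c * z_c[i]
      } else if (st$ends_g[i]) {
        theta * (1 - p_c) * z_g[i]
      } else {
        (1 - theta) * z_at[i]
      }
    }
  } else {
    z_gc <- w * st$is_gc
    z_gc <- z_gc / sum(z_gc)
    for (i in seq_len(k)) {
      P[i, ] <- if (st$is_gc[i]) theta * z_gc[i] else (1 - theta) * z_at[i]
    }
  }
  P
}

#' Specify a synthetic genome
#'
#' Parameters of the synthetic CDS generator. Gene lengths (codons,
#' including the stop) are `min_codons` plus a negative-binomial draw with
#' mean `length_mean - min_codons` and dispersion `length_dispersion`.
#' Each gene's GC3 target is drawn from a two-component normal mixture
#' (`gc_low_weight` on the low component); interior codons are
#' amino-acid-uniform over the 18 synonymous families, the third base is
#' G/C with the gene's target probability, and where a family offers both
#' C- and G-ending codons the C choice has probability
#' `skew_p0 - skew_beta * (j - 1)` at codon position j. A finite
#' `family_bias` draws genome-level Dirichlet weights within each family
#' subclass; `preferred_codons` with `preference_strength > 1` tilt the
#' within-family distribution of a `preferred_fraction` subpopulation of
#' genes.
#'
#' @param n_genes Number of genes (default 500).
#' @param length_mean Mean gene length in codons including the stop
#'   (default 450).
#' @param length_dispersion Negative-binomial size parameter (default 2).
#' @param min_codons Minimum gene length in codons including the stop
#'   (default 100, i.e. 300 nt).
#' @param gc_low_weight,gc_low_mean,gc_high_mean,gc_sd GC3-target mixture:
#'   weight of the low component and the two component means (defaults
#'   0.62, 0.48, 0.78) with common standard deviation `gc_sd`
#'   (default 0.05); draws are clamped to `[0, 1]`.
#' @param skew_p0 Probability that a G/C third position is C at the first
#'   codon (default 0.55).
#' @param skew_beta Per-codon linear decline of that probability
#'   (default 1e-4).
#' @param gc3_decay Per-codon linear decline of the gene's GC3 target
#'   along the CDS (default 0 = flat); the per-position target is clamped
#'   to `[0, 1]`. A positive value plants a 5'-to-3' decline in G+C and
#'   hence in hydrogen bonds per codon.
#' @param family_bias Dirichlet concentration for genome-level
#'   within-family weights; `Inf` (default) means uniform weights.
#' @param preferred_codons Optional codons preferred by a subpopulation.
#' @param preference_strength Multiplicative within-family tilt applied to
#'   the preferred codons (default 1 = none).
#' @param preferred_fraction Fraction of genes carrying the preference
#'   (default 0).
#' @param seed RNG seed (default 1).
#' @param label Set label.
#' @return List of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_genes = 500L, length_mean = 450,
                                  length_dispersion = 2,
                                  min_codons = 100L,
                                  gc_low_weight = 0.62,
                                  gc_low_mean = 0.48,
                                  gc_high_mean = 0.78,
                                  gc_sd = 0.05,
                                  skew_p0 = 0.55, skew_beta = 1e-4,
                                  gc3_decay = 0,
                                  family_bias = Inf,
                                  preferred_codons = NULL,
                                  preference_strength = 1,
                                  preferred_fraction = 0,
                                  seed = 1L, label = "synthetic") {
  stopifnot(n_genes >= 1L, min_codons >= 100L,
            length_mean > min_codons,
            gc_low_weight >= 0, gc_low_weight <= 1,
            gc_low_mean >= 0, gc_low_mean <= 1,
            gc_high_mean >= 0, gc_high_mean <= 1, gc_sd >= 0,
            skew_p0 >= 0, skew_p0 <= 1,
            preference_strength >= 1,
            preferred_fraction >= 0, preferred_fraction <= 1)
  if (!is.null(preferred_codons)) {
    bad <- setdiff(preferred_codons, SYN_CODONS)
    if (length(bad)) {
      stop("preferred codons must be synonymous codons; invalid: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), length_mean = length_mean,
         length_dispersion = length_dispersion,
         min_codons = as.integer(min_codons),
         gc_low_weight = gc_low_weight, gc_low_mean = gc_low_mean,
         gc_high_mean = gc_high_mean, gc_sd = gc_sd,
         skew_p0 = skew_p0, skew_beta = skew_beta,
         gc3_decay = gc3_decay,
         family_bias = family_bias,
         preferred_codons = preferred_codons,
         preference_strength = preference_strength,
         preferred_fraction = preferred_fraction,
         seed = seed, label = label),
    class = "synthetic_genome_spec"
  )
}

# genome-level within-family weights
.draw_family_weights <- function(conc) {
  w <- rep(1, length(unlist(lapply(.FAM18, `[[`, "codons"))))
  names(w) <- unlist(lapply(.FAM18, `[[`, "codons"))
  if (is.finite(conc)) {
    w[] <- stats::rgamma(length(w), shape = conc, rate = conc)
  }
  w
}

#' Generate a synthetic CDS set
#'
#' Draws a genome according to a [synthetic_genome_spec()]: every gene
#' starts with ATG, ends with a uniformly chosen stop codon, contains no
#' internal stop (interior codons are sense codons of the 18 synonymous
#' families), has a length that is a multiple of three and at least
#' 300 nt, and is fully reproducible given the spec's seed. Gene-level
#' GC3 targets, preference flags, lengths and family weights are attached
#' as attributes for use by the expectation oracles.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A [cds_set()] with attributes `theta`, `preferred`,
#'   `n_codons`, `weights` and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes

  len <- spec$min_codons +
    stats::rnbinom(n, size = spec$length_dispersion,
                   mu = spec$length_mean - spec$min_codons)
  low <- stats::runif(n) < spec$gc_low_weight
  theta <- stats::rnorm(n, ifelse(low, spec$gc_low_mean, spec$gc_high_mean),
                        spec$gc_sd)
  theta <- pmin(pmax(theta, 0), 1)
  preferred <- stats::runif(n) < spec$preferred_fraction
  w <- .draw_family_weights(spec$family_bias)

  j_max <- max(len) - 1L
  p_end <- spec$skew_p0 - spec$skew_beta * (j_max - 1L)
  if (p_end < 0 || p_end > 1) {
    stop("skew gradient leaves [0, 1] over the generated lengths ",
         "(p = ", signif(p_end, 4), " at codon ", j_max, ")")
  }

  m <- len - 2L  # interior codons
  gene_idx <- rep(seq_len(n), m)
  j <- sequence(m) + 1L
  M <- length(j)
  fam <- sample(names(.FAM18), M, replace = TRUE)
  codv <- character(M)
  pref_mult <- rep(1, length(SENSE_CODONS))
  names(pref_mult) <- SENSE_CODONS
  if (!is.null(spec$preferred_codons)) {
    pref_mult[spec$preferred_codons] <- spec$preference_strength
  }

  for (f in names(.FAM18)) {
    s <- which(fam == f)
    if (!length(s)) next
    st <- .FAM18[[f]]
    k <- length(st$codons)
    th <- pmin(pmax(theta[gene_idx[s]] - spec$gc3_decay * (j[s] - 1L), 0), 1)
    P <- .family_prob_matrix(st, th,
                             spec$skew_p0 - spec$skew_beta * (j[s] - 1L), w)
    pg <- preferred[gene_idx[s]]
    if (any(pg) && spec$preference_strength > 1) {
      P[, pg] <- P[, pg, drop = FALSE] * pref_mult[st$codons]
    }
    P <- sweep(P, 2L, colSums(P), "/")
    u <- stats::runif(length(s))
    if (k > 1L) {
      cum <- P[1L, ]
      idx <- rep(1L, length(s))
      for (r in seq_len(k - 1L)) {
        idx <- idx + (u > cum)
        if (r < k - 1L) cum <- cum + P[r + 1L, ]
      }
    } else {
      idx <- rep(1L, length(s))
    }
    codv[s] <- st$codons[idx]
  }

  interior <- vapply(split(codv, factor(gene_idx, levels = seq_len(n))),
                     paste, character(1L), collapse = "")
  stops <- sample(STOP_CODONS, n, replace = TRUE)
  seqs <- paste0("ATG", interior, stops)
  ids <- sprintf("g%04d.1", seq_len(n))
  x <- cds_set(seqs, id = ids, label = spec$label)
  attr(x, "theta") <- theta
  attr(x, "preferred") <- preferred
  attr(x, "n_codons") <- len
  attr(x, "weights") <- w
  attr(x, "spec") <- spec
  x
}

# mean interior codon distribution at codon position j over a set of
# genes, exploiting linearity of the distribution in theta
.interior_dist <- function(theta_bar, p_c, w) {
  out <- numeric(length(SENSE_CODONS))
  names(out) <- SENSE_CODONS
  for (f in names(.FAM18)) {
    st <- .FAM18[[f]]
    out[st$codons] <- .family_prob_matrix(st, theta_bar, p_c, w)[, 1L] /
      length(.FAM18)
  }
  out
}

.check_expectation_ok <- function(x) {
  if (is.null(attr(x, "spec"))) {
    stop("expectations require a genome produced by generate_genome()")
  }
  if (any(attr(x, "preferred"))) {
    stop("closed-form expectations are only available for specs without ",
         "codon preference tilts")
  }
}

#' Expected positional composition of a synthetic genome
#'
#' Exact conditional expectation (given the realized GC3 targets) of the
#' per-position codon distribution of a generated genome: expected mean
#' hydrogen bonds, expected expensive-codon fraction and the per-base
#' composition of each codon position. Because the generator's codon
#' distribution is linear in the gene GC3 target, the expectation equals
#' the distribution evaluated at the mean target. Only defined for
#' specs without preference tilts and for positions covered by every gene
#' (so no end effects enter).
#'
#' @param x A genome from [generate_genome()].
#' @param max_pos Last codon position (must be covered by all genes).
#' @return List: `profile` (data frame `position`, `exp_hbonds`,
#'   `exp_expensive_fraction`) and `base_probs` (array 4 bases x 3
#'   within-codon positions x `max_pos`).
#' @export
expected_positional_profile <- function(x, max_pos) {
  .check_expectation_ok(x)
  spec <- attr(x, "spec")
  len <- attr(x, "n_codons")
  if (max_pos > min(len) - 1L) {
    stop("max_pos exceeds the shortest gene; expectations require full coverage")
  }
  theta <- attr(x, "theta")
  w <- attr(x, "weights")
  expensive <- hbonds_per_codon(SENSE_CODONS) >= 8L
  bases <- c("A", "C", "G", "T")
  bp <- array(0, dim = c(4L, 3L, max_pos),
              dimnames = list(bases, NULL, NULL))
  hb <- numeric(max_pos)
  ef <- numeric(max_pos)
  cod_bases <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  for (jj in seq_len(max_pos)) {
    P <- if (jj == 1L) {
      stats::setNames(as.numeric(SENSE_CODONS == "ATG"), SENSE_CODONS)
    } else {
      # distribution is linear in the (clamped) per-gene target, so the
      # mean over genes equals the distribution at the mean target
      theta_bar_j <- mean(pmin(pmax(theta - spec$gc3_decay * (jj - 1L), 0), 1))
      .interior_dist(theta_bar_j,
                     spec$skew_p0 - spec$skew_beta * (jj - 1L), w)
    }
    hb[jj] <- sum(P * hbonds_per_codon(SENSE_CODONS))
    ef[jj] <- sum(P[expensive])
    for (k in 1:3) {
      bp[, k, jj] <- vapply(bases, function(b) sum(P[cod_bases[, k] == b]),
                            numeric(1L))
    }
  }
  list(profile = data.frame(position = seq_len(max_pos), exp_hbonds = hb,
                            exp_expensive_fraction = ef),
       base_probs = bp)
}

# per-bp affine coefficients of the base probabilities in the gene's
# (clamped) GC3 target: prob(base, t | gene) = alpha[base, t] +
# beta[base, t] * theta_clamped(gene, codon(t))
.base_prob_coefs <- function(x, last_bp) {
  spec <- attr(x, "spec")
  w <- attr(x, "weights")
  n_cod <- ceiling(last_bp / 3)
  bases <- c("A", "C", "G", "T")
  cod_bases <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  p0 <- array(0, dim = c(4L, 3L, n_cod))
  p1 <- array(0, dim = c(4L, 3L, n_cod))
  for (jj in seq_len(n_cod)) {
    if (jj == 1L) {
      P0 <- P1 <- stats::setNames(as.numeric(SENSE_CODONS == "ATG"),
                                  SENSE_CODONS)
    } else {
      p_c <- spec$skew_p0 - spec$skew_beta * (jj - 1L)
      P0 <- .interior_dist(0, p_c, w)
      P1 <- .interior_dist(1, p_c, w)
    }
    for (k in 1:3) {
      for (b in seq_along(bases)) {
        sel <- cod_bases[, k] == bases[b]
        p0[b, k, jj] <- sum(P0[sel])
        p1[b, k, jj] <- sum(P1[sel])
      }
    }
  }
  t_idx <- seq_len(last_bp)
  jj <- ((t_idx - 1L) %/% 3L) + 1L
  k <- ((t_idx - 1L) %% 3L) + 1L
  alpha <- matrix(0, 4L, last_bp, dimnames = list(bases, NULL))
  beta <- alpha
  for (b in seq_along(bases)) {
    alpha[b, ] <- p0[cbind(b, k, jj)]
    beta[b, ] <- p1[cbind(b, k, jj)] - p0[cbind(b, k, jj)]
  }
  list(alpha = alpha, beta = beta, jj = jj)
}

#' Expected skew profile of a synthetic genome
#'
#' The estimand of [aggregate_skew_profile()] is the unweighted mean over
#' CDSs of per-CDS window skews. This oracle computes, for every gene,
#' the expected base counts of each window from the generator's exact
#' per-position codon distribution (affine in the gene's clamped GC3
#' target), forms the per-gene skew of expected counts, and averages
#' across genes, together with the analytic OLS trend slopes. Only
#' defined for specs without preference tilts and for regions covered by
#' every gene (stop codons excluded).
#'
#' @param x A genome from [generate_genome()].
#' @param max_len Last window start in bp.
#' @param window,step As in [aggregate_skew_profile()].
#' @return List: `profile` (data frame `position`, `exp_cg_skew`,
#'   `exp_at_skew`), `slope_cg`, `slope_at`.
#' @export
expected_skew_profile <- function(x, max_len, window = 100L, step = 1L) {
  .check_expectation_ok(x)
  spec <- attr(x, "spec")
  len <- attr(x, "n_codons")
  theta <- attr(x, "theta")
  last_bp <- max_len + window - 1L
  if (last_bp > 3L * (min(len) - 1L)) {
    stop("profiled region must exclude every gene's stop codon; reduce max_len")
  }
  cf <- .base_prob_coefs(x, last_bp)
  # genes x bp clamped GC3 target
  th_bp <- outer(theta, cf$jj, function(th, j) {
    pmin(pmax(th - spec$gc3_decay * (j - 1L), 0), 1)
  })
  starts <- seq.int(1L, max_len, by = step)
  wsum <- function(M) {
    cums <- t(apply(M, 1L, cumsum))
    cums[, starts + window - 1L, drop = FALSE] -
      cbind(0, cums)[, starts, drop = FALSE]
  }
  wcount <- function(b) {
    M <- matrix(cf$alpha[b, ], nrow(th_bp), last_bp, byrow = TRUE) +
      th_bp * matrix(cf$beta[b, ], nrow(th_bp), last_bp, byrow = TRUE)
    wsum(M)
  }
  eC <- wcount("C"); eG <- wcount("G")
  eA <- wcount("A"); eT <- wcount("T")
  cg <- colMeans((eC - eG) / (eC + eG))
  at <- colMeans((eA - eT) / (eA + eT))
  list(profile = data.frame(position = starts, exp_cg_skew = cg,
                            exp_at_skew = at),
       slope_cg = .ols_slope(starts, cg),
       slope_at = .ols_slope(starts, at))
}

#' Deterministic fixture CDS set
#'
#' A hard-coded five-record set exercising the filter rules: one valid
#' gene (which lacks the Cys family entirely and contains a 100+ bp
#' G/C-only stretch, an AT-skew edge case), a 299-nt record, a record
#' without an ATG start, a record with an in-frame TGA at codon 10, and a
#' valid but shorter isoform of the first gene. Exactly one record
#' survives [filter_cds()]. Byte-stable across calls.
#'
#' @return A [cds_set()] of 5 records.
#' @examples
#' filter_cds(generate_fixture())$report
#' @export
generate_fixture <- function() {
  filler <- c("TTT", "GAA", "CTG", "CCA", "GAT", "TAC", "AAA", "GTT",
              "TCA", "CGA")
  g1 <- paste0(
    "ATG",
    strrep("GGC", 34L),                                   # GC-only stretch
    paste(rep_len(filler, 84L), collapse = ""),
    "TAA"
  )                                                        # 360 nt, no Cys
  g2 <- paste0("ATG", strrep("GCA", 98L), "TA")            # 299 nt
  g3 <- paste0("TTG", strrep("GCT", 99L), "TAA")           # no ATG start
  g4 <- paste0("ATG", strrep("GCC", 8L), "TGA",
               strrep("GCC", 90L), "TAA")                  # internal stop
  g5 <- paste0("ATG", strrep("GCA", 98L), "TAA")           # shorter isoform
  cds_set(c(g1, g2, g3, g4, g5),
          id = c("g1.1", "g2.1", "g3.1", "g4.1", "g1.2"),
          label = "fixture")
}
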