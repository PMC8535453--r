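test_that("extreme selection takes ceiling(fraction*N) disjoint genes per end", {
  g <- generate_genome(synthetic_genome_spec(n_genes = 100L, seed = 3))
  prof <- gene_profiles(g)
  coa <- run_coa(build_rscu_matrix(prof))
  b <- select_extreme_genes(coa, attr(prof, "counts"), fraction = 0.05)
  expect_equal(length(b$high_ids), 5L)
  expect_equal(length(b$low_ids), 5L)
  expect_length(intersect(b$high_ids, b$low_ids), 0L)
  # orientation: the high end has the larger pooled GC3s
  expect_gte(b$gc3s_high, b$gc3s_low)
  expect_error(select_extreme_genes(coa, attr(prof, "counts"),
                                    fraction = 0.6), "too few")
})

test_that("optimal calls are invariant to the arbitrary CA axis sign", {
  g <- generate_genome(synthetic_genome_spec(n_genes = 120L, seed = 13))
  prof <- gene_profiles(g)
  coa <- run_coa(build_rscu_matrix(prof))
  flipped <- coa
  flipped$row_coords <- -coa$row_coords
  b1 <- select_extreme_genes(coa, attr(prof, "counts"))
  b2 <- select_extreme_genes(flipped, attr(prof, "counts"))
  expect_setequal(b1$high_ids, b2$high_ids)
  o1 <- call_optimal_codons(b1)
  o2 <- call_optimal_codons(b2)
  expect_equal(o1$optimal, o2$optimal)
})

test_that("a degenerate ranking is flagged non-informative", {
  m <- matrix(rep(c(5, 1, 1, 5), each = 50L), 50L, 4L)
  colnames(m) <- c("TTT", "TTC", "GCT", "GCC")
  counts <- matrix(0L, 50L, 61L,
                   dimnames = list(paste0("row", 1:50),
                                   genetic_code_table()$codon[
                                     genetic_code_table()$aa != "*"]))
  counts[, colnames(m)] <- m
  coa <- run_coa(m)
  expect_warning(b <- select_extreme_genes(coa, counts, fraction = 0.1),
                 "non-informative")
  expect_true(b$noninformative)
})

test_that("the 2x2 chi-square matches the closed form and chisq.test", {
  cts_h <- make_counts(c(rep("TTT", 30L), rep("TTC", 10L)))
  cts_l <- make_counts(c(rep("TTT", 10L), rep("TTC", 30L)))
  b <- bias_datasets(cts_h, cts_l)
  res <- chi_square_codon_test(b, "TTT")
  expect_equal(unname(res["chi2"]), 20)
  expect_equal(unname(res["p"]),
               stats::pchisq(20, df = 1L, lower.tail = FALSE))
  # random tables agree with stats::chisq.test without correction
  set.seed(61)
  for (i in 1:5) {
    h <- make_counts(sample(c("GCT", "GCC", "GCA", "GCG"), 200L,
                            replace = TRUE, prob = stats::rexp(4)))
    l <- make_counts(sample(c("GCT", "GCC", "GCA", "GCG"), 200L,
                            replace = TRUE, prob = stats::rexp(4)))
    bb <- bias_datasets(h, l)
    mine <- chi_square_codon_test(bb, "GCC")
    ref <- stats::chisq.test(attr(mine, "table"), correct = FALSE)
    expect_equal(unname(mine["chi2"]), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical usage gives no association; empty families are skipped", {
  cts <- make_counts(rep(c("TTT", "TTC", "GAA"), 20L))
  b <- bias_datasets(cts, cts)
  res <- chi_square_codon_test(b, "TTC")
  expect_equal(unname(res["chi2"]), 0)
  expect_equal(unname(res["p"]), 1)
  # Cys absent from both sets
  res2 <- chi_square_codon_test(b, "TGC")
  expect_true(is.na(res2["p"]))
  expect_equal(attr(res2, "reason"), "empty margin")
})

test_that("optimality needs both significance and the right direction", {
  h <- make_counts(c(rep("TTT", 10L), rep("TTC", 90L)))
  l <- make_counts(c(rep("TTT", 50L), rep("TTC", 50L)))
  o <- call_optimal_codons(bias_datasets(h, l))
  expect_true(o$optimal[o$codon == "TTC"])
  # TTT is equally significant but less frequent in the high set
  expect_lt(o$p[o$codon == "TTT"], 0.01)
  expect_false(o$optimal[o$codon == "TTT"])
  expect_equal(nrow(o), 59L)
  # Bonferroni tightens the calls
  ob <- call_optimal_codons(bias_datasets(h, l), correction = "bonferroni")
  expect_lte(sum(ob$optimal), sum(o$optimal))
})

test_that("a planted high-GC3 subpopulation dominates the high extreme", {
  planted <- c("CTG", "TCC", "CGC", "GCC", "GGC", "CCG", "ACC", "GTG",
               "AAG", "GAG")
  g <- generate_genome(synthetic_genome_spec(
    n_genes = 300L, gc_low_weight = 1, gc_low_mean = 0.55,
    gc_high_mean = 0.55, gc_sd = 0, skew_beta = 0,
    preferred_codons = planted, preference_strength = 4,
    preferred_fraction = 0.3, seed = 17))
  prof <- gene_profiles(g)
  coa <- run_coa(build_rscu_matrix(prof))
  b <- select_extreme_genes(coa, attr(prof, "counts"))
  pref <- attr(g, "preferred")
  names(pref) <- g$id
  expect_gt(mean(pref[b$high_ids]), 0.8)
  expect_lt(mean(pref[b$low_ids]), 0.2)
})
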