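test_that("codon counting reads the frame and excludes stops", {
  c1 <- count_codons("ATGTTTTAA")
  expect_equal(c1[["ATG"]], 1L)
  expect_equal(c1[["TTT"]], 1L)
  expect_equal(attr(c1, "total_codons"), 2L)
  c2 <- count_codons("ATGTAA")
  expect_equal(attr(c2, "total_codons"), 1L)
  # 300-nt record: 99 counted codons, stop excluded
  c3 <- count_codons(paste(c("ATG", rep("GCA", 98L), "TAA"), collapse = ""))
  expect_equal(attr(c3, "total_codons"), 99L)
  # internal stops flagged, not counted
  c4 <- count_codons("ATGTGATTTTAA")
  expect_equal(attr(c4, "n_internal_stop"), 1L)
  expect_equal(attr(c4, "total_codons"), 2L)
  expect_error(count_codons("ATGT"), "multiple of 3")
})

test_that("composition indices use the synonymous-codon denominator", {
  cts <- make_counts(c(rep("TTC", 10L), rep("AAA", 10L)))
  ci <- composition_indices(cts)
  expect_equal(ci$c3s, 0.5)
  expect_equal(ci$a3s, 0.5)
  expect_equal(ci$g3s, 0)
  expect_equal(ci$t3s, 0)
  expect_equal(ci$gc3s, 0.5)
  expect_equal(ci$l_sym, 20L)
  expect_equal(ci$l_aa, 20L)
})

test_that("genes with no synonymous codons have undefined 3s indices", {
  cts <- make_counts(c(rep("ATG", 5L), rep("TGG", 5L)))
  ci <- composition_indices(cts)
  expect_equal(ci$l_sym, 0L)
  expect_equal(ci$l_aa, 10L)
  expect_true(is.na(ci$t3s) && is.na(ci$gc3s))
})

test_that("saturated GC composition reaches 1", {
  cts <- make_counts(rep("GCG", 7L))
  ci <- composition_indices(cts)
  expect_equal(ci$gc, 1)
  expect_equal(ci$gc3s, 1)
  expect_equal(ci$l_sym, 7L)
  expect_equal(ci$l_aa, 7L)
})

test_that("3s indices sum to one and gc3s decomposes", {
  set.seed(71)
  for (i in 1:10) {
    cts <- random_gene_counts(400L)
    ci <- composition_indices(cts)
    expect_equal(ci$t3s + ci$c3s + ci$a3s + ci$g3s, 1)
    expect_equal(ci$gc3s, ci$g3s + ci$c3s)
    expect_true(ci$l_sym <= ci$l_aa)
  }
})

test_that("RSCU is the count over the family mean", {
  # uniform usage in every family
  r <- rscu(make_counts(rep(sense_codons(), 10L)))
  expect_equal(as.numeric(r), rep(1, 61L))
  # Phe 3:1 split
  r2 <- rscu(make_counts(c(rep("TTT", 3L), "TTC")))
  expect_equal(r2[["TTT"]], 1.5)
  expect_equal(r2[["TTC"]], 0.5)
  # single-codon family is always 1 when observed
  expect_equal(r2[["ATG"]], 0)  # absent here
  r3 <- rscu(make_counts(c("ATG", "TTT")))
  expect_equal(r3[["ATG"]], 1)
  expect_true("F" %in% attr(rscu(make_counts("ATG")), "absent_families"))
})

test_that("RSCU sums to the family size within observed families", {
  set.seed(72)
  tab <- genetic_code_table()
  for (i in 1:10) {
    cts <- random_gene_counts(1500L)
    r <- rscu(cts)
    fam_sum <- tapply(r, tab$aa[match(names(r), tab$codon)], sum)
    observed <- tapply(cts, tab$aa[match(names(cts), tab$codon)], sum) > 0
    fs <- tapply(tab$family_size[tab$aa != "*"], tab$aa[tab$aa != "*"],
                 unique)
    expect_equal(fam_sum[observed], fs[names(fam_sum)][observed])
  }
})

test_that("ENC spans 20 for maximal bias to 61 for uniform usage", {
  one <- one_codon_per_aa()
  expect_equal(enc_observed(make_counts(rep(one, 50L))), 20)
  expect_equal(enc_observed(make_counts(rep(sense_codons(), 100L))), 61)
  # uncapped value exceeds 61 for equal usage (finite-sample F-hat < 1/k)
  expect_gt(enc_observed(make_counts(rep(sense_codons(), 100L)),
                         cap = FALSE), 61)
})

test_that("ENC matches an independent brute-force oracle", {
  set.seed(73)
  for (i in 1:25) {
    cts <- random_gene_counts(2000L)
    expect_equal(enc_observed(cts, cap = FALSE), oracle_enc(cts),
                 tolerance = 1e-9)
  }
})

test_that("ENC decreases as within-family usage concentrates", {
  set.seed(74)
  sense <- sense_codons()
  tab <- genetic_code_table()
  aa <- tab$aa[match(sense, tab$codon)]
  groups <- split(seq_along(sense), aa)
  mean_enc <- vapply(c(50, 5, 0.5, 0.05), function(conc) {
    encs <- vapply(1:20, function(i) {
      wts <- numeric(length(sense))
      for (ix in groups) {
        g <- stats::rgamma(length(ix), shape = conc)
        wts[ix] <- g / sum(g)
      }
      cts <- make_counts(sample(sense, 3000L, replace = TRUE, prob = wts))
      enc_observed(cts)
    }, numeric(1L))
    mean(encs)
  }, numeric(1L))
  expect_true(all(diff(mean_enc) < 0))
  expect_gt(mean_enc[1L], 55)
  expect_lt(mean_enc[4L], 30)
})

test_that("GRAVY and aromaticity follow the residue composition", {
  expect_equal(gravy_aromo(make_counts(rep("ATT", 10L)))$gravy, 4.5)  # Ile
  expect_equal(gravy_aromo(make_counts(rep("TTT", 10L)))$aromo, 1)    # Phe
  ga <- gravy_aromo(make_counts(c(rep("TTT", 5L), rep("GCT", 5L))))
  expect_equal(ga$aromo, 0.5)
  expect_equal(ga$gravy, (2.8 + 1.8) / 2)
})

test_that("gene profiles collect every index with valid ranges", {
  set.seed(75)
  x <- cds_set(vapply(1:6, function(i) random_cds(150L), ""),
               id = sprintf("g%d.1", 1:6))
  prof <- gene_profiles(x)
  expect_s3_class(prof, "gene_profiles")
  expect_named(prof, c("id", "l_aa", "l_sym", "t3s", "c3s", "a3s", "g3s",
                       "gc3s", "gc", "enc", "gravy", "aromo"))
  expect_true(all(prof$enc >= 20 & prof$enc <= 61))
  expect_true(all(prof$l_aa == 149L))  # 150 codons minus the stop
  m <- attr(prof, "counts")
  expect_equal(dim(m), c(6L, 61L))
  expect_equal(unname(rowSums(m)), prof$l_aa)
})
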