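test_that("generation is deterministic given the seed", {
  spec <- synthetic_genome_spec(n_genes = 20L, seed = 99)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$seq, g2$seq)
  path1 <- withr::local_tempfile(fileext = ".fasta")
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(g1, path1)
  write_cds_fasta(g2, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("generated genes always satisfy the CDS filter", {
  g <- generate_genome(synthetic_genome_spec(n_genes = 60L, seed = 12))
  rep <- filter_cds(g)$report
  expect_equal(rep$n_passed, rep$n_input)
  expect_true(all(g$length %% 3L == 0L))
  expect_true(all(g$length >= 300L))
  expect_true(all(substring(g$seq, 1L, 3L) == "ATG"))
})

test_that("a degenerate GC3 mixture saturates the measured GC3s", {
  g <- generate_genome(synthetic_genome_spec(
    n_genes = 15L, gc_low_weight = 1, gc_low_mean = 1, gc_high_mean = 1,
    gc_sd = 0, seed = 5))
  prof <- gene_profiles(g)
  expect_true(all(prof$gc3s == 1))
})

test_that("the GC3 mixture parameters are recovered by the pipeline", {
  g <- generate_genome(synthetic_genome_spec(
    n_genes = 500L, gc_low_weight = 0.7, gc_low_mean = 0.45,
    gc_high_mean = 0.70, seed = 8))
  prof <- gene_profiles(g)
  expect_lt(abs(mean(prof$gc3s) - (0.7 * 0.45 + 0.3 * 0.70)), 0.02)
  # the low mode carries more genes (bimodal, low-heavy)
  expect_gt(mean(prof$gc3s < 0.575), 0.6)
  # component means recovered by splitting at the valley
  expect_lt(abs(mean(prof$gc3s[prof$gc3s < 0.575]) - 0.45), 0.02)
  expect_lt(abs(mean(prof$gc3s[prof$gc3s >= 0.575]) - 0.70), 0.02)
  # measured GC3s tracks the latent per-gene target
  expect_gt(stats::cor(attr(g, "theta"), prof$gc3s), 0.9)
})

test_that("an infeasible skew gradient is refused", {
  spec <- synthetic_genome_spec(n_genes = 10L, length_mean = 1000,
                                min_codons = 900L, skew_p0 = 0.1,
                                skew_beta = 1e-3, seed = 1)
  expect_error(generate_genome(spec), "\\[0, 1\\]")
  expect_error(synthetic_genome_spec(preferred_codons = "TAA"),
               "synonymous")
})

test_that("expectation oracles demand full coverage and no preference", {
  g <- generate_genome(synthetic_genome_spec(n_genes = 10L, seed = 3))
  expect_error(expected_positional_profile(g, max_pos = 10000L),
               "coverage")
  gp <- generate_genome(synthetic_genome_spec(
    n_genes = 10L, preferred_codons = "GCC", preference_strength = 3,
    preferred_fraction = 1, seed = 3))
  expect_error(expected_positional_profile(gp, 10L), "preference")
  # plain cds_set without generator metadata
  expect_error(expected_positional_profile(generate_fixture(), 5L),
               "generate_genome")
})

test_that("the expected positional profile matches simulation closely", {
  g <- generate_genome(synthetic_genome_spec(
    n_genes = 2000L, length_mean = 180, min_codons = 120L, seed = 14))
  ep <- expected_positional_profile(g, 100L)
  p <- positional_profile(g, max_pos = 100L, n_boot = 10L, seed = 1)
  expect_equal(ep$profile$exp_hbonds[1L], 7)  # ATG
  expect_lt(mean(abs(p$mean_hbonds - ep$profile$exp_hbonds)), 0.02)
  expect_lt(max(abs(p$mean_hbonds - ep$profile$exp_hbonds)), 0.12)
  expect_lt(mean(abs(p$expensive_fraction[-1L] -
                     ep$profile$exp_expensive_fraction[-1L])), 0.02)
  # base probabilities are proper distributions
  expect_equal(apply(ep$base_probs, c(2, 3), sum),
               matrix(1, 3L, 100L), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the fixture is byte-stable and exercises the edge cases", {
  f1 <- generate_fixture()
  f2 <- generate_fixture()
  expect_identical(f1, f2)
  expect_equal(length(f1$id), 5L)
  expect_true(any(f1$length == 299L))
  # one gene lacks an entire amino-acid family (Cys, in-frame)
  kept <- filter_cds(f1)$cds
  cts <- count_codons(kept$seq[1L])
  expect_equal(cts[["TGT"]] + cts[["TGC"]], 0L)
  # GC-only stretch long enough for an AT-free 100-bp window
  expect_true(grepl(strrep("GGC", 34L), kept$seq[1L], fixed = TRUE))
})
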