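test_that("a uniform all-GC set gives mean 9 with zero-width intervals", {
  x <- cds_set(rep(strrep("GGC", 40L), 30L), id = sprintf("g%d.1", 1:30))
  p <- positional_profile(x, max_pos = 50L, n_boot = 50L, seed = 1)
  expect_equal(nrow(p), 40L)  # no terminal stop, all 40 codons profiled
  expect_true(all(p$mean_hbonds == 9))
  expect_true(all(p$ci_low == 9 & p$ci_high == 9))
  expect_true(all(p$expensive_fraction == 1))
  expect_true(all(p$n_cds == 30L))
})

test_that("terminal stops are excluded and coverage gates positions", {
  seqs <- c(rep(paste(c("ATG", rep("GCA", 198L), "TAA"), collapse = ""), 40L),
            rep(paste(c("ATG", rep("GCA", 398L), "TAA"), collapse = ""), 10L))
  x <- cds_set(seqs, id = sprintf("g%03d.1", seq_along(seqs)))
  p <- positional_profile(x, max_pos = 450L, n_boot = 20L,
                          min_coverage = 30L, seed = 1)
  # stop codons never enter: 199 codons for the short genes
  expect_equal(max(p$position), 199L)
  expect_true(all(p$n_cds >= 30L))
  # n_cds is non-increasing left-aligned coverage
  expect_true(all(diff(p$n_cds) <= 0))
  expect_error(positional_profile(x, max_pos = 0L), "max_pos")
})

test_that("mean hydrogen bonds equal 6 + 3 * positional GC fraction", {
  set.seed(81)
  x <- cds_set(vapply(1:40, function(i) random_cds(60L), ""),
               id = sprintf("g%d.1", 1:40))
  p <- positional_profile(x, max_pos = 59L, n_boot = 10L,
                          min_coverage = 30L, seed = 1)
  for (pos in c(1L, 10L, 59L)) {
    codons <- substring(x$seq, 3L * (pos - 1L) + 1L, 3L * pos)
    gc_frac <- mean(vapply(strsplit(codons, ""), function(b) {
      mean(b %in% c("G", "C"))
    }, numeric(1L)))
    expect_equal(p$mean_hbonds[p$position == pos], 6 + 3 * gc_frac)
  }
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  set.seed(82)
  x <- cds_set(vapply(1:35, function(i) random_cds(50L), ""),
               id = sprintf("g%d.1", 1:35))
  p1 <- positional_profile(x, max_pos = 40L, n_boot = 200L, seed = 9)
  p2 <- positional_profile(x, max_pos = 40L, n_boot = 200L, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$ci_low <= p1$mean_hbonds & p1$mean_hbonds <= p1$ci_high))
  # cheap + expensive fractions are complementary by construction
  cheap <- 1 - p1$expensive_fraction
  expect_true(all(cheap >= 0 & cheap <= 1))
})

test_that("crossing detection requires a sustained drop", {
  flat <- data.frame(position = 1:100, expensive_fraction = 0.6)
  expect_true(is.na(crossing_position(flat)))
  stepped <- data.frame(position = 1:400,
                        expensive_fraction = c(rep(0.6, 199L),
                                               rep(0.4, 201L)))
  expect_equal(crossing_position(stepped), 200L)
  # a brief dip does not count
  dip <- data.frame(position = 1:100,
                    expensive_fraction = c(rep(0.6, 40L), rep(0.45, 5L),
                                           rep(0.6, 55L)))
  expect_true(is.na(crossing_position(dip)))
  # a run reaching the end of the profile qualifies
  tail_run <- data.frame(position = 1:50,
                         expensive_fraction = c(rep(0.6, 45L),
                                                rep(0.4, 5L)))
  expect_equal(crossing_position(tail_run), 46L)
})

test_that("a planted GC decline yields the analytic crossing position", {
  spec <- synthetic_genome_spec(
    n_genes = 8000L, length_mean = 230, min_codons = 170L,
    gc_low_weight = 1, gc_low_mean = 0.884, gc_high_mean = 0.884,
    gc_sd = 0.02, gc3_decay = 2e-3, skew_p0 = 0.55, skew_beta = 0,
    seed = 42)
  g <- generate_genome(spec)
  p <- positional_profile(g, max_pos = 169L, n_boot = 10L,
                          min_coverage = 30L, seed = 1)
  ep <- expected_positional_profile(g, 169L)
  analytic <- crossing_position(
    data.frame(position = ep$profile$position,
               expensive_fraction = ep$profile$exp_expensive_fraction))
  measured <- crossing_position(p)
  expect_false(is.na(measured))
  expect_lte(abs(measured - analytic), 10L)
  # the hydrogen-bond profile declines along the CDS
  expect_lt(p$mean_hbonds[nrow(p)], p$mean_hbonds[2L])
})
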