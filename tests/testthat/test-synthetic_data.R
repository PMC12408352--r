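chrom1 <- function(len = 1e6) c(chr1 = len)

test_that("density zero places exactly the causal variant", {
  set.seed(1)
  cfg <- sim_config(chrom1(), variant_density = 0)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 5e5)
  v <- place_variants(cfg, des)
  expect_equal(nrow(v), 1)
  expect_equal(v$pos, 500000L)
  expect_true(v$is_causal)
  expect_equal(c(v$ref, v$alt), c("G", "A"))
})

test_that("ems_gc_to_at_fraction = 1 yields only G>A / C>T substitutions", {
  set.seed(2)
  cfg <- sim_config(chrom1(), variant_density = 1 / 2000,
                    ems_gc_to_at_fraction = 1)
  v <- place_variants(cfg, NULL)
  expect_gt(nrow(v), 100)
  expect_true(all((v$ref == "G" & v$alt == "A") |
                    (v$ref == "C" & v$alt == "T")))
  expect_false(any(duplicated(v$pos)))
})

test_that("variant counts are Poisson with mean density x length", {
  set.seed(3)
  cfg <- sim_config(c(chr1 = 1e7), variant_density = 1 / 50000)
  counts <- replicate(200, nrow(place_variants(cfg, NULL)))
  # mean 200 per replicate, s.e. of the mean over 200 reps = sqrt(200/200) = 1
  expect_lt(abs(mean(counts) - 200), 3)
})

test_that("Haldane recombination fraction matches its closed form", {
  expect_equal(recomb_fraction(0, 4), 0)
  expect_equal(recomb_fraction(1e12, 4), 0.5, tolerance = 1e-12)
  # 25 Mb at 0.4 cM/Mb = 0.1 Morgan -> (1 - exp(-0.2)) / 2
  expect_equal(recomb_fraction(25e6, 0.4), 0.09063462, tolerance = 1e-7)
  expect_error(recomb_fraction(-1, 4), "non-negative")
  expect_true(all(recomb_fraction(10^(0:9), 4) >= 0))
  expect_true(all(recomb_fraction(10^(0:9), 4) <= 0.5))
})

test_that("mutant bulk is fixed at the causal site and the WT bulk averages 1/3", {
  cfg <- sim_config(chrom1(), variant_density = 0)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 5e5)
  set.seed(4)
  v <- place_variants(cfg, des)
  f_wt <- replicate(200, {
    truth <- simulate_population(des, v, cfg)
    expect_equal(truth$f_mut, 1)   # conditioning on aa
    truth$f_wt
  })
  # E[f_wt] = (0*1 + 1*2) / (2*3) = 1/3 over the 1 AA : 2 Aa class
  # sd(f_wt) ~ sqrt(50 * 2/9) / 100 = 0.033; 3 s.e. over 200 reps = 0.007
  expect_lt(abs(mean(f_wt) - 1 / 3), 0.01)
})

test_that("unlinked sites average frequency 1/2 in both bulks", {
  set.seed(5)
  cfg <- sim_config(c(chr1 = 1e6, chr2 = 1e6), variant_density = 0)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 5e5)
  v <- place_variants(cfg, des)
  unlinked <- dplyr::bind_rows(v, tibble::tibble(
    chrom = "chr2", pos = 5e5, ref = "G", alt = "A", is_causal = FALSE))
  f <- replicate(400, {
    truth <- simulate_population(des, unlinked, cfg)
    c(truth$f_mut[2], truth$f_wt[2])
  })
  # sd(f) ~ sqrt(1/(8N)); 3 s.e. over 400 reps < 0.009
  expect_lt(abs(mean(f[1, ]) - 0.5), 0.01)
  expect_lt(abs(mean(f[2, ]) - 0.5), 0.01)
})

test_that("linkage decays monotonically with distance from the causal locus", {
  cfg <- sim_config(c(chr1 = 4e7), variant_density = 0)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 1L)
  dist_grid <- as.integer(seq(1e5, 3.9e7, length.out = 10))
  v <- tibble::tibble(chrom = "chr1", pos = c(1L, dist_grid),
                      ref = "G", alt = "A",
                      is_causal = c(TRUE, rep(FALSE, 10)))
  set.seed(6)
  f <- rowMeans(replicate(200, simulate_population(des, v, cfg)$f_mut))[-1]
  expect_lte(suppressWarnings(cor(f, dist_grid, method = "spearman")), 0)
  expect_true(all(diff(recomb_fraction(dist_grid, cfg$cm_per_mb)) > 0))
})

test_that("read sampling respects depth and frequency limits", {
  truth <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "G", alt = "A",
                          f_mut = c(1, 0, 0.5), f_wt = c(1, 0, 0.5))
  set.seed(7)
  zero <- simulate_reads(truth, sim_config(chrom1(), depth_mean = 0))
  expect_true(all(zero$mut_ref + zero$mut_alt == 0))
  expect_true(all(zero$wt_ref + zero$wt_alt == 0))

  cfg <- sim_config(chrom1(), depth_mean = 50, error_rate = 0)
  r <- simulate_reads(truth, cfg)
  expect_equal(r$mut_ref[1], 0L)   # f = 1, no errors: all reads alt
  expect_equal(r$wt_alt[2], 0L)    # f = 0: no alt reads
})

test_that("per-site mean alt fraction matches the binomial expectation at f = 1/2", {
  set.seed(8)
  truth <- tibble::tibble(chrom = "chr1", pos = 1:10000, ref = "G", alt = "A",
                          f_mut = 0.5, f_wt = 0.5)
  r <- simulate_reads(truth, sim_config(chrom1(1e7), depth_mean = 30,
                                        error_rate = 0))
  dm <- r$mut_ref + r$mut_alt
  frac <- r$mut_alt[dm > 0] / dm[dm > 0]
  # s.e. of the mean over ~1e4 sites ~ sqrt(0.25/30/1e4) = 9e-4
  expect_lt(abs(mean(frac) - 0.5), 3 * 0.001)
})

test_that("at very high depth with no errors the SNP index matches the true frequency", {
  set.seed(9)
  cfg <- sim_config(c(chr1 = 5e6), variant_density = 1 / 50000,
                    depth_mean = 1e4, error_rate = 0)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 2.5e6)
  sim <- simulate_bsa_dataset(des, cfg)
  stats <- compute_site_stats(sim$sites)
  expect_true(all(abs(stats$index_mut - sim$truth$f_mut) <= 0.02))
  expect_true(all(abs(stats$index_wt - sim$truth$f_wt) <= 0.02))
})

test_that("generate_dataset is byte-identical per seed and varies across seeds", {
  cfg <- sim_config(chrom1(), seed = 11)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 5e5)
  p1 <- file.path(tempdir(), "sim_a")
  p2 <- file.path(tempdir(), "sim_b")
  f1 <- generate_dataset(des, cfg, p1, write_vcf = TRUE)
  f2 <- generate_dataset(des, cfg, p2, write_vcf = TRUE)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  cfg2 <- sim_config(chrom1(), seed = 12)
  f3 <- generate_dataset(des, cfg2, file.path(tempdir(), "sim_c"))
  v1 <- read_variants_tsv(f1[["variants"]])
  v3 <- read_variants_tsv(f3[["variants"]])
  expect_false(identical(v1$pos, v3$pos))
})

test_that("the truth table contains exactly one fixed causal row", {
  cfg <- sim_config(chrom1(), seed = 13)
  des <- cross_design(causal_chrom = "chr1", causal_pos = 5e5)
  sim <- simulate_bsa_dataset(des, cfg)
  expect_equal(sum(sim$truth$is_causal), 1)
  expect_equal(sim$truth$f_mut[sim$truth$is_causal], 1)
  expect_true(all(sim$truth$f_mut >= 0 & sim$truth$f_mut <= 1))
  expect_true(all(sim$truth$f_wt >= 0 & sim$truth$f_wt <= 1))
  expect_true(all(sim$truth$r >= 0 & sim$truth$r <= 0.5))
})
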