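# Feature variability, positional profiles, Fisher comparison.

test_that("feature variability performs the normalization arithmetic", {
  g <- random_genome(1000, seed = 71)
  catalog <- variant_catalog(rep("chr1", 10), c(5, 50, 150, 250, 350, 450,
                                                550, 650, 750, 850),
                             rep("A", 10), rep("G", 10))
  feats <- list(two_hit = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 100)))  # contains variants at 5 and 50
  vt <- feature_variability(catalog, feats, g)
  row <- vt[vt$feature == "two_hit", ]
  expect_identical(row$n_variants, 2L)
  expect_equal(row$density, 2.0)
  expect_equal(row$relative_variability, 2.0)
  gw <- vt[vt$feature == "genome_wide", ]
  expect_identical(gw$relative_variability, 1.0)  # exact, by definition
})

test_that("whole-genome relative variability is exactly 1 for any catalogue", {
  cfg <- small_sim_config(seed = 73L, chrom_length = 60000L, n_genes = 6L)
  sim <- simulate_genome(cfg)
  catalog <- simulate_variants(sim)
  feats <- list(whole = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 60000)))
  vt <- feature_variability(catalog, feats, sim$genome)
  expect_identical(vt$relative_variability[vt$feature == "whole"], 1.0)
  expect_identical(vt$relative_variability[vt$feature == "genome_wide"], 1.0)
})

test_that("variant counts per class match the per-base brute force", {
  cfg <- small_sim_config(seed = 79L, chrom_length = 80000L, n_genes = 8L)
  sim <- simulate_genome(cfg)
  catalog <- simulate_variants(sim)
  models <- parse_annotation(sim$annotation, sim$genome)
  introns <- derive_introns(models)
  feats <- build_feature_catalog(models, sim$genome, introns = introns)
  vt <- feature_variability(catalog, feats, sim$genome)
  for (cl in c("exon", "intron", "intergenic", "five_prime_ss",
               "three_prime_ss", "coding")) {
    expect_identical(vt$n_variants[vt$feature == cl],
                     oracle_variant_count(catalog, GenomicRanges::reduce(
                       feats[[cl]], ignore.strand = TRUE)))
  }
  # superset feature counts at least as many variants as its subset
  expect_gte(vt$n_variants[vt$feature == "genic"],
             vt$n_variants[vt$feature == "exon"])
})

test_that("splice-site profile localizes depletion and single variants", {
  # zero splice multiplier -> relative variability 0 at the 4 splice bases
  mult <- c(splice_site = 0, bps_bp = 0.12, bps_other = 0.85, coding = 0.35,
            utr = 0.7, intron = 0.9, intergenic = 1.15)
  cfg <- small_sim_config(seed = 83L, chrom_length = 150000L, n_genes = 15L,
                          base_mutation_rate = 0.1,
                          constraint_multipliers = mult)
  sim <- simulate_genome(cfg)
  catalog <- simulate_variants(sim)
  models <- parse_annotation(sim$annotation, sim$genome)
  introns <- derive_introns(models)
  ssp <- splice_site_profile(catalog, introns, sim$genome)
  four <- rbind(ssp[ssp$context == "donor" & ssp$offset %in% c("+1", "+2"), ],
                ssp[ssp$context == "acceptor" & ssp$offset %in% c("-2", "-1"), ])
  expect_identical(nrow(four), 4L)
  expect_true(all(four$relative_variability == 0))
  expect_true(all(four$n_total_sites == length(introns)))

  # one intron, one SNV on its first donor base
  g <- random_genome(500, seed = 84)
  intron <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+")
  s <- strsplit(as.character(g[[1]]), "")[[1]]
  vc <- variant_catalog("chr1", 101, s[101],
                        if (s[101] == "A") "G" else "A")
  prof <- splice_site_profile(vc, intron, g)
  d1 <- prof[prof$context == "donor" & prof$offset == "+1", ]
  expect_identical(d1$n_variable_sites, 1L)
  expect_identical(d1$n_total_sites, 1L)
  expect_error(splice_site_profile(vc, GenomicRanges::GRanges(), g),
               "no introns")
})

test_that("splice-site profile hovers near 1 when all multipliers are equal", {
  mult <- c(splice_site = 1, bps_bp = 1, bps_other = 1, coding = 1,
            utr = 1, intron = 1, intergenic = 1)
  cfg <- small_sim_config(seed = 89L, chrom_length = 250000L, n_genes = 25L,
                          base_mutation_rate = 0.2,
                          constraint_multipliers = mult)
  sim <- simulate_genome(cfg)
  catalog <- simulate_variants(sim)
  models <- parse_annotation(sim$annotation, sim$genome)
  introns <- derive_introns(models)
  ssp <- splice_site_profile(catalog, introns, sim$genome)
  # binomial sampling: ~100 introns at p ~ 0.2; allow a generous CI
  expect_true(all(ssp$relative_variability > 0.6 &
                    ssp$relative_variability < 1.4))
})

test_that("BPS profile counts sites (not variants) and flags planted depletion", {
  # 2 SNVs at the same heptamer position count once
  g <- random_genome(500, seed = 91)
  preds <- structure(
    data.frame(intron_id = c("i1", "i2"), chrom = "chr1",
               strand = c("+", "+"), intron_start = c(51L, 251L),
               intron_end = c(150L, 350L), bp_pos = c(130L, 330L),
               distance = c(20L, 20L), heptamer = "TACTAAC", score = 1,
               stringsAsFactors = FALSE),
    class = c("bps_predictions", "data.frame"))
  s <- strsplit(as.character(g[[1]]), "")[[1]]
  # two distinct SNVs at position 4 of the first heptamer (bp - 2 = 128)
  alts <- setdiff(c("A", "C", "G", "T"), s[128])[1:2]
  vc <- variant_catalog(rep("chr1", 2), c(128L, 128L), rep(s[128], 2), alts)
  prof <- bps_profile(vc, preds, g)
  p4 <- prof[prof$offset == "4", ]
  expect_identical(p4$n_variable_sites, 1L)
  expect_identical(p4$n_total_sites, 2L)

  # zero multiplier at heptamer positions 4/6 -> zero variable sites there
  mult <- c(splice_site = 0.02, bps_bp = 0, bps_other = 0.85, coding = 0.35,
            utr = 0.7, intron = 0.9, intergenic = 1.15)
  cfg <- small_sim_config(seed = 93L, chrom_length = 150000L, n_genes = 15L,
                          base_mutation_rate = 0.1,
                          constraint_multipliers = mult)
  sim <- simulate_genome(cfg)
  catalog <- simulate_variants(sim)
  truth_preds <- structure(
    data.frame(intron_id = paste0("t", seq_len(nrow(sim$truth))),
               chrom = sim$truth$chrom, strand = sim$truth$strand,
               intron_start = sim$truth$intron_start,
               intron_end = sim$truth$intron_end, bp_pos = sim$truth$bp_pos,
               distance = sim$truth$distance, heptamer = sim$truth$heptamer,
               score = 0, stringsAsFactors = FALSE),
    class = c("bps_predictions", "data.frame"))
  prof2 <- bps_profile(catalog, truth_preds, sim$genome)
  expect_identical(prof2$n_variable_sites[prof2$offset == "4"], 0L)
  expect_identical(prof2$n_variable_sites[prof2$offset == "6"], 0L)
  expect_gt(prof2$n_variable_sites[prof2$offset == "1"], 0L)
})

test_that("compare_positions matches the hypergeometric enumeration oracle", {
  mk_profile <- function(va, vb, n) {
    structure(data.frame(
      context = "bps", offset = c("4", "6"),
      n_variable_sites = c(va, vb), n_total_sites = c(n, n),
      relative_variability = NA_real_),
      class = c("position_profile", "data.frame"))
  }
  # identical margins -> p = 1
  cmp <- compare_positions(mk_profile(5, 5, 100))
  expect_equal(cmp$p_value, 1.0)
  # extreme table -> vanishing p
  cmp2 <- compare_positions(mk_profile(0, 100, 100))
  expect_lt(cmp2$p_value, 1e-20)
  # exhaustive agreement with the enumeration oracle for tables n <= 200
  cases <- rbind(c(10, 12, 200), c(0, 7, 150), c(3, 3, 40), c(25, 9, 180),
                 c(1, 0, 12), c(17, 30, 200), c(50, 40, 120))
  for (i in seq_len(nrow(cases))) {
    va <- cases[i, 1]; vb <- cases[i, 2]; n <- cases[i, 3]
    cmp <- compare_positions(mk_profile(va, vb, n))
    tab <- matrix(c(va, n - va, vb, n - vb), 2, byrow = TRUE)
    expect_equal(cmp$p_value, oracle_fisher_p(tab), tolerance = 1e-12)
  }
  # verdict uses the Bonferroni threshold
  cmp3 <- compare_positions(mk_profile(0, 25, 120), alpha = 0.05,
                            m_tests = 11)
  expect_equal(cmp3$threshold, 0.05 / 11)
  expect_true(cmp3$significant)
  expect_error(compare_positions(mk_profile(0, 0, 0)), "zero site")
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 11), 2), 4.5e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 3), 0.05 / 3)
  expect_error(bonferroni_threshold(0.05, 0), "m_tests")
  expect_error(bonferroni_threshold(1.2, 3), "alpha")
})
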