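test_that("snp_density counts deduplicated CpG SNPs over sites", {
  sites <- data.table::data.table(chrom = "chr1", pos = seq(10L, 400L, 10L))
  ctl <- make_catalog("chr1", c(20L, 50L), "C", "T", "CpG_C>T")
  d <- snp_density(sites, ctl)
  expect_equal(d$density, 2 / 40)
  # non-CpG SNP at a listed position is not counted
  ctl2 <- rbind(ctl, make_catalog("chr1", 30L, "C", "T", "nonCpG_C>T"))
  expect_equal(snp_density(sites, ctl2)$n_snps, 2L)
  # two records at one site count once
  ctl3 <- rbind(ctl, make_catalog("chr1", 20L, "C", "A", "CpG_C>A"))
  expect_equal(snp_density(sites, ctl3)$n_snps, 2L)
  # a G-side record keys against the C of the same CpG
  ctl4 <- rbind(ctl, make_catalog("chr1", 61L, "G", "A", "CpG_C>T"))
  expect_equal(snp_density(sites, ctl4)$n_snps, 3L)
  expect_warning(z <- snp_density(sites[0], ctl), "no sites")
  expect_true(is.na(z$density))
})

test_that("snp_density equals the naive per-site oracle on a laid-out fixture", {
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(5L, 11L, 17L, 23L, 29L, 35L,
                                          41L, 47L, 53L, 59L, 65L, 71L))
  ctl <- rbind(
    make_catalog("chr1", c(11L, 23L), "C", "T", "CpG_C>T"),
    make_catalog("chr1", 36L, "G", "A", "CpG_C>T"),   # G of the CpG at 35
    make_catalog("chr1", 47L, "C", "T", "nonCpG_C>T"),
    make_catalog("chr1", 80L, "C", "T", "CpG_C>T"))   # off-site
  got <- snp_density(sites, ctl)
  want <- naive_site_density(sites, ctl, cpg_snp_types())
  expect_equal(got$n_snps, want$n_snps)
  expect_equal(got$density, want$density)
  expect_equal(got$density, 0.25)
})

test_that("stage profile categories are additive over the five bins", {
  set.seed(42)
  n <- 400L
  lev <- stats::runif(n)
  st <- make_stage_table("chr1", seq_len(n) * 10L,
                         round(lev * 20L), rep(20L, n))
  called <- call_methylated(depth_filter(st))
  ctl <- make_catalog("chr1", sample(seq_len(n) * 10L, 60L), "C", "T",
                      "CpG_C>T")
  pr <- suppressWarnings(stage_bin_profile(called, ctl))
  bins <- pr[pr$category %in% methylation_bins(), ]
  expect_equal(sum(bins$n_sites),
               pr$n_sites[pr$category == "methylated"])
  expect_equal(sum(bins$n_snps),
               pr$n_snps[pr$category == "methylated"])
  expect_equal(pr$n_sites[pr$category == "all"],
               pr$n_sites[pr$category == "methylated"] +
                 pr$n_sites[pr$category == "unmethylated"])
})

test_that("bin trend correlation matches the direct Pearson formula", {
  mk <- function(d) data.table::data.table(
    category = methylation_bins(), n_sites = 100L,
    n_snps = as.integer(d * 100), density = d)
  perfect <- bin_trend_correlation(mk(c(1, 2, 3, 4, 5) / 100))
  expect_equal(perfect$r, 1)
  expect_error(bin_trend_correlation(mk(rep(0.1, 5))), "constant")
  expect_error(bin_trend_correlation(mk(c(1, 2, 3, 4, 5) / 100)[-2]),
               "20-40%")
  d <- c(0.05, 0.07, 0.10, 0.14, 0.18)
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  r_hand <- sum((x - mean(x)) * (d - mean(d))) /
    sqrt(sum((x - mean(x))^2) * sum((d - mean(d))^2))
  expect_equal(bin_trend_correlation(mk(d))$r, r_hand, tolerance = 1e-12)
})

test_that("methylated vs unmethylated chi-square matches the Yates formula", {
  pr <- data.table::data.table(
    category = c("methylated", "unmethylated"),
    n_sites = c(1000L, 1000L), n_snps = c(50L, 5L),
    density = c(0.05, 0.005))
  got <- meth_vs_unmeth_test(pr)
  tab <- matrix(c(50, 5, 950, 995), nrow = 2)
  expect_equal(got$chi2, naive_chisq_yates(tab), tolerance = 1e-10)
  same <- data.table::data.table(
    category = c("methylated", "unmethylated"),
    n_sites = c(1000L, 1000L), n_snps = c(50L, 50L),
    density = 0.05)
  expect_gt(meth_vs_unmeth_test(same)$p_value, 0.95)
  empty <- data.table::data.table(category = c("methylated", "unmethylated"),
                                  n_sites = c(1000L, 0L),
                                  n_snps = c(50L, 0L), density = c(0.05, NA))
  expect_error(meth_vs_unmeth_test(empty), "empty")
})

test_that("pattern enumeration builds 13-state codes in stage order", {
  ms <- make_all_stages("chr1", c(10L, 20L, 30L), level = 0.9, depth = 10L)
  cs <- common_sites(ms)
  lm_ <- level_matrix(ms, cs)
  pats <- enumerate_patterns(lm_)
  expect_equal(unique(pats$patterns$pattern), strrep("H", 13))
  expect_equal(pats$n_unique, 1L)
  # sperm high, all others unmethylated
  lm2 <- data.table::copy(lm_)[1]
  for (s in germline_stages()) lm2[, paste0("m_", s) := 0.1]
  lm2[, m_sperm := 0.9]
  expect_equal(enumerate_patterns(lm2)$patterns$pattern,
               paste0("H", strrep("U", 12)))
  # distinct codes counted
  lm3 <- rbind(lm_[1:2], lm2)
  expect_equal(enumerate_patterns(lm3)$n_unique, 2L)
})

test_that("pattern ranking filters by SNP count and orders deterministically", {
  pats <- data.table::data.table(
    chrom = "chr1", pos = 1:300,
    pattern = rep(c("A", "B", "C"), each = 100))
  data.table::setkeyv(pats, c("chrom", "pos"))
  # A: 30 snps, B: 10, C: 9 (below threshold)
  ctl <- make_catalog("chr1", c(1:30, 101:110, 201:209), "C", "T", "CpG_C>T")
  pm <- pattern_mutability(pats, ctl, min_snps = 10L, top_k = 2L)
  expect_equal(nrow(pm$full), 3L)
  expect_equal(pm$ranked$pattern, c("A", "B"))
  expect_equal(pm$top$pattern, c("A", "B"))
  expect_equal(pm$ranked$density, c(0.3, 0.1))
  # conservation: pattern site counts partition the common sites
  expect_equal(sum(pm$full$n_sites), nrow(pats))
  # ties broken by n_sites then code
  pats2 <- data.table::data.table(
    chrom = "chr1", pos = 1:150,
    pattern = c(rep("Z", 50), rep("Y", 100)))
  data.table::setkeyv(pats2, c("chrom", "pos"))
  ctl2 <- make_catalog("chr1", c(1:10, 51:70), "C", "T", "CpG_C>T")
  pm2 <- pattern_mutability(pats2, ctl2, min_snps = 10L)
  expect_equal(pm2$ranked$pattern, c("Y", "Z")) # equal density 0.2
})
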