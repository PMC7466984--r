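test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 5, genome = list(chrom_length = 50000L))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$methylomes$sperm, b$methylomes$sperm)
  expect_identical(a$variants, b$variants)
  expect_identical(a$expression$expr, b$expression$expr)
})

test_that("CpG placement hits the target rate within binomial bounds", {
  cfg <- sim_config(seed = 6, genome = list(chrom_length = 100000L,
                                            islands_per_mb = 0L))
  sg <- simulate_genome(cfg)
  L <- 100000
  expected <- 0.02 * L
  tol <- 4 * sqrt(L * 0.02 * 0.98)
  expect_lt(abs(nrow(sg$cpg) - expected), tol)
})

test_that("island blocks are CpG-enriched and hypomethylated", {
  cfg <- sim_config(seed = 7, genome = list(chrom_length = 200000L))
  sg <- simulate_genome(cfg)
  sgr <- GenomicRanges::GRanges(sg$cpg$chrom,
                                IRanges::IRanges(sg$cpg$pos, sg$cpg$pos))
  in_isl <- IRanges::overlapsAny(sgr, sg$islands)
  isl_bp <- sum(GenomicRanges::width(sg$islands))
  bg_bp <- 200000 - isl_bp
  expect_gt(sum(in_isl) / isl_bp, sum(!in_isl) / bg_bp)
  sm <- simulate_methylomes(cfg, sg)
  expect_lt(mean(sm$truth$m_sperm[in_isl]),
            mean(sm$truth$m_sperm[!in_isl]) - 0.3)
})

test_that("emitted methylomes track the latent levels and stage means", {
  cfg <- sim_config(seed = 8, genome = list(chrom_length = 200000L))
  sg <- simulate_genome(cfg)
  sm <- simulate_methylomes(cfg, sg)
  sp <- sm$methylomes$sperm
  expect_true(all(sp$meth_reads <= sp$total_reads))
  # low-depth rows are emitted (depth filters must see them)
  expect_gt(sum(sp$total_reads < 5L), 0L)
  ok <- sp$total_reads >= 5L
  lev <- sp$meth_reads[ok] / sp$total_reads[ok]
  # sperm stays highly methylated genome-wide, PGC stages do not
  expect_gt(mean(lev), 0.7)
  pg <- sm$methylomes$PGC13wm
  okp <- pg$total_reads >= 5L
  expect_lt(mean(pg$meth_reads[okp] / pg$total_reads[okp]), 0.25)
  # observed levels track the latent truth
  expect_gt(stats::cor(lev, sm$truth$m_sperm[ok]), 0.9)
})

test_that("with zero effects the CpG mutation fraction matches the baseline", {
  beta0 <- stats::setNames(rep(0, 13), germline_stages())
  cfg <- sim_config(seed = 9, genome = list(chrom_length = 1000000L),
                    mutation = list(beta = beta0))
  sg <- simulate_genome(cfg)
  sm <- simulate_methylomes(cfg, sg)
  sv <- simulate_variants(cfg, sm, sg)
  n <- nrow(sg$cpg)
  frac <- mean(sv$truth$mutated)
  expect_lt(abs(frac - 0.01), 4 * sqrt(0.01 * 0.99 / n))
})

test_that("pure C>T share closes the loop through classification", {
  cfg <- sim_config(seed = 10, genome = list(chrom_length = 50000L),
                    mutation = list(ct_share = 1),
                    variants = list(qual_noise = 0, contamination = 0))
  sg <- simulate_genome(cfg)
  sm <- simulate_methylomes(cfg, sg)
  sv <- simulate_variants(cfg, sm, sg)
  flt <- filter_variants(sv$variants, "chr1")
  ctl <- classify_mutations(flt$variants, sg$genome)
  cpg_types <- ctl$mutation_type[startsWith(ctl$mutation_type, "CpG")]
  expect_gt(length(cpg_types), 50L)
  expect_true(all(cpg_types == "CpG_C>T"))
})

test_that("the AF spectrum and QUAL exercise the filters as configured", {
  cfg <- sim_config(seed = 11, genome = list(chrom_length = 200000L))
  ds <- simulate_dataset(cfg)
  afn <- as.numeric(ds$variants$af)
  expect_gt(mean(afn < 0.001), 0.9)
  expect_gt(sum(afn >= 0.001), 0L) # contamination present
  expect_gt(sum(ds$variants$qual != 100), 0L)
  expect_gt(mean(ds$variants$qual == 100), 0.9)
})

test_that("annotation tracks exercise the disjointification rules", {
  cfg <- sim_config(seed = 12, genome = list(chrom_length = 500000L))
  sg <- simulate_genome(cfg)
  sa <- simulate_annotations(cfg, sg)
  sl <- seq_lengths(sg$genome)
  prom <- promoter_intervals(sa$genes, sl)
  expect_gt(sum(IRanges::overlapsAny(sa$enhancers, prom)), 0L)
  expect_gt(sum(IRanges::overlapsAny(sa$enhancers, sa$cgi)), 0L)
  expect_gt(sum(IRanges::overlapsAny(sa$repeats, sa$genes,
                                     type = "within")), 0L)
  for (tr in sa) {
    expect_true(all(GenomicRanges::start(tr) >= 1L))
    expect_true(all(GenomicRanges::end(tr) <= sl[[1]]))
  }
  expect_setequal(unique(as.character(GenomicRanges::strand(sa$genes))),
                  c("+", "-"))
})

test_that("generator outputs parse back through the readers unchanged", {
  cfg <- sim_config(seed = 13, genome = list(chrom_length = 50000L))
  ds <- simulate_dataset(cfg)
  fa <- tmp_file(".fa")
  write_fasta(ds$genome, fa)
  g2 <- read_fasta(fa)
  expect_identical(g2$seq, ds$genome$seq)
  vcf <- tmp_file(".vcf")
  write_vcf(ds$variants, vcf, contigs = seq_lengths(ds$genome))
  v2 <- read_vcf(vcf)
  expect_equal(v2$pos, ds$variants$pos)
  expect_equal(as.numeric(v2$af), as.numeric(ds$variants$af),
               tolerance = 1e-6)
  mt <- tmp_file(".tsv")
  write_methylation_table(ds$methylomes$oocyte, mt,
                          comments = "round trip")
  m2 <- read_methylation_table(mt, "oocyte")
  expect_equal(m2[, !"stage"], ds$methylomes$oocyte[, !"stage"],
               ignore_attr = TRUE)
})
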