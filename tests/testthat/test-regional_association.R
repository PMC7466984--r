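library(GenomicRanges)

gr <- function(chrom, start, end, strand = NULL, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(strand)) GenomicRanges::strand(g) <- strand
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}

test_that("promoters are strand-aware TSS windows", {
  sl <- c(chr1 = 100000L)
  plus <- gr("chr1", 5001L, 8000L, "+")
  p <- promoter_intervals(plus, sl)
  # 1-based [4001, 5200] == 0-based half-open [4000, 5200)
  expect_equal(start(p), 4001L)
  expect_equal(end(p), 5200L)
  minus <- gr("chr1", 2000L, 5000L, "-")
  p2 <- promoter_intervals(minus, sl)
  # TSS at 5000 on the minus strand: 0-based [4800, 6000)
  expect_equal(start(p2), 4801L)
  expect_equal(end(p2), 6000L)
  expect_error(promoter_intervals(gr("chr1", 10L, 20L), sl), "strand")
})

ann_fixture <- function() {
  sl <- c(chr1 = 20000L)
  genes <- gr("chr1", c(2001L, 9001L), c(6000L, 14000L), c("+", "-"),
              gene_id = c("g1", "g2"))
  exons <- gr("chr1", c(2001L, 4001L, 9001L, 12001L),
              c(2500L, 4500L, 9600L, 12400L))
  cgi <- gr("chr1", 7001L, 7600L)
  enh <- gr("chr1", c(1L, 7401L, 16001L), c(1200L, 8000L, 17000L))
  reps <- gr("chr1", c(101L, 4201L), c(200L, 4300L))
  list(sl = sl, genes = genes, exons = exons, cgi = cgi, enh = enh,
       reps = reps)
}

test_that("region classes follow the precedence and exclusion rules", {
  fx <- ann_fixture()
  ann <- build_region_annotation(fx$genes, fx$exons, fx$cgi, fx$enh,
                                 fx$reps, fx$sl)
  # g1 TSS = 2001 (+): promoter is 1-based [1001, 2200]
  p1 <- ann$promoter
  expect_true(any(start(p1) == 1001L))
  enh <- ann$enhancer
  # enhancer [1, 1200] loses its promoter overlap: kept part abuts 1001
  expect_false(any(IRanges::overlapsAny(enh, p1)))
  expect_true(any(end(enh) == 1000L))
  # CGI-enhancer common region removed from enhancer
  expect_false(any(IRanges::overlapsAny(enh, ann$CGI)))
  # repeat inside an exon is excluded from the exon class
  expect_false(any(IRanges::overlapsAny(ann$exon, ann$`repeat`)))
  # intron = gene minus exon (minus higher classes)
  expect_false(any(IRanges::overlapsAny(ann$intron, ann$exon)))
  # intragenic is exactly exon union intron
  expect_equal(sum(width(ann$intragenic)),
               sum(width(GenomicRanges::reduce(c(ann$exon, ann$intron)))))
})

test_that("region classes are pairwise disjoint and cover the genome", {
  fx <- ann_fixture()
  ann <- build_region_annotation(fx$genes, fx$exons, fx$cgi, fx$enh,
                                 fx$reps, fx$sl)
  leaf <- c("promoter", "CGI", "enhancer", "intergenic", "exon", "intron",
            "repeat")
  for (i in seq_along(leaf)) for (j in seq_along(leaf)) {
    if (i >= j) next
    ov <- GenomicRanges::intersect(ann[[leaf[i]]], ann[[leaf[j]]],
                                   ignore.strand = TRUE)
    expect_equal(sum(width(ov)), 0L,
                 info = paste(leaf[i], "vs", leaf[j]))
  }
  covered <- GenomicRanges::reduce(do.call(c, unname(ann[leaf])))
  expect_equal(sum(width(covered)), unname(fx$sl))
})

test_that("tiling cuts intervals into consecutive windows", {
  # 0-based [0, 2500) == 1-based [1, 2500]
  t1 <- tile_regions(gr("chr1", 1L, 2500L), 1000L)
  expect_equal(start(t1), c(1L, 1001L, 2001L))
  expect_equal(end(t1), c(1000L, 2000L, 2500L))
  t2 <- tile_regions(gr("chr1", 5L, 300L), 1000L)
  expect_equal(length(t2), 1L)
  expect_equal(width(t2), 296L)
  t3 <- tile_chromosomes(c(chr1 = 2500000L), 1e6)
  expect_equal(length(t3), 3L)
  expect_error(tile_regions(gr("chr1", 1L, 10L), 0L), "window")
  t4 <- tile_regions(gr("chr1", 1L, 2500L), 1000L, drop_partial = TRUE)
  expect_equal(length(t4), 2L)
})

test_that("tile_stats densities match a naive recount on a fixture", {
  set.seed(33)
  cfg <- sim_config(seed = 33, genome = list(chrom_length = 25000L))
  ds <- simulate_dataset(cfg)
  flt <- filter_variants(ds$variants, "chr1")
  ctl <- classify_mutations(flt$variants, ds$genome)
  tiles <- tile_chromosomes(seq_lengths(ds$genome), 1500L) # <= 20 tiles
  ts <- tile_stats(tiles, ds$genome, ds$methylomes, ctl, min_cpg = 5L)
  expect_lte(nrow(ts), 20L)
  expect_gt(nrow(ts), 5L)
  for (i in seq_len(nrow(ts))) {
    want <- naive_tile_stats("chr1", ts$start[i], ts$end[i], ds$genome, ctl)
    expect_equal(ts$cpg_count[i], want$cpg_count)
    expect_equal(ts$cpg_cg_bases[i], want$cpg_cg_bases)
    expect_equal(ts$noncpg_cg_bases[i], want$noncpg_cg_bases)
    expect_equal(ts$cpg_ct_snps[i], want$cpg_ct)
    expect_equal(ts$noncpg_ct_snps[i], want$noncpg_ct)
    expect_equal(ts$cpg_ct_density[i], want$cpg_ct / want$cpg_cg_bases)
  }
  # a tile's weighted methylation equals the read-weighted recount
  m <- ds$methylomes$sperm
  sub <- m[m$pos >= ts$start[1] & m$pos <= ts$end[1]]
  expect_equal(ts$meth_sperm[1],
               sum(sub$meth_reads) / sum(sub$total_reads))
})

test_that("tiles below the CpG minimum are dropped", {
  g <- genome_seq(c(chr1 = paste0(strrep("AT", 100),
                                  strrep("CG", 10),
                                  strrep("TA", 100))))
  tiles <- tile_regions(gr("chr1", 1L, 440L), 220L)
  ctl <- make_catalog("chr1", integer(), character(), character(),
                      character())
  ms <- list()
  ts <- tile_stats(tiles, g, list(), ctl, stages = character(),
                   min_cpg = 5L)
  # first tile holds the CpG run (10 CpGs), second has none
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$cpg_count[1], 10L)
})

test_that("spearman correlations match direct rank computation", {
  mk_tiles <- function(meth, dens) {
    data.table::data.table(
      chrom = "chr1", start = 1L, end = 2L, group = "g", tile_id = 1L,
      cpg_count = 5L, cpg_cg_bases = 10L, noncpg_cg_bases = 10L,
      cpg_ct_snps = 0L, noncpg_ct_snps = 0L,
      cpg_ct_density = dens, noncpg_ct_density = rev(dens),
      meth_sperm = meth)
  }
  td <- mk_tiles(1:10 / 10, 1:10 / 100)
  rc <- region_correlations(td, stages = "sperm", min_tiles = 3L)
  expect_equal(rc$rho[rc$measure == "cpg"], 1)
  expect_equal(rc$rho[rc$measure == "noncpg"], -1)
  # ties: against the midrank oracle
  dens <- c(0.1, 0.1, 0.3, 0.2, 0.2, 0.5, 0.4, 0.4, 0.6, 0.6)
  meth <- c(0.2, 0.3, 0.3, 0.5, 0.4, 0.6, 0.6, 0.8, 0.7, 0.9)
  td2 <- mk_tiles(meth, dens)
  rc2 <- region_correlations(td2, stages = "sperm", min_tiles = 3L)
  expect_equal(rc2$rho[rc2$measure == "cpg"], naive_spearman(meth, dens),
               tolerance = 1e-12)
  # constant vector reported as a missing cell
  td3 <- mk_tiles(rep(0.5, 10), 1:10 / 100)
  rc3 <- region_correlations(td3, stages = "sperm", min_tiles = 3L)
  expect_true(all(is.na(rc3$rho)))
})
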