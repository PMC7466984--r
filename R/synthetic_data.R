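## Synthetic toy genomes, 13-stage methylomes, methylation-dependent
## variant catalogs, annotation tracks and expression matrices, with known
## ground truth, so every pipeline stage is testable without downloads.
##
## The default configuration encodes the emulated study conditions: a
## near-fully methylated sperm methylome (> 80% genome-wide), progressive
## embryonic and PGC demethylation, WGBS-like overdispersed read depth with a
## small non-conversion error, a linear methylation -> mutation effect
## acting through the sperm stage, a rare-variant AF spectrum with a small
## common-allele contamination, and expression anti-correlated with
## promoter methylation in germline tissues only.

#' Simulation configuration
#'
#' Builds the nested configuration list consumed by the `simulate_*`
#' functions, with documented defaults. Supply overrides as nested lists,
#' e.g. `sim_config(seed = 7, genome = list(chrom_length = 1e7))`.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param ... nested overrides for the sections `genome`, `methylome`,
#'   `mutation`, `variants`, `annotations`, `expression`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  stage_means <- c(
    sperm = 0.85, oocyte = 0.55, `8cell` = 0.45, morula = 0.40, ICM = 0.40,
    PGC7wm = 0.30, PGC10wm = 0.15, PGC10wf = 0.12, PGC11wm = 0.10,
    PGC11wf = 0.10, PGC13wm = 0.08, PGC17wf = 0.08, PGC19wm = 0.10)
  beta <- stats::setNames(rep(0, 13), germline_stages())
  beta["sperm"] <- 0.15
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 1L, chrom_length = 1e6L, cpg_rate = 0.02,
                  islands_per_mb = 10L, island_length = 2000L,
                  island_cpg_rate = 0.10),
    methylome = list(stage_means = stage_means, island_scale = 0.15,
                     block_size = 1000L, block_sd = 1.5,
                     site_concentration = 8, depth_mean = 30,
                     depth_shape = 2, epsilon = 0.005),
    mutation = list(b0 = 0.01, beta = beta, ct_share = 0.8,
                    noncpg_rate = 0.002),
    variants = list(af_rare = c(1e-5, 9.9e-4), af_common = c(1e-3, 5e-2),
                    contamination = 0.05, qual = 100, qual_noise = 0.05,
                    qual_alt = c(80, 90, 99)),
    annotations = list(genes_per_mb = 20L, gene_length = c(10000L, 30000L),
                       exons_per_gene = c(3L, 8L),
                       exon_length = c(100L, 400L), enhancers_per_mb = 15L,
                       enhancer_length = 1000L, repeats_per_mb = 40L,
                       repeat_length = c(200L, 2000L)),
    expression = list(n_genes = 2000L, n_tissues = 40L, n_germline = 20L,
                      germline_coupling = -0.5, somatic_coupling = 0,
                      noise_sd = 0.3)
  )
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], over[[sec]])
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#' @param cfg a config list.
#' @return `cfg`, invisibly; errors on invalid settings.
#' @export
validate_sim_config <- function(cfg) {
  g <- cfg$genome
  if (g$chrom_length < 1000) stop("chrom_length < 1000")
  if (g$cpg_rate <= 0 || g$cpg_rate >= 0.5) stop("cpg_rate outside (0, 0.5)")
  m <- cfg$methylome
  if (any(m$stage_means <= 0 | m$stage_means >= 1))
    stop("stage means must lie in (0, 1)")
  if (m$island_scale <= 0 || m$island_scale > 1)
    stop("island_scale outside (0, 1]")
  if (m$depth_mean <= 0) stop("depth_mean must be positive")
  if (m$epsilon < 0 || m$epsilon >= 0.5) stop("epsilon outside [0, 0.5)")
  mu <- cfg$mutation
  if (!setequal(names(mu$beta), germline_stages()))
    stop("beta must be named by the 13 canonical stages")
  if (mu$b0 + sum(pmax(mu$beta, 0)) > 1)
    stop("mutation probability can exceed 1 (b0 + positive betas > 1)")
  if (mu$ct_share < 0 || mu$ct_share > 1) stop("ct_share outside [0, 1]")
  invisible(cfg)
}

#' Simulate a toy genome with placed CpGs
#'
#' Background i.i.d. sequence with all natural CG dinucleotides broken,
#' then CpGs placed at the target per-position rate (elevated inside CGI
#' blocks), so the realised CpG positions are fully known. Deterministic
#' given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [genome_seq()]), `cpg` (`data.table` of
#'   (`chrom`, `pos`) CpG C positions) and `islands` (`GRanges` of CGI
#'   blocks).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  g <- config$genome
  seqs <- character(g$n_chroms)
  isl_all <- list()
  for (k in seq_len(g$n_chroms)) {
    L <- as.integer(g$chrom_length)
    b <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    ## break every natural CG so placements define the CpG set exactly
    is_cg <- which(b[-L] == "C" & b[-1] == "G")
    if (length(is_cg)) b[is_cg + 1L] <- "A"
    rate <- rep(g$cpg_rate, L - 1L)
    n_isl <- round(g$islands_per_mb * L / 1e6)
    if (n_isl > 0) {
      gap <- L %/% (n_isl + 1L)
      ist <- gap * seq_len(n_isl)
      ien <- pmin(ist + g$island_length - 1L, L - 1L)
      for (j in seq_along(ist)) rate[ist[j]:ien[j]] <- g$island_cpg_rate
      isl_all[[k]] <- data.table::data.table(
        chrom = paste0("chr", k), start = ist, end = ien)
    }
    cand <- which(stats::runif(L - 1L) < rate)
    if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) >= 2L)]
    b[cand] <- "C"; b[cand + 1L] <- "G"
    seqs[k] <- paste(b, collapse = "")
  }
  names(seqs) <- paste0("chr", seq_len(g$n_chroms))
  genome <- genome_seq(seqs)
  ## authoritative CpG scan of the final sequence
  cpg <- data.table::rbindlist(lapply(names(seqs), function(cm) {
    p <- gregexpr("CG", seqs[[cm]], fixed = TRUE)[[1]]
    p <- if (p[1] == -1L) integer() else as.integer(p)
    data.table::data.table(chrom = cm, pos = p)
  }))
  data.table::setkeyv(cpg, c("chrom", "pos"))
  islands <- if (length(isl_all)) {
    d <- data.table::rbindlist(isl_all)
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
  } else GenomicRanges::GRanges()
  list(genome = genome, cpg = cpg[], islands = islands)
}

#' Simulate 13-stage methylomes over the CpG sites
#'
#' Latent per-site levels follow a hierarchical model emulating the
#' regional coherence of real methylomes: each site's expected level is
#' the stage background mean, scaled down by `island_scale` inside CGI
#' blocks (CpG islands stay hypomethylated in every stage), shifted on the
#' logit scale by a per-block (length `block_size`) Gaussian regional
#' effect with sd `block_sd`, and the site level is then drawn
#' `Beta(mu * conc, (1 - mu) * conc)` around that block mean. Read depth
#' is negative-binomial (mean `depth_mean`, shape `depth_shape`), the
#' overdispersed coverage typical of WGBS, so a realistic fraction of
#' sites falls under the 5-read filter; low-depth sites are emitted, not
#' suppressed. Methylated counts are
#' `~ Binomial(depth, m (1 - eps) + (1 - m) eps)` for bisulfite error
#' `eps`.
#'
#' @param config a [sim_config()].
#' @param sim_gen output of [simulate_genome()] (CpG positions and island
#'   blocks).
#' @return list with `methylomes` (named list of canonical methylation
#'   `data.table`s) and `truth` (`data.table` of latent `m_<stage>` levels
#'   per site).
#' @export
simulate_methylomes <- function(config, sim_gen) {
  set.seed(config$seed + 1L)
  mc <- config$methylome
  cpg <- sim_gen$cpg
  n <- nrow(cpg)
  stages <- germline_stages()
  ## island membership of each CpG
  in_island <- rep(FALSE, n)
  if (length(sim_gen$islands)) {
    sgr <- GenomicRanges::GRanges(cpg$chrom, IRanges::IRanges(cpg$pos,
                                                              cpg$pos))
    in_island <- IRanges::overlapsAny(sgr, sim_gen$islands)
  }
  block <- paste(cpg$chrom, (cpg$pos - 1L) %/% mc$block_size)
  bid <- match(block, unique(block))
  nb <- max(bid)
  truth <- data.table::copy(cpg)
  methylomes <- vector("list", length(stages))
  names(methylomes) <- stages
  conc <- mc$site_concentration
  for (s in stages) {
    base <- mc$stage_means[[s]] * ifelse(in_island, mc$island_scale, 1)
    u <- stats::rnorm(nb, 0, mc$block_sd)
    mu_site <- stats::plogis(stats::qlogis(base) + u[bid])
    m <- stats::rbeta(n, mu_site * conc, (1 - mu_site) * conc)
    d <- stats::rnbinom(n, size = mc$depth_shape, mu = mc$depth_mean)
    p_obs <- m * (1 - mc$epsilon) + (1 - m) * mc$epsilon
    mr <- stats::rbinom(n, d, p_obs)
    truth[, paste0("m_", s) := m]
    methylomes[[s]] <- data.table::data.table(
      chrom = cpg$chrom, pos = cpg$pos, strand = "+", context = "CpG",
      meth_reads = mr, total_reads = d, stage = s)
    data.table::setkeyv(methylomes[[s]], c("chrom", "pos"))
  }
  list(methylomes = methylomes, truth = truth[])
}

#' Simulate a variant catalog with methylation-dependent CpG mutability
#'
#' Each CpG site mutates with probability
#' `clip(b0 + sum_s beta_s m_{i,s}, 0, 1)`; a mutated CpG draws C>T with
#' probability `ct_share`, else C>A / C>G equally, and is reported at the
#' plus-strand C or the minus-strand C (the G) with equal probability so
#' strand collapse is exercised. Non-CpG C/G and T/A positions mutate at
#' the background rate with a uniform type choice. Allele frequencies are
#' rare with a configurable common-allele contamination; QUAL is 100 with
#' a configurable fraction at other values (so AF and QUAL filters are
#' exercised).
#'
#' @param config a [sim_config()].
#' @param sim_meth output of [simulate_methylomes()] (for latent levels).
#' @param sim_gen output of [simulate_genome()].
#' @param bg_index optional cached [background_site_index()] of the genome
#'   (it depends only on the sequence, so replicate runs over one genome
#'   can share it).
#' @return list with `variants` (raw-variant `data.table` as from
#'   [read_vcf()]) and `truth` (`data.table` of per-CpG mutation
#'   indicator and assigned pyrimidine-strand type).
#' @export
simulate_variants <- function(config, sim_meth, sim_gen, bg_index = NULL) {
  set.seed(config$seed + 2L)
  mu <- config$mutation
  vc <- config$variants
  cpg <- sim_gen$cpg
  truth <- sim_meth$truth
  stages <- germline_stages()
  m <- as.matrix(truth[, paste0("m_", stages), with = FALSE])
  p_mut <- pmin(pmax(mu$b0 + drop(m %*% mu$beta[stages]), 0), 1)
  mutated <- stats::runif(nrow(cpg)) < p_mut

  idx <- which(mutated)
  ## pyrimidine-strand change for each mutated CpG
  ct <- stats::runif(length(idx)) < mu$ct_share
  alt_p <- ifelse(ct, "T", sample(c("A", "G"), length(idx), replace = TRUE))
  ## report at the C (plus strand) or the G (minus strand) of the CpG
  on_g <- stats::runif(length(idx)) < 0.5
  v_cpg <- data.table::data.table(
    chrom = cpg$chrom[idx],
    pos = cpg$pos[idx] + ifelse(on_g, 1L, 0L),
    ref = ifelse(on_g, "G", "C"),
    alt = ifelse(on_g, unname(.COMP[alt_p]), alt_p)
  )

  ## background mutations outside CpGs (skipped entirely at rate zero:
  ## these draws come after the CpG layer in the RNG stream, so the CpG
  ## ground truth is unaffected either way)
  bg <- list()
  if (mu$noncpg_rate > 0 && is.null(bg_index))
    bg_index <- background_site_index(sim_gen$genome)
  if (mu$noncpg_rate == 0) bg_index <- list()
  for (cm in names(bg_index)) {
    s <- sim_gen$genome$seq[[cm]]
    cg_pos <- bg_index[[cm]]$cg
    ta_pos <- bg_index[[cm]]$ta
    for (set in list(list(p = cg_pos, alts = list(C = c("T", "A", "G"),
                                                  G = c("A", "T", "C"))),
                     list(p = ta_pos, alts = list(T = c("C", "G", "A"),
                                                  A = c("G", "C", "T"))))) {
      np <- length(set$p)
      if (np == 0L) next
      k <- stats::rbinom(1L, np, mu$noncpg_rate)
      if (k == 0L) next
      pp <- sort(sample(set$p, k))
      rf <- substring(s, pp, pp)
      al <- vapply(rf, function(r) sample(set$alts[[r]], 1L), character(1))
      bg[[length(bg) + 1L]] <- data.table::data.table(
        chrom = cm, pos = pp, ref = rf, alt = unname(al))
    }
  }
  v <- data.table::rbindlist(c(list(v_cpg), bg))
  nv <- nrow(v)
  common <- stats::runif(nv) < vc$contamination
  afv <- ifelse(common,
                stats::runif(nv, vc$af_common[1], vc$af_common[2]),
                stats::runif(nv, vc$af_rare[1], vc$af_rare[2]))
  qualv <- ifelse(stats::runif(nv) < vc$qual_noise,
                  sample(vc$qual_alt, nv, replace = TRUE), vc$qual)
  v[, qual := qualv]
  v[, af := format(afv, digits = 6, trim = TRUE, scientific = FALSE)]
  v[, symbolic := FALSE]
  v[, freq_unknown := FALSE]
  data.table::setorderv(v, c("chrom", "pos"))

  mut_truth <- data.table::data.table(
    chrom = cpg$chrom, pos = cpg$pos, mutated = mutated,
    type = NA_character_)
  mut_truth$type[idx] <- paste0("CpG_C>", alt_p)
  list(variants = v[], truth = mut_truth[])
}

## 1-based positions of a single character in a string
which_pos <- function(s, ch) {
  p <- gregexpr(ch, s, fixed = TRUE)[[1]]
  if (p[1] == -1L) integer() else as.integer(p)
}

#' Index the mutable background positions of a genome
#'
#' Per chromosome: sorted positions of non-CpG C/G bases and of T/A
#' bases, the two background pools of [simulate_variants()]. Depends only
#' on the sequence, so it can be computed once and shared across
#' replicate simulations over the same genome.
#'
#' @param genome a [genome_seq()].
#' @return named list per chromosome with `cg` and `ta` position vectors.
#' @export
background_site_index <- function(genome) {
  bi <- genome_base_index(genome)
  out <- lapply(names(bi), function(cm) {
    s <- genome$seq[[cm]]
    list(cg = bi[[cm]]$noncpg_cg,
         ta = sort(c(which_pos(s, "T"), which_pos(s, "A"))))
  })
  names(out) <- names(bi)
  out
}

#' Simulate annotation tracks
#'
#' Non-pathological gene / exon / CGI / enhancer / repeat tracks over the
#' toy genome, deliberately including a promoter-enhancer overlap, a
#' CGI-enhancer overlap and a repeat inside a gene body, so the region
#' disjointification rules are exercised; both strands are represented
#' among genes.
#'
#' @param config a [sim_config()].
#' @param sim_gen output of [simulate_genome()].
#' @return named list of `GRanges`: `genes` (with `gene_id`), `exons`,
#'   `cgi`, `enhancers`, `repeats`.
#' @export
simulate_annotations <- function(config, sim_gen) {
  set.seed(config$seed + 3L)
  an <- config$annotations
  seqlens <- seq_lengths(sim_gen$genome)
  cm <- names(seqlens)[1]
  L <- seqlens[[1]]
  ng <- max(round(an$genes_per_mb * L / 1e6), 2L)
  slot <- L %/% ng
  gl <- pmin(round(stats::runif(ng, an$gene_length[1], an$gene_length[2])),
             slot - 2000L)
  gst <- (seq_len(ng) - 1L) * slot +
    round(stats::runif(ng, 1000L, pmax(slot - gl - 1000L, 1001L)))
  gen <- GenomicRanges::GRanges(cm, IRanges::IRanges(gst, gst + gl - 1L),
                                strand = rep(c("+", "-"), length.out = ng))
  gen$gene_id <- sprintf("gene%03d", seq_len(ng))
  ## exons: evenly spaced blocks inside each gene
  ex <- list()
  for (i in seq_len(ng)) {
    k <- sample(an$exons_per_gene[1]:an$exons_per_gene[2], 1L)
    el <- round(stats::runif(k, an$exon_length[1], an$exon_length[2]))
    anchors <- round(seq(gst[i], gst[i] + gl[i] - max(el) - 1L,
                         length.out = k))
    ex[[i]] <- data.table::data.table(start = anchors,
                                      end = anchors + el - 1L)
  }
  exd <- data.table::rbindlist(ex)
  exons <- GenomicRanges::GRanges(cm, IRanges::IRanges(exd$start, exd$end))
  ## CGIs: the genome's island blocks plus a few random ones
  cgi <- c(sim_gen$islands,
           random_intervals(cm, L, 5L, 1500L))
  ## enhancers: random, plus one overlapping gene 1's promoter and one
  ## overlapping the first CGI
  n_enh <- max(round(an$enhancers_per_mb * L / 1e6), 3L)
  n_rep <- max(round(an$repeats_per_mb * L / 1e6), 2L)
  tss1 <- GenomicRanges::start(gen)[1]
  enh <- c(random_intervals(cm, L, n_enh - 2L, an$enhancer_length),
           GenomicRanges::GRanges(cm, IRanges::IRanges(
             max(tss1 - 500L, 1L), tss1 + 500L)),
           GenomicRanges::GRanges(cm, IRanges::IRanges(
             GenomicRanges::start(cgi)[1],
             GenomicRanges::start(cgi)[1] + an$enhancer_length - 1L)))
  ## repeats: random, plus one inside gene 2
  g2 <- gen[2]
  rep_in_gene <- GenomicRanges::GRanges(cm, IRanges::IRanges(
    GenomicRanges::start(g2) + 2000L, GenomicRanges::start(g2) + 2999L))
  reps <- c(random_intervals(cm, L, n_rep - 1L,
                             round(mean(an$repeat_length))), rep_in_gene)
  list(genes = gen, exons = exons, cgi = cgi, enhancers = enh,
       repeats = reps)
}

random_intervals <- function(chrom, L, n, width) {
  if (n <= 0L) return(GenomicRanges::GRanges())
  st <- round(stats::runif(n, 1L, L - width - 1L))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + width - 1L))
}

#' Simulate a gene expression matrix coupled to promoter methylation
#'
#' `expression[g, t] = c_t * meth_g + noise`, with negative coupling `c_t`
#' for germline tissues and (by default) zero for somatic tissues, so
#' expression is a negative proxy for promoter methylation exactly in the
#' germline. When no `promoter_meth` is supplied, latent per-gene promoter
#' methylation is drawn `Beta(2, 2)` over a standalone gene panel.
#'
#' @param config a [sim_config()].
#' @param promoter_meth optional named vector of true per-gene promoter
#'   methylation.
#' @return list with `expr` (genes x tissues matrix), `tissues`
#'   (`data.table`: `tissue`, `class`, `germline`) and `truth` (list with
#'   `promoter_meth` and `coupling`).
#' @export
simulate_expression <- function(config, promoter_meth = NULL) {
  set.seed(config$seed + 4L)
  ec <- config$expression
  if (is.null(promoter_meth)) {
    promoter_meth <- stats::setNames(stats::rbeta(ec$n_genes, 2, 2),
                                     sprintf("gene%04d", seq_len(ec$n_genes)))
  }
  nt <- ec$n_tissues
  ngl <- ec$n_germline
  stopifnot(ngl <= nt)
  germ <- c(rep(TRUE, ngl), rep(FALSE, nt - ngl))
  cls <- ifelse(germ,
                sample(c("primordial_germ", "male_germ", "female_germ"),
                       nt, replace = TRUE),
                sample(c("ESC", "somatic", "GCT", "other"), nt,
                       replace = TRUE))
  coupling <- ifelse(germ, ec$germline_coupling, ec$somatic_coupling)
  tissues <- data.table::data.table(
    tissue = sprintf("tissue%02d", seq_len(nt)), class = cls,
    germline = germ)
  expr <- outer(promoter_meth, coupling) +
    matrix(stats::rnorm(length(promoter_meth) * nt, sd = ec$noise_sd),
           ncol = nt)
  dimnames(expr) <- list(names(promoter_meth), tissues$tissue)
  list(expr = expr, tissues = tissues,
       truth = list(promoter_meth = promoter_meth, coupling = coupling))
}

#' Simulate promoters with varying historical CpG loss
#'
#' Emulates evolutionary CpG erosion: each promoter has a latent historical
#' mutability `h`; its sequence is built with CpG rate depressed by `h`
#' (lowering CpG O/E) while its current SNP density rises with `h`. Used to
#' check that CpG O/E and SNP density move oppositely.
#'
#' @param n number of promoters.
#' @param seed integer seed.
#' @param length promoter length in bp.
#' @param base_cpg_rate CpG rate at zero loss.
#' @return `data.table` with `seq`, `loss`, `snp_density`.
#' @export
simulate_promoter_loss <- function(n = 200L, seed = 1L, length = 1200L,
                                   base_cpg_rate = 0.05) {
  set.seed(seed)
  loss <- stats::runif(n)
  seqs <- vapply(loss, function(h) {
    rate <- base_cpg_rate * (1 - 0.8 * h)
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    cgpos <- which(b[-length] == "C" & b[-1] == "G")
    if (length(cgpos)) b[cgpos + 1L] <- "A"
    cand <- which(stats::runif(length - 1L) < rate)
    if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) >= 2L)]
    b[cand] <- "C"; b[cand + 1L] <- "G"
    paste(b, collapse = "")
  }, character(1))
  dens <- pmin(pmax(0.02 + 0.2 * loss +
                      stats::rnorm(n, sd = 0.01), 0), 1)
  data.table::data.table(seq = seqs, loss = loss, snp_density = dens)
}

#' Run the whole generator
#'
#' Chains genome, methylomes, variants, annotations and (standalone-panel)
#' expression under one seed. The expression layer uses its own gene panel:
#' the toy genome's handful of genes cannot support rank correlations.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `cpg`, `islands`, `methylomes`,
#'   `truth_levels`, `variants`, `truth_mutations`, `annotations`,
#'   `expression`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sg <- simulate_genome(config)
  sm <- simulate_methylomes(config, sg)
  sv <- simulate_variants(config, sm, sg)
  sa <- simulate_annotations(config, sg)
  se <- simulate_expression(config)
  list(genome = sg$genome, cpg = sg$cpg, islands = sg$islands,
       methylomes = sm$methylomes, truth_levels = sm$truth,
       variants = sv$variants, truth_mutations = sv$truth,
       annotations = sa, expression = se, config = config)
}
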