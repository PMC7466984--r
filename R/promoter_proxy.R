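## Promoter CpG observed/expected ratio, promoter CpG SNP density, and
## per-tissue Spearman correlations with gene expression.
##
## CpG O/E is depressed by historical methylation-driven CpG loss, so it
## serves as an evolutionary-timescale readout of the germline CpG mutation
## rate; expression is used as a negative proxy for promoter methylation
## (promoter methylation silences transcription), never to infer
## methylation values directly.

#' Observed/expected CpG ratio of a sequence
#'
#' The Gardiner-Garden form: `(N_CpG * L) / (N_C * N_G)`, with `N` bases
#' excluded from all counts and from `L`. An alternative dinucleotide
#' normalisation using `L - 1` is available via `dinucleotide_l`.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param dinucleotide_l use `L - 1` as the dinucleotide opportunity count
#'   (default `FALSE`, the canonical formula).
#' @return numeric vector of ratios; `NA` (with a warning) when a sequence
#'   has no C or no G.
#' @export
cpg_oe <- function(seqs, dinucleotide_l = FALSE) {
  seqs <- toupper(seqs)
  out <- vapply(seqs, function(s) {
    n_n <- lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
    L <- nchar(s) - n_n
    if (L < 2) return(NA_real_)
    n_c <- lengths(regmatches(s, gregexpr("C", s, fixed = TRUE)))
    n_g <- lengths(regmatches(s, gregexpr("G", s, fixed = TRUE)))
    n_cg <- lengths(regmatches(s, gregexpr("CG", s, fixed = TRUE)))
    if (n_c == 0 || n_g == 0) return(NA_real_)
    denom_l <- if (dinucleotide_l) L - 1 else L
    (n_cg * denom_l) / (n_c * n_g)
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(out)) warning(sum(is.na(out)), " sequence(s) with undefined CpG O/E")
  out
}

#' Per-gene promoter statistics
#'
#' For each gene: the promoter interval (strand-aware TSS - 1000 to
#' TSS + 200), its CpG O/E, and its CpG SNP density (SNPs of the given
#' types over the count of C/G bases at CpG sites within the promoter).
#' Genes whose promoter has no CpG C/G bases (density undefined) or no
#' C or G (O/E undefined) get `NA` in that statistic.
#'
#' @param genes `GRanges` of gene bodies with strand and a `gene_id`
#'   metadata column.
#' @param genome a [genome_seq()].
#' @param catalog classified catalog.
#' @param types SNP types counted (default all three CpG types; C>T-only
#'   is available by passing `"CpG_C>T"`).
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end`, `length`,
#'   `n_cpg`, `cpg_cg_bases`, `n_snps`, `cpg_snp_density`, `cpg_oe`.
#' @export
promoter_stats <- function(genes, genome, catalog,
                           types = cpg_snp_types()) {
  seqlens <- seq_lengths(genome)
  pr <- promoter_intervals(genes, seqlens)
  dt <- data.table::data.table(
    gene_id = if (!is.null(pr$gene_id)) pr$gene_id else
      paste0("gene", seq_along(pr)),
    chrom = as.character(GenomeInfoDb::seqnames(pr)),
    start = GenomicRanges::start(pr),
    end = GenomicRanges::end(pr)
  )
  dt[, length := end - start + 1L]
  bi <- genome_base_index(genome)
  snps <- unique(catalog[catalog$mutation_type %in% types,
                         c("chrom", "pos")])
  seqs <- character(nrow(dt))
  for (cm in unique(dt$chrom)) {
    i <- which(dt$chrom == cm)
    idx <- bi[[cm]]
    dt[i, n_cpg := .count_in(idx$cpg_start, start, end - 1L)]
    dt[i, cpg_cg_bases := .count_in(idx$cpg_bases, start, end)]
    dt[i, n_snps := .count_in(sort(snps$pos[snps$chrom == cm]), start, end)]
    seqs[i] <- substring(genome$seq[[cm]], dt$start[i], dt$end[i])
  }
  dt[, cpg_snp_density := ifelse(cpg_cg_bases > 0, n_snps / cpg_cg_bases,
                                 NA_real_)]
  dt[, cpg_oe := suppressWarnings(cpg_oe(seqs))]
  dropped <- sum(is.na(dt$cpg_snp_density) | is.na(dt$cpg_oe))
  if (dropped) warning(dropped, " gene(s) with undefined promoter statistic")
  dt[]
}

#' Per-tissue correlation of expression with a promoter statistic
#'
#' Spearman correlation, per tissue, between gene expression and a
#' per-gene promoter statistic (CpG SNP density, CpG O/E, or any proxy),
#' over the genes shared by the expression matrix and the statistic.
#' Tissues are ranked ascending by rho; the bottom-`bottom_k` germline
#' count summarises how strongly germline tissues dominate the most
#' negative correlations.
#'
#' @param expr numeric matrix, genes x tissues, with dimnames.
#' @param gene_stat named numeric vector of the per-gene statistic.
#' @param tissue_classes `data.table`/data.frame with columns `tissue`,
#'   `class` and logical `germline`.
#' @param min_genes minimum shared genes per tissue (default 50; tissues
#'   below it are skipped with a warning).
#' @param bottom_k size of the bottom-rank summary (default 20).
#' @return `data.table` with `tissue`, `class`, `germline`, `rho`,
#'   `p_value`, `n_genes`, `rank_` (ascending by rho); attribute
#'   `"bottom_k_germline"` counts germline tissues among the lowest
#'   `bottom_k` rhos.
#' @export
expression_correlations <- function(expr, gene_stat, tissue_classes,
                                    min_genes = 50L, bottom_k = 20L) {
  gene_stat <- gene_stat[!is.na(gene_stat)]
  shared <- intersect(rownames(expr), names(gene_stat))
  if (length(shared) < min_genes)
    stop("fewer than ", min_genes, " genes shared with the statistic")
  tc <- data.table::as.data.table(tissue_classes)
  rows <- lapply(colnames(expr), function(tt) {
    e <- expr[shared, tt]
    ok <- !is.na(e)
    if (sum(ok) < min_genes) {
      warning("tissue ", tt, " has fewer than ", min_genes,
              " usable genes; skipped")
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(e[ok], gene_stat[shared][ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.table::data.table(tissue = tt, rho = unname(ct$estimate),
                           p_value = ct$p.value, n_genes = sum(ok))
  })
  out <- data.table::rbindlist(rows)
  out <- merge(out, tc[, c("tissue", "class", "germline")], by = "tissue",
               all.x = TRUE, sort = FALSE)
  data.table::setorder(out, rho)
  out[, rank_ := seq_len(.N)]
  k <- min(bottom_k, nrow(out))
  attr(out, "bottom_k_germline") <- sum(out$germline[seq_len(k)],
                                        na.rm = TRUE)
  out[]
}
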