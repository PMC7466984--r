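## Site-level SNP-density mutability by methylation category, trend and
## contingency tests, and dynamic-pattern mutability ranking.
##
## SNP density is the per-site probability-mass estimator of the mutation
## rate: the number of sites carrying at least one CpG-context SNP over the
## number of eligible sites. Multiple catalog records at one cytosine count
## once (deduplicated), keeping densities <= 1.

#' Deduplicated SNP positions, CpG SNPs collapsed to the C of their CpG
#'
#' A CpG dinucleotide has two cytosine positions (the plus-strand C and
#' the minus-strand C, i.e. the G); a SNP at either belongs to the same
#' CpG site. When `collapse_to_c` is `TRUE` (the default for CpG-type
#' counting), CpG-context SNPs whose reference base is the G are mapped to
#' `pos - 1` so they key against the plus-strand cytosine the methylome
#' reports.
#'
#' @param catalog classified catalog from [classify_mutations()].
#' @param types mutation types to keep.
#' @param collapse_to_c map G-side CpG SNPs to the C position.
#' @return keyed `data.table` of unique (`chrom`, `pos`).
#' @export
snp_positions <- function(catalog, types = cpg_snp_types(),
                          collapse_to_c = TRUE) {
  hits <- data.table::as.data.table(
    catalog)[mutation_type %in% types, c("chrom", "pos", "ref",
                                         "mutation_type")]
  if (collapse_to_c) {
    cpg_g <- hits$ref == "G" & startsWith(hits$mutation_type, "CpG")
    hits[cpg_g, pos := pos - 1L]
  }
  out <- unique(hits[, c("chrom", "pos")])
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' SNP density over a set of cytosine positions
#'
#' Counts catalog SNPs of the given types whose position falls in
#' `sites`, at most one per site, and divides by the number of sites.
#' CpG-type SNPs at the G of a CpG are attributed to the C position (see
#' [snp_positions()]).
#'
#' @param sites `data.table` of (`chrom`, `pos`) cytosine positions.
#' @param catalog classified catalog from [classify_mutations()].
#' @param types mutation types counted in the numerator (default the three
#'   CpG types).
#' @param collapse_to_c see [snp_positions()].
#' @return list with `n_sites`, `n_snps`, `density` (`NA` density with a
#'   warning when `n_sites == 0`).
#' @export
snp_density <- function(sites, catalog, types = cpg_snp_types(),
                        collapse_to_c = TRUE) {
  n_sites <- nrow(sites)
  if (n_sites == 0L) {
    warning("no sites in category; density undefined")
    return(list(n_sites = 0L, n_snps = 0L, density = NA_real_))
  }
  hits <- snp_positions(catalog, types, collapse_to_c)
  n_snps <- nrow(merge(unique(sites[, c("chrom", "pos")]), hits,
                       by = c("chrom", "pos")))
  list(n_sites = n_sites, n_snps = n_snps, density = n_snps / n_sites)
}

#' Site-level mutability profile of one stage
#'
#' Densities for the categories: all covered CpG sites, methylated-called
#' sites, unmethylated-called sites, and the five methylation-level bins
#' over methylated sites. Categories with zero sites are dropped with a
#' warning.
#'
#' @param called_sites depth-filtered, called CpG methylation table for one
#'   stage (from [call_methylated()]); must contain `level` and `call`.
#' @param catalog classified catalog.
#' @return `data.table` with `category`, `n_sites`, `n_snps`, `density`.
#' @export
stage_bin_profile <- function(called_sites, catalog) {
  cs <- called_sites[called_sites$context == "CpG"]
  meth <- cs[cs$call == "methylated"]
  unmeth <- cs[cs$call == "unmethylated"]
  cats <- list(all = cs, methylated = meth, unmethylated = unmeth)
  if (nrow(meth)) {
    b <- assign_bin(meth$level)
    for (lv in methylation_bins()) cats[[lv]] <- meth[b == lv]
  }
  rows <- lapply(names(cats), function(nm) {
    x <- cats[[nm]]
    if (nrow(x) == 0L) {
      warning("category '", nm, "' has no sites; dropped")
      return(NULL)
    }
    d <- snp_density(x, catalog)
    data.table::data.table(category = nm, n_sites = d$n_sites,
                           n_snps = d$n_snps, density = d$density)
  })
  data.table::rbindlist(rows)
}

#' Pearson trend of bin densities against bin midpoints
#'
#' Correlates the five bin densities with the bin midpoints
#' (0.1, 0.3, 0.5, 0.7, 0.9 by default); two-sided p from the t transform
#' with n = 5.
#'
#' @param profile output of [stage_bin_profile()].
#' @param midpoints x-values for the five bins.
#' @return list with `r` and `p_value`.
#' @export
bin_trend_correlation <- function(profile,
                                  midpoints = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  idx <- match(methylation_bins(), profile$category)
  if (anyNA(idx))
    stop("missing bins: ",
         paste(methylation_bins()[is.na(idx)], collapse = ", "))
  d <- profile$density[idx]
  if (stats::sd(d) == 0) stop("bin densities are constant; r undefined")
  ct <- stats::cor.test(midpoints, d, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Chi-squared test of methylated vs unmethylated mutability
#'
#' 2x2 test on (methylated, unmethylated) x (site has SNP, site has no
#' SNP) counts, with Yates continuity correction by default. A warning is
#' issued (and an exact test suggested) when any expected cell is below 1.
#'
#' @param profile output of [stage_bin_profile()].
#' @param correct apply Yates continuity correction (default `TRUE`).
#' @return list with `chi2`, `p_value` and the 2x2 `table`.
#' @export
meth_vs_unmeth_test <- function(profile, correct = TRUE) {
  need <- c("methylated", "unmethylated")
  idx <- match(need, profile$category)
  if (anyNA(idx))
    stop("profile lacks category: ", paste(need[is.na(idx)], collapse = ", "))
  m <- profile[idx]
  tab <- matrix(c(m$n_snps, m$n_sites - m$n_snps), nrow = 2,
                dimnames = list(need, c("snp", "no_snp")))
  if (any(m$n_sites == 0)) stop("empty category in 2x2 test")
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expct < 1))
    warning("expected cell count < 1; consider an exact test")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p_value = ht$p.value, table = tab)
}

#' Enumerate dynamic methylation patterns
#'
#' The dynamic pattern of a site is the 13-character H/M/U string of its
#' three-state methylation codes in fixed stage order.
#'
#' @param lmat level matrix from [level_matrix()] (columns `m_<stage>`).
#' @param stages stage order (default the canonical 13).
#' @return list with `patterns` (`data.table`: `chrom`, `pos`, `pattern`)
#'   and `n_unique` (count of distinct codes).
#' @export
enumerate_patterns <- function(lmat, stages = germline_stages()) {
  cols <- paste0("m_", stages)
  missing <- setdiff(cols, names(lmat))
  if (length(missing))
    stop("level matrix missing stages: ", paste(missing, collapse = ", "))
  if (any(!stats::complete.cases(lmat[, cols, with = FALSE])))
    stop("missing level at some stage for a common site")
  codes <- do.call(paste0, lapply(cols, function(cl) three_state(lmat[[cl]])))
  out <- data.table::data.table(chrom = lmat$chrom, pos = lmat$pos,
                                pattern = codes)
  data.table::setkeyv(out, c("chrom", "pos"))
  list(patterns = out[], n_unique = data.table::uniqueN(codes))
}

#' Rank dynamic methylation patterns by mutability
#'
#' Per-pattern density = deduplicated CpG-SNP count over site count.
#' Patterns with fewer than `min_snps` SNPs are excluded from the ranking
#' but retained in the full table. Ties are broken by descending site
#' count, then lexicographic code, for determinism.
#'
#' @param patterns `patterns` table from [enumerate_patterns()].
#' @param catalog classified catalog.
#' @param min_snps minimum CpG SNP count for ranking (default 10).
#' @param top_k size of the top table (default 20).
#' @param types SNP types counted (default all three CpG types).
#' @return list with `full` (every pattern), `ranked` (filtered, ordered by
#'   descending density) and `top` (first `top_k` of `ranked`).
#' @export
pattern_mutability <- function(patterns, catalog, min_snps = 10L,
                               top_k = 20L, types = cpg_snp_types()) {
  hits <- snp_positions(catalog, types)
  hits[, snp := TRUE]
  data.table::setkeyv(hits, c("chrom", "pos"))
  pt <- data.table::copy(patterns)
  pt[, snp := !is.na(hits[pt, snp])]
  full <- pt[, .(n_sites = .N, n_snps = sum(snp)), by = pattern]
  full[, density := n_snps / n_sites]
  ranked <- full[n_snps >= min_snps]
  if (nrow(ranked) == 0L)
    warning("no pattern reaches ", min_snps, " SNPs; ranking is empty")
  data.table::setorder(ranked, -density, -n_sites, pattern)
  list(full = full[], ranked = ranked[],
       top = ranked[seq_len(min(top_k, nrow(ranked)))])
}
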