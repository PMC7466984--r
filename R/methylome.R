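## Per-site methylation levels, binomial methylation calls, level bins,
## three-state codes, cross-stage common sites, and tile-level weighted
## methylation.

#' Per-site methylation level
#'
#' The fraction of methylated (unconverted C) reads out of all covered
#' reads at a site. Sites with fewer than `min_reads` total reads carry no
#' usable level and should be excluded upstream via [depth_filter()].
#'
#' @param meth_reads,total_reads non-negative integer vectors.
#' @return numeric vector of levels in \[0, 1\].
#' @export
site_level <- function(meth_reads, total_reads) {
  if (any(meth_reads > total_reads))
    stop("meth_reads > total_reads")
  if (any(meth_reads < 0 | total_reads <= 0))
    stop("read counts must be non-negative with total_reads > 0")
  meth_reads / total_reads
}

#' Depth-filter a methylation table
#'
#' Retains sites covered by at least `min_reads` reads and records the
#' exclusion count in the `"n_excluded"` attribute (exclusion is reported,
#' never an error).
#'
#' @param sites canonical methylation `data.table`.
#' @param min_reads minimum read depth (default 5).
#' @return filtered `data.table` with a `level` column added.
#' @export
depth_filter <- function(sites, min_reads = 5L) {
  keep <- sites$total_reads >= min_reads
  out <- sites[keep]
  out[, level := site_level(meth_reads, total_reads)]
  attr(out, "n_excluded") <- sum(!keep)
  out[]
}

#' Call methylated sites with an exact binomial test
#'
#' Each site is tested against the null that its methylated-read count
#' arises from a background rate `p0` (bisulfite non-conversion / error),
#' one-sided (alternative: greater), with Benjamini-Hochberg correction
#' across all tested sites of the stage. Sites rejecting at level `alpha`
#' are called `"methylated"`, the rest `"unmethylated"`.
#'
#' @param sites depth-filtered methylation `data.table` with `level`.
#' @param p0 null methylation rate, in (0, 1). Default 0.01.
#' @param alpha BH-adjusted significance level. Default 0.05.
#' @return the input with `pvalue`, `qvalue` and `call` columns added.
#' @export
call_methylated <- function(sites, p0 = 0.01, alpha = 0.05) {
  stopifnot(p0 > 0, p0 < 1, alpha > 0, alpha < 1)
  out <- data.table::copy(sites)
  ## one-sided exact binomial upper tail P(X >= m | n, p0)
  out[, pvalue := stats::pbinom(meth_reads - 1L, total_reads, p0,
                                lower.tail = FALSE)]
  out[, qvalue := stats::p.adjust(pvalue, method = "BH")]
  out[, call := ifelse(qvalue <= alpha, "methylated", "unmethylated")]
  out[]
}

#' Methylation-level bin labels
#' @return character vector of the five bin labels.
#' @export
methylation_bins <- function() {
  c("0-20%", "20-40%", "40-60%", "60-80%", "80-100%")
}

#' Assign a methylation level to one of five bins
#'
#' Bins are left-closed, right-open, with the top bin closed:
#' \[0, 0.2), \[0.2, 0.4), \[0.4, 0.6), \[0.6, 0.8), \[0.8, 1\]. Applied to
#' methylated-called sites.
#'
#' @param level numeric vector in \[0, 1\].
#' @return factor with levels [methylation_bins()].
#' @export
assign_bin <- function(level) {
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("level outside [0, 1]")
  cut(level, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9),
      labels = methylation_bins(), right = FALSE)
}

#' Three-state methylation code
#'
#' `H` (highly methylated) for level >= 0.7, `U` (unmethylated) for
#' level < 0.2, `M` (methylated) in between.
#'
#' @param level numeric vector in \[0, 1\].
#' @return character vector over `{H, M, U}`.
#' @export
three_state <- function(level) {
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("level outside [0, 1]")
  ifelse(level >= 0.7, "H", ifelse(level < 0.2, "U", "M"))
}

#' Sites covered in every stage
#'
#' A position enters the common set iff every stage covers it with at
#' least `min_reads` reads. Avoids coverage bias between stage samples.
#'
#' @param methylomes named list of canonical methylation `data.table`s,
#'   one per stage; names must cover `stages`.
#' @param stages required stage identifiers (default the canonical 13).
#' @param min_reads minimum depth per stage (default 5).
#' @return keyed `data.table` of (`chrom`, `pos`), sorted.
#' @export
common_sites <- function(methylomes, stages = germline_stages(),
                         min_reads = 5L) {
  missing <- setdiff(stages, names(methylomes))
  if (length(missing))
    stop("missing stages: ", paste(missing, collapse = ", "))
  keys <- lapply(stages, function(s) {
    m <- methylomes[[s]]
    unique(m[m$total_reads >= min_reads & m$context == "CpG",
             c("chrom", "pos")])
  })
  out <- Reduce(function(a, b) {
    merge(a, b, by = c("chrom", "pos"))
  }, keys)
  out <- data.table::as.data.table(out)
  data.table::setkeyv(out, c("chrom", "pos"))
  if (nrow(out) == 0L) warning("no sites common to all stages")
  out[]
}

#' Per-site level matrix across stages
#'
#' One row per common site, one `m_<stage>` column per stage with the
#' site-level methylation fraction.
#'
#' @inheritParams common_sites
#' @param sites keyed (`chrom`, `pos`) `data.table` (e.g. from
#'   [common_sites()]).
#' @return `data.table` with `chrom`, `pos` and `m_<stage>` columns.
#' @export
level_matrix <- function(methylomes, sites, stages = germline_stages()) {
  out <- data.table::copy(sites[, c("chrom", "pos")])
  data.table::setkeyv(out, c("chrom", "pos"))
  for (s in stages) {
    m <- data.table::as.data.table(methylomes[[s]])
    m <- m[, .(level = sum(meth_reads) / sum(total_reads)),
           by = c("chrom", "pos")]
    data.table::setkeyv(m, c("chrom", "pos"))
    out[, paste0("m_", s) := m[out, level]]
  }
  miss <- !stats::complete.cases(out)
  if (any(miss))
    stop(sum(miss), " common site(s) lack a level in some stage")
  out[]
}

#' Weighted methylation level of a tile
#'
#' Read-weighted, not site-averaged: the sum of methylated reads over the
#' sum of total reads across the sites of a tile.
#'
#' @param meth_reads,total_reads per-site read counts within one tile.
#' @return a single level, or `NA` if total coverage is zero.
#' @export
tile_weighted_methylation <- function(meth_reads, total_reads) {
  tot <- sum(total_reads)
  if (tot == 0) return(NA_real_)
  sum(meth_reads) / tot
}
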