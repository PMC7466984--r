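## Rare-variant filtering and 9-way mutation-type classification.
##
## Rare autosomal SNPs (allele frequency < 0.1%, call quality exactly 100)
## stand in for de novo germline mutations. Each retained SNP is assigned
## one of nine reference-context mutation types, collapsing the purine
## strand onto the pyrimidine strand (G>A == C>T on the other strand, etc.):
## three CpG-context pyrimidine changes (C>T, C>A, C>G) and six non-CpG
## changes (C>T, C>A, C>G, T>C, T>G, T>A).

#' The nine mutation types
#' @param include_unclassified also append `"UNCLASSIFIED"`.
#' @return character vector of type labels.
#' @export
mutation_types <- function(include_unclassified = FALSE) {
  t <- c("CpG_C>T", "CpG_C>A", "CpG_C>G",
         "nonCpG_C>T", "nonCpG_C>A", "nonCpG_C>G",
         "nonCpG_T>C", "nonCpG_T>G", "nonCpG_T>A")
  if (include_unclassified) c(t, "UNCLASSIFIED") else t
}

#' The three CpG-context mutation types
#' @return character vector.
#' @export
cpg_snp_types <- function() c("CpG_C>T", "CpG_C>A", "CpG_C>G")

#' Filter raw variants to the rare-SNP proxy set
#'
#' Applies, in order: structural/symbolic removal, indel removal,
#' multi-allelic removal, autosome restriction, frequency-unknown removal,
#' allele-frequency cutoff (strictly less than `max_af`), and quality
#' equality (`qual == qual_exact`). Each record is counted under the first
#' rule it fails, so the report categories plus `retained` sum to the input
#' count.
#'
#' @param raw raw-variant `data.table` from [read_vcf()].
#' @param autosome_names chromosomes considered autosomal (e.g.
#'   `paste0("chr", 1:22)` for hg19; arbitrary for toy genomes).
#' @param max_af allele-frequency cutoff; retained variants have
#'   `af < max_af`. Default 0.001 (rare variants, < 0.1%).
#' @param qual_exact required QUAL value (exact equality, the convention of
#'   the 1000 Genomes phase 3 call set). Set to `NA` to instead require
#'   `qual >= min_qual`.
#' @param min_qual lower bound used only when `qual_exact` is `NA`.
#' @return list with `variants` (retained records, single `ref`/`alt`
#'   bases, numeric `af`) and `report` (named integer vector of removal
#'   counts plus `retained`).
#' @export
filter_variants <- function(raw, autosome_names, max_af = 0.001,
                            qual_exact = 100, min_qual = 100) {
  stopifnot(is.character(autosome_names), length(autosome_names) > 0)
  dt <- data.table::copy(data.table::as.data.table(raw))
  n_in <- nrow(dt)
  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", dt$alt)
  symbolic <- isTRUE_vec(dt$symbolic) | grepl("<|\\[|\\]", dt$alt)
  indel <- !symbolic & !multi &
    (nchar(dt$ref) != 1L | nchar(dt$alt) != 1L |
       !(dt$ref %in% bases) | !(dt$alt %in% bases))
  ## multi-allelic SNP rule also catches multi-alt records whose alts are
  ## single bases; symbolic alts inside a multi-alt record count as symbolic
  multi_symbolic <- multi & grepl("<|\\[|\\]", dt$alt)
  symbolic <- symbolic | multi_symbolic
  multi <- multi & !symbolic
  non_auto <- !(dt$chrom %in% autosome_names)
  afn <- suppressWarnings(as.numeric(dt$af))
  funk <- isTRUE_vec(dt$freq_unknown) | is.na(afn)
  af_fail <- !is.na(afn) & afn >= max_af
  if (is.na(qual_exact)) {
    qual_fail <- is.na(dt$qual) | dt$qual < min_qual
  } else {
    qual_fail <- is.na(dt$qual) | dt$qual != qual_exact
  }

  reason <- rep(NA_character_, n_in)
  take <- function(cond, label) {
    idx <- which(is.na(reason) & cond)
    reason[idx] <<- label
  }
  take(symbolic, "structural")
  take(indel, "indel")
  take(multi, "multiallelic")
  take(non_auto, "non_autosomal")
  take(funk, "frequency_unknown")
  take(af_fail, "allele_frequency")
  take(qual_fail, "quality")

  keep <- is.na(reason)
  report <- c(
    structural = sum(reason == "structural", na.rm = TRUE),
    indel = sum(reason == "indel", na.rm = TRUE),
    multiallelic = sum(reason == "multiallelic", na.rm = TRUE),
    non_autosomal = sum(reason == "non_autosomal", na.rm = TRUE),
    frequency_unknown = sum(reason == "frequency_unknown", na.rm = TRUE),
    allele_frequency = sum(reason == "allele_frequency", na.rm = TRUE),
    quality = sum(reason == "quality", na.rm = TRUE),
    retained = sum(keep)
  )
  stopifnot(sum(report) == n_in)
  out <- dt[keep, .(chrom, pos, ref, alt, qual)]
  out[, af := afn[keep]]
  data.table::setkeyv(out, c("chrom", "pos"))
  list(variants = out[], report = report)
}

## treat absent/NA logical columns as FALSE
isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}

#' Classify filtered SNPs into the nine mutation types
#'
#' CpG context is determined from the reference genome only: a SNP is
#' CpG-context iff its reference base is the C of a CpG (next reference
#' base is G) or the G of a CpG (previous reference base is C). Purine-
#' strand changes are collapsed to the pyrimidine strand. SNPs whose
#' required neighbour base is `N` or off the chromosome end are labelled
#' `UNCLASSIFIED` and tallied in the skip report attribute, as are SNPs
#' whose stated `ref` disagrees with the genome.
#'
#' @param variants filtered variant `data.table` (`chrom`, `pos`, `ref`,
#'   `alt` single bases).
#' @param genome a [genome_seq()] covering the variant positions.
#' @return the input with added columns `mutation_type` and `cpg_context`
#'   (`"CpG"`, `"nonCpG"` or `"unknown"`); attribute `"skip_report"` counts
#'   `UNCLASSIFIED` records by cause.
#' @export
classify_mutations <- function(variants, genome) {
  dt <- data.table::copy(data.table::as.data.table(variants))
  n <- nrow(dt)
  ref_gen <- get_bases(genome, dt$chrom, dt$pos)
  prv <- get_bases(genome, dt$chrom, dt$pos - 1L)
  nxt <- get_bases(genome, dt$chrom, dt$pos + 1L)

  type <- rep("UNCLASSIFIED", n)
  ctx <- rep("unknown", n)
  cause <- rep(NA_character_, n)

  ref_mismatch <- is.na(ref_gen) | ref_gen != dt$ref
  cause[ref_mismatch] <- ifelse(is.na(ref_gen[ref_mismatch]),
                                "position_off_genome", "ref_mismatch")

  ## collapse purine strand: pyrimidine-strand ref/alt
  is_pur <- dt$ref %in% c("G", "A")
  pref <- ifelse(is_pur, .COMP[dt$ref], dt$ref)
  palt <- ifelse(is_pur, .COMP[dt$alt], dt$alt)

  ## the neighbour that decides CpG context: next base for ref C, previous
  ## base for ref G; T/A never CpG, no neighbour needed
  need_nb <- dt$ref %in% c("C", "G")
  nb <- ifelse(dt$ref == "C", nxt, ifelse(dt$ref == "G", prv, NA))
  nb_bad <- need_nb & (is.na(nb) | nb == "N")
  cause[is.na(cause) & nb_bad] <- "neighbor_unavailable"

  ok <- is.na(cause)
  is_cpg <- ok & ((dt$ref == "C" & nxt == "G") | (dt$ref == "G" & prv == "C"))
  ctx[ok] <- ifelse(is_cpg[ok], "CpG", "nonCpG")
  lab <- paste0(ifelse(is_cpg, "CpG", "nonCpG"), "_", pref, ">", palt)
  valid <- ok & lab %in% mutation_types()
  type[valid] <- lab[valid]
  cause[ok & !valid] <- "invalid_allele_pair"
  ctx[type == "UNCLASSIFIED"] <- "unknown"

  dt[, mutation_type := type]
  dt[, cpg_context := ctx]
  skip <- table(cause[!is.na(cause)])
  attr(dt, "skip_report") <- stats::setNames(as.integer(skip), names(skip))
  dt[]
}

#' Classify a single SNP
#' @inheritParams classify_mutations
#' @param chrom,pos,ref,alt one SNP.
#' @return a mutation-type label.
#' @export
classify_mutation <- function(chrom, pos, ref, alt, genome) {
  classify_mutations(
    data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt),
    genome
  )$mutation_type
}

#' Proportion of each mutation type in a catalog
#'
#' `UNCLASSIFIED` records are excluded from the denominator and reported
#' via the `"n_unclassified"` attribute.
#'
#' @param catalog classified catalog from [classify_mutations()].
#' @return named numeric vector of fractions over the nine types, summing
#'   to 1.
#' @export
type_proportions <- function(catalog) {
  if (nrow(catalog) == 0L) stop("empty catalog")
  cls <- catalog$mutation_type[catalog$mutation_type != "UNCLASSIFIED"]
  if (length(cls) == 0L) stop("no classified SNPs in catalog")
  tab <- table(factor(cls, levels = mutation_types()))
  out <- as.numeric(tab) / length(cls)
  names(out) <- mutation_types()
  attr(out, "n_unclassified") <- sum(catalog$mutation_type == "UNCLASSIFIED")
  out
}
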