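# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-record loops, direct formulas) and never call the package paths they
# check.

# genome with known hand-placed contexts
mini_genome <- function() {
  # chr1: positions 1..16
  #        1234567890123456
  genome_seq(c(chr1 = "ACGTACATATGTCGAT",
               chr2 = "TTACGGCGAA"))
}

tmp_file <- function(ext = "") tempfile(fileext = ext)

write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

# minimal VCF text with given body rows (tab-separated strings)
write_mini_vcf <- function(rows, path = tmp_file(".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
           "##contig=<ID=chr1,length=100000>",
           "##contig=<ID=chrX,length=100000>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  write_lines(c(hdr, rows), path)
}

# catalog row constructor
make_catalog <- function(chrom, pos, ref, alt, type) {
  data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         mutation_type = type)
}

# --- independent oracles -------------------------------------------------

# per-site loop: a site carries a SNP iff some catalog record of the given
# types sits at its C position, or at pos + 1 with reference G (the other
# cytosine of the same CpG)
naive_site_density <- function(sites, catalog, types) {
  hit <- 0L
  for (i in seq_len(nrow(sites))) {
    cm <- sites$chrom[i]; p <- sites$pos[i]
    rows <- catalog[catalog$chrom == cm & catalog$mutation_type %in% types, ]
    has <- any(rows$pos == p) ||
      any(rows$pos == p + 1L & rows$ref == "G" &
            startsWith(rows$mutation_type, "CpG"))
    if (has) hit <- hit + 1L
  }
  list(n_sites = nrow(sites), n_snps = hit,
       density = hit / nrow(sites))
}

# naive tile recount from raw sequence and catalog loops
naive_tile_stats <- function(chrom, start, end, genome, catalog) {
  s <- substring(genome$seq[[chrom]], start, end)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  cpg_start <- which(chars[-n] == "C" & chars[-1] == "G")
  # in-tile bases of CpGs, including straddlers at either edge
  full <- genome$seq[[chrom]]
  is_cpg_base <- function(p) {
    b <- substring(full, p, p)
    (b == "C" && p < nchar(full) && substring(full, p + 1, p + 1) == "G") ||
      (b == "G" && p > 1 && substring(full, p - 1, p - 1) == "C")
  }
  cpg_bases <- sum(vapply(start:end, is_cpg_base, logical(1)))
  noncpg_cg <- sum(vapply(start:end, function(p) {
    b <- substring(full, p, p)
    b %in% c("C", "G") && !is_cpg_base(p)
  }, logical(1)))
  in_tile <- function(rows) sum(rows$pos >= start & rows$pos <= end &
                                  rows$chrom == chrom)
  list(cpg_count = length(cpg_start),
       cpg_cg_bases = cpg_bases,
       noncpg_cg_bases = noncpg_cg,
       cpg_ct = in_tile(catalog[catalog$mutation_type == "CpG_C>T", ]),
       noncpg_ct = in_tile(catalog[catalog$mutation_type == "nonCpG_C>T", ]))
}

# average-rank Spearman by direct formula (Pearson on midranks)
naive_spearman <- function(x, y) {
  rk <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    out
  }
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Yates-corrected 2x2 chi-square by direct formula
naive_chisq_yates <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - e) - 0.5)^2 / e)
}

# small deterministic methylome builder: one stage table
make_stage_table <- function(chrom, pos, meth, total, stage = "sperm",
                             context = "CpG") {
  data.table::data.table(chrom = chrom, pos = pos, strand = "+",
                         context = context, meth_reads = meth,
                         total_reads = total, stage = stage)
}

# 13 stage tables covering the same positions at given depth
make_all_stages <- function(chrom, pos, level = 0.5, depth = 10L) {
  ms <- lapply(germline_stages(), function(s)
    make_stage_table(chrom, pos, round(level * depth), depth, stage = s))
  names(ms) <- germline_stages()
  ms
}
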