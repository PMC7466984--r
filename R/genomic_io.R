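## Readers/writers for the standard formats the pipeline touches.
##
## Coordinate conventions: point positions (VCF records, methylation rows)
## are 1-based throughout; intervals are carried as GenomicRanges objects
## (1-based closed) and converted to/from BED's 0-based half-open dialect
## only at the rtracklayer I/O boundary.

#' Construct a genome sequence object
#'
#' A light container for an in-memory reference genome: a named character
#' vector of uppercase chromosome sequences plus an optional soft-mask
#' (lowercase-in-source) logical vector per chromosome.
#'
#' @param seqs named character vector of nucleotide sequences (any case;
#'   stored uppercased).
#' @param mask optional named list of logical vectors, `TRUE` where the
#'   source base was soft-masked. Defaults to all-`FALSE`.
#' @return An object of class `genome_seq` with elements `seq` (uppercase
#'   sequences), `mask`, and `lengths`.
#' @export
genome_seq <- function(seqs, mask = NULL) {
  if (length(seqs) == 0L) stop("no sequences supplied")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  lens <- nchar(seqs)
  if (any(lens == 0L))
    stop("zero-length sequence: ", paste(names(seqs)[lens == 0L], collapse = ", "))
  up <- toupper(seqs)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad))
    stop("non-ACGTN characters in sequence: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (is.null(mask)) {
    mask <- lapply(lens, function(n) rep(FALSE, n))
    names(mask) <- names(seqs)
  }
  stopifnot(identical(names(mask), names(seqs)),
            all(vapply(mask, length, 1L) == lens))
  structure(list(seq = up, mask = mask, lengths = lens), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x$seq), "sequence(s):\n")
  for (nm in names(x$seq))
    cat(sprintf("  %s: %d bp (%d soft-masked)\n", nm, x$lengths[[nm]],
                sum(x$mask[[nm]])))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `genome_seq`.
#' @return named integer vector.
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  lens <- genome$lengths
  stats::setNames(as.integer(lens), names(lens))
}

#' Extract reference bases at 1-based positions
#'
#' Positions outside the chromosome return `NA`.
#'
#' @param genome a `genome_seq`.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 1-based positions.
#' @return character vector of single bases (or `NA`).
#' @export
get_bases <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "genome_seq"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_character_, n)
  for (cm in unique(chrom)) {
    i <- which(chrom == cm)
    if (!cm %in% names(genome$seq)) next
    L <- genome$lengths[[cm]]
    ok <- i[pos[i] >= 1L & pos[i] <= L]
    if (length(ok))
      out[ok] <- substring(genome$seq[[cm]], pos[ok], pos[ok])
  }
  out
}

#' Read a FASTA file into a genome_seq
#'
#' Sequences are uppercased; soft-masked (lowercase) bases are recorded in
#' the parallel mask rather than used for filtering (repeat exclusion is
#' driven by the repeat BED track, not the mask).
#'
#' @param path path to a FASTA file.
#' @return a [genome_seq()].
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(raw))
  seqs <- as.character(raw)
  names(seqs) <- nms
  if (anyDuplicated(nms))
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence in ", path, ": ",
         paste(nms[nchar(seqs) == 0L], collapse = ", "))
  mask <- lapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    v %in% c("a", "c", "g", "t", "n")
  })
  genome_seq(seqs, mask = mask)
}

#' Write a genome_seq to FASTA
#' @param genome a `genome_seq`.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seq[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a VCF into a raw-variant table
#'
#' Positions are kept 1-based. Multi-allelic records are emitted as a single
#' row with comma-separated `alt` (splitting and removal is the job of
#' [filter_variants()]). Allele frequency is resolved from the `AF` INFO
#' field, else derived as `AC/AN`; records with neither are flagged
#' `freq_unknown` rather than dropped. Symbolic (structural) ALT alleles are
#' flagged `symbolic`.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped).
#' @return `data.table` with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `af` (comma-separated per alt, `NA` when unknown), `symbolic`,
#'   `freq_unknown`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dt <- data.table::data.table(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  info_field <- function(key) {
    suppressWarnings(vcfR::extract.info(v, element = key))
  }
  af <- info_field("AF")
  ac <- info_field("AC")
  an <- suppressWarnings(as.numeric(info_field("AN")))
  derive <- is.na(af) & !is.na(ac) & !is.na(an) & an > 0
  if (any(derive)) {
    af[derive] <- vapply(which(derive), function(i) {
      acs <- as.numeric(strsplit(ac[i], ",")[[1]])
      paste(format(acs / an[i], digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ",")
    }, character(1))
  }
  dt[, af := af]
  dt[, symbolic := grepl("<|\\[|\\]", alt) | grepl("<|\\[|\\]", ref)]
  dt[, freq_unknown := is.na(af)]
  stopifnot(all(dt$pos >= 1L))
  dt[]
}

#' Write a variant table as a minimal VCF
#'
#' Emits an 8-column site-only VCF 4.2 with `AF` in INFO, consumable by
#' [read_vcf()] and standard VCF tooling.
#'
#' @param variants `data.table` with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `af` (character or numeric; `NA` writes no AF).
#' @param path output path.
#' @param contigs optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=methmut",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  info <- ifelse(is.na(variants$af), ".", paste0("AF=", variants$af))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ifelse(is.na(variants$qual), ".", variants$qual), "PASS",
                info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## canonical methylation TSV column set
.METH_COLS <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")

#' Read a per-cytosine methylation table
#'
#' The canonical dialect is a TSV with columns `chrom`, `pos` (1-based
#' cytosine position), `strand`, `context` (`CpG`/`CHG`/`CHH`),
#' `meth_reads`, `total_reads`; lines starting with `#` are provenance
#' comments. Adapters convert two common dialects to canonical form:
#' * `"bismark_cx"`: Bismark cytosine report
#'   (chrom, 1-based pos, strand, count methylated, count unmethylated,
#'   context, trinucleotide); total = methylated + unmethylated.
#' * `"bedmethyl"`: bedMethyl BED9+2 (0-based start; columns 10 and 11 are
#'   read coverage and percent methylation); `pos = start + 1`.
#'
#' Rows with non-CpG context are retained but flagged via the `context`
#' column (non-CpG density estimation counts reference bases, not these
#' rows).
#'
#' @param path input path.
#' @param stage_id stage label stored in the `stage` column.
#' @param dialect one of `"canonical"`, `"bismark_cx"`, `"bedmethyl"`.
#' @return `data.table` with the canonical columns plus `stage`.
#' @export
read_methylation_table <- function(path, stage_id,
                                   dialect = c("canonical", "bismark_cx",
                                               "bedmethyl")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) stop("no data rows in ", path)
  dt <- data.table::fread(text = lines, header = (dialect == "canonical"),
                          sep = "\t")
  if (dialect == "canonical") {
    missing <- setdiff(.METH_COLS, names(dt))
    if (length(missing))
      stop("canonical methylation table missing columns: ",
           paste(missing, collapse = ", "))
    dt <- dt[, .METH_COLS, with = FALSE]
  } else if (dialect == "bismark_cx") {
    data.table::setnames(dt, 1:6, c("chrom", "pos", "strand", "meth_reads",
                                    "unmeth_reads", "context"))
    dt[, total_reads := meth_reads + get("unmeth_reads")]
    dt[, context := ifelse(context == "CG", "CpG", context)]
    dt <- dt[, .METH_COLS, with = FALSE]
  } else { # bedmethyl
    if (ncol(dt) < 11L) stop("bedMethyl requires >= 11 columns")
    out <- data.table::data.table(
      chrom = as.character(dt[[1]]),
      pos = as.integer(dt[[2]]) + 1L, # 0-based start -> 1-based position
      strand = as.character(dt[[6]]),
      context = "CpG",
      total_reads = as.integer(dt[[10]])
    )
    out[, meth_reads := as.integer(round(total_reads * as.numeric(dt[[11]]) / 100))]
    dt <- out[, .METH_COLS, with = FALSE]
  }
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  if (any(dt$meth_reads < 0L | dt$total_reads < 0L))
    stop("negative read counts in ", path)
  bad <- which(dt$meth_reads > dt$total_reads)
  if (length(bad))
    stop("meth_reads > total_reads at row ", bad[1], " (",
         dt$chrom[bad[1]], ":", dt$pos[bad[1]], ") of ", path)
  dt[, stage := stage_id]
  data.table::setkeyv(dt, c("chrom", "pos"))
  dt[]
}

#' Write a canonical methylation table
#' @param sites `data.table` with the canonical columns.
#' @param path output path.
#' @param comments character vector of provenance comments (written with a
#'   `#` prefix before the header).
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(sites, path, comments = character()) {
  stopifnot(all(.METH_COLS %in% names(sites)))
  hdr <- c(if (length(comments)) paste0("# ", comments),
           paste(.METH_COLS, collapse = "\t"))
  writeLines(hdr, path)
  data.table::fwrite(sites[, .METH_COLS, with = FALSE], path, sep = "\t",
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED3+ with optional name/score/strand columns. BED's 0-based half-open
#' coordinates are converted to the 1-based closed `GRanges` convention by
#' rtracklayer; `start(gr) - 1` recovers the source 0-based start.
#'
#' @param path path to a BED file.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  ## validate end > start explicitly: rtracklayer error messages for
  ## malformed rows are opaque
  peek <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  peek <- peek[!grepl("^(track|browser|#)", peek[[1]])]
  if (nrow(peek) == 0L) stop("no intervals in ", path)
  s <- as.numeric(peek[[2]]); e <- as.numeric(peek[[3]])
  bad <- which(e <= s)
  if (length(bad))
    stop("BED interval with end <= start at data row ", bad[1], " of ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write a GRanges to BED
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
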