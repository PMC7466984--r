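## Disjoint genomic-region classes, fixed-width tiling, per-tile weighted
## methylation and C>T density measures, and Spearman correlation tables.
##
## Region precedence (highest first): repeat, promoter, CGI, enhancer,
## then exon / intron inside gene bodies; intergenic is the complement of
## every annotated track. Intragenic (the gene body outside higher-
## precedence classes) is the union of the final exon and intron sets, the
## one permitted containment.

#' Region class names
#' @return character vector.
#' @export
region_classes <- function() {
  c("promoter", "CGI", "enhancer", "intergenic", "intragenic",
    "exon", "intron", "repeat")
}

#' Promoter intervals around transcription start sites
#'
#' Strand-aware window from 1000 bp upstream to 200 bp downstream of the
#' TSS: `[TSS - 1000, TSS + 200)` on the plus strand, mirrored on the
#' minus strand. Trimmed to chromosome bounds.
#'
#' @param genes `GRanges` of gene bodies with strand.
#' @param seqlens named chromosome lengths.
#' @param upstream,downstream window extents in bp.
#' @return `GRanges` of promoters (metadata columns preserved).
#' @export
promoter_intervals <- function(genes, seqlens, upstream = 1000L,
                               downstream = 200L) {
  if (any(GenomicRanges::strand(genes) == "*"))
    stop("gene without strand; promoters need a TSS orientation")
  pr <- GenomicRanges::promoters(genes, upstream = upstream,
                                 downstream = downstream)
  GenomicRanges::start(pr) <- pmax(GenomicRanges::start(pr), 1L)
  GenomicRanges::end(pr) <- pmin(GenomicRanges::end(pr),
                                 seqlens[as.character(
                                   GenomeInfoDb::seqnames(pr))])
  pr
}

.reduce_sort <- function(gr) {
  GenomicRanges::sort(GenomicRanges::reduce(gr, ignore.strand = TRUE),
                      ignore.strand = TRUE)
}

.subtract <- function(a, b) {
  .reduce_sort(GenomicRanges::setdiff(.reduce_sort(a), .reduce_sort(b),
                                      ignore.strand = TRUE))
}

#' Build the disjoint region annotation
#'
#' From raw gene / exon / CGI / enhancer / repeat tracks, builds merged,
#' mutually exclusive region classes: repeats are excluded from every
#' other class; promoter > CGI > enhancer precedence resolves their
#' overlaps (in particular the promoter-enhancer and CGI-enhancer common
#' regions are removed from the enhancer class); exon and intron are gene
#' body minus all higher classes; intragenic is their union; intergenic is
#' the genome complement of every annotated track.
#'
#' @param genes `GRanges` of gene bodies with strand (TSS at the
#'   strand-aware 5' end).
#' @param exons `GRanges` of exons.
#' @param cgi `GRanges` of CpG islands.
#' @param enhancers `GRanges` of enhancers.
#' @param repeats `GRanges` of repeat elements.
#' @param seqlens named chromosome lengths (e.g. [seq_lengths()]).
#' @return named list of merged, sorted `GRanges`, one per
#'   [region_classes()] entry.
#' @export
build_region_annotation <- function(genes, exons, cgi, enhancers, repeats,
                                    seqlens) {
  genome_gr <- GenomicRanges::GRanges(
    names(seqlens), IRanges::IRanges(1L, as.integer(seqlens)))
  prom <- promoter_intervals(genes, seqlens)

  rep_ <- .reduce_sort(repeats)
  promoter <- .subtract(prom, rep_)
  cgi_f <- .subtract(cgi, c(rep_, promoter))
  enh_f <- .subtract(enhancers, c(rep_, promoter, cgi_f))
  higher <- .reduce_sort(c(rep_, promoter, cgi_f, enh_f))
  exon_f <- .subtract(exons, higher)
  intron_raw <- .subtract(genes, exons)
  intron_f <- .subtract(intron_raw, higher)
  intragenic <- .reduce_sort(c(exon_f, intron_f))
  all_tracks <- .reduce_sort(c(GenomicRanges::granges(genes), prom,
                               GenomicRanges::granges(cgi),
                               GenomicRanges::granges(enhancers), rep_))
  intergenic <- .subtract(genome_gr, all_tracks)

  list(promoter = promoter, CGI = cgi_f, enhancer = enh_f,
       intergenic = intergenic, intragenic = intragenic,
       exon = exon_f, intron = intron_f, `repeat` = rep_)
}

#' Cut merged intervals into fixed-width tiles
#'
#' Each interval is cut into consecutive windows from its start; terminal
#' partial windows are retained by default (downstream filters apply the
#' minimum-CpG rule).
#'
#' @param regions a `GRanges` of merged intervals.
#' @param window tile width in bp (1000 for region analysis, 1e6 for
#'   chromosome analysis).
#' @param drop_partial drop terminal windows narrower than `window`.
#' @return `GRanges` of tiles.
#' @export
tile_regions <- function(regions, window = 1000L, drop_partial = FALSE) {
  if (window <= 0) stop("window must be positive")
  st <- GenomicRanges::start(regions)
  en <- GenomicRanges::end(regions)
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  n_tiles <- pmax(ceiling((en - st + 1) / window), 1L)
  idx <- rep(seq_along(st), n_tiles)
  off <- unlist(lapply(n_tiles, function(k) seq_len(k) - 1L)) * window
  ts <- st[idx] + off
  te <- pmin(ts + window - 1L, en[idx])
  keep <- rep(TRUE, length(ts))
  if (drop_partial) keep <- (te - ts + 1L) == window
  GenomicRanges::GRanges(chr[idx][keep], IRanges::IRanges(ts[keep], te[keep]))
}

#' Tile whole chromosomes
#' @param seqlens named chromosome lengths.
#' @param window tile width (default 1 Mb).
#' @return `GRanges` of tiles with a `group` column holding the chromosome.
#' @export
tile_chromosomes <- function(seqlens, window = 1e6) {
  gr <- tile_regions(GenomicRanges::GRanges(
    names(seqlens), IRanges::IRanges(1L, as.integer(seqlens))), window)
  gr$group <- as.character(GenomeInfoDb::seqnames(gr))
  gr
}

#' Tile every region class
#' @param annotation named list from [build_region_annotation()].
#' @param window tile width.
#' @param classes which classes to tile (default all but `repeat`).
#' @return `GRanges` of tiles with a `group` column holding the class.
#' @export
tile_region_classes <- function(annotation, window = 1000L,
                                classes = setdiff(region_classes(),
                                                  "repeat")) {
  parts <- lapply(classes, function(cl) {
    t <- tile_regions(annotation[[cl]], window)
    if (length(t)) t$group <- cl
    t
  })
  do.call(c, parts)
}

#' Index reference C/G bases by CpG membership
#'
#' Per chromosome: sorted positions of CpG dinucleotide starts (the C),
#' of all C/G bases belonging to a CpG, and of C/G bases outside CpGs.
#'
#' @param genome a [genome_seq()].
#' @return named list per chromosome with `cpg_start`, `cpg_bases`,
#'   `noncpg_cg`.
#' @export
genome_base_index <- function(genome) {
  out <- lapply(names(genome$seq), function(cm) {
    s <- genome$seq[[cm]]
    cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
    cg <- if (cg[1] == -1L) integer() else as.integer(cg)
    cpg_bases <- sort(c(cg, cg + 1L))
    cpos <- gregexpr("C", s, fixed = TRUE)[[1]]
    gpos <- gregexpr("G", s, fixed = TRUE)[[1]]
    allcg <- sort(c(if (cpos[1] == -1L) integer() else as.integer(cpos),
                    if (gpos[1] == -1L) integer() else as.integer(gpos)))
    list(cpg_start = cg, cpg_bases = cpg_bases,
         noncpg_cg = setdiff(allcg, cpg_bases))
  })
  names(out) <- names(genome$seq)
  out
}

## counts of sorted positions falling in [starts, ends] (1-based closed)
.count_in <- function(pos_sorted, starts, ends) {
  findInterval(ends, pos_sorted) - findInterval(starts - 1L, pos_sorted)
}

#' Per-tile statistics: CpG content, methylation, C>T densities
#'
#' For each tile: the CpG dinucleotide count (fully contained CpGs), the
#' count of C/G bases at CpG sites (a CpG straddling the tile edge
#' contributes only its in-tile base), the count of C/G bases at non-CpG
#' sites, the CpG C>T and non-CpG C>T SNP counts and densities, and the
#' read-weighted methylation level per stage. Tiles with fewer than
#' `min_cpg` CpGs are dropped; a zero denominator leaves that density `NA`
#' for that measure only.
#'
#' @param tiles `GRanges` of tiles (optionally with a `group` column).
#' @param genome a [genome_seq()].
#' @param methylomes named list of CpG methylation tables (one per stage).
#' @param catalog classified catalog.
#' @param stages stages to compute methylation for.
#' @param min_cpg minimum fully contained CpGs per retained tile.
#' @return `data.table`, one row per retained tile: `chrom`, `start`,
#'   `end`, `group`, counts, `cpg_ct_density`, `noncpg_ct_density` and
#'   `meth_<stage>` columns.
#' @export
tile_stats <- function(tiles, genome, methylomes, catalog,
                       stages = germline_stages(), min_cpg = 5L) {
  bi <- genome_base_index(genome)
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(tiles)),
    start = GenomicRanges::start(tiles),
    end = GenomicRanges::end(tiles),
    group = if (!is.null(tiles$group)) tiles$group else NA_character_
  )
  dt[, tile_id := .I]
  cpg_ct <- catalog[catalog$mutation_type == "CpG_C>T", ]
  ncpg_ct <- catalog[catalog$mutation_type == "nonCpG_C>T", ]
  for (cm in unique(dt$chrom)) {
    i <- which(dt$chrom == cm)
    idx <- bi[[cm]]
    ## fully contained CpG: start position in [tile_start, tile_end - 1]
    dt[i, cpg_count := .count_in(idx$cpg_start, start, end - 1L)]
    dt[i, cpg_cg_bases := .count_in(idx$cpg_bases, start, end)]
    dt[i, noncpg_cg_bases := .count_in(idx$noncpg_cg, start, end)]
    dt[i, cpg_ct_snps := .count_in(sort(cpg_ct$pos[cpg_ct$chrom == cm]),
                                   start, end)]
    dt[i, noncpg_ct_snps := .count_in(sort(ncpg_ct$pos[ncpg_ct$chrom == cm]),
                                      start, end)]
  }
  dt <- dt[cpg_count >= min_cpg]
  dt[, cpg_ct_density := ifelse(cpg_cg_bases > 0,
                                cpg_ct_snps / cpg_cg_bases, NA_real_)]
  dt[, noncpg_ct_density := ifelse(noncpg_cg_bases > 0,
                                   noncpg_ct_snps / noncpg_cg_bases,
                                   NA_real_)]
  ## weighted methylation per stage over CpG rows falling in each tile
  tl <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
  for (s in stages) {
    m <- methylomes[[s]]
    m <- m[m$context == "CpG"]
    sg <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$pos, m$pos))
    ov <- GenomicRanges::findOverlaps(sg, tl)
    mr <- tapply(m$meth_reads[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), sum)
    tr <- tapply(m$total_reads[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), sum)
    lev <- rep(NA_real_, nrow(dt))
    ti <- as.integer(names(mr))
    vals <- as.numeric(mr) / as.numeric(tr)
    vals[as.numeric(tr) == 0] <- NA_real_
    lev[ti] <- vals
    dt[, paste0("meth_", s) := lev]
  }
  dt[]
}

#' Spearman correlation of methylation vs C>T density per group and stage
#'
#' For each group (region class or chromosome), stage and measure (CpG
#' C>T density, non-CpG C>T density), the Spearman correlation across
#' tiles of per-tile weighted methylation against per-tile density. Ties
#' get average ranks; p-values from the t transform. Groups with fewer
#' than `min_tiles` complete tiles are skipped; constant vectors yield an
#' `NA` rho (reported missing).
#'
#' @param tile_dt output of [tile_stats()].
#' @param stages stages to correlate.
#' @param min_tiles minimum complete tiles per group (default 10).
#' @return `data.table` with `group`, `stage`, `measure`, `rho`,
#'   `p_value`, `n_tiles`.
#' @export
region_correlations <- function(tile_dt, stages = germline_stages(),
                                min_tiles = 10L) {
  min_tiles <- max(min_tiles, 3L) # a rank correlation needs >= 3 points
  rows <- list()
  for (g in unique(tile_dt$group)) {
    sub <- tile_dt[tile_dt$group == g]
    for (s in stages) {
      mcol <- sub[[paste0("meth_", s)]]
      for (meas in c("cpg", "noncpg")) {
        d <- if (meas == "cpg") sub$cpg_ct_density else sub$noncpg_ct_density
        ok <- !is.na(mcol) & !is.na(d)
        if (sum(ok) < min_tiles) next
        if (stats::sd(mcol[ok]) == 0 || stats::sd(d[ok]) == 0) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            group = g, stage = s, measure = meas, rho = NA_real_,
            p_value = NA_real_, n_tiles = sum(ok))
          next
        }
        ct <- suppressWarnings(stats::cor.test(mcol[ok], d[ok],
                                               method = "spearman",
                                               exact = FALSE))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          group = g, stage = s, measure = meas,
          rho = unname(ct$estimate), p_value = ct$p.value,
          n_tiles = sum(ok))
      }
    }
  }
  data.table::rbindlist(rows)
}
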