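## End-to-end orchestration: chain the analysis stages over synthetic or
## user-supplied inputs, writing TSV/JSON outputs plus a run manifest.
## Reruns with identical inputs and configuration are byte-identical.

#' Analysis thresholds
#'
#' All paper-stated defaults in one place: allele-frequency cutoff 0.1%,
#' QUAL exactly 100, at least 5 reads per site, at least 5 CpGs per tile,
#' at least 10 SNPs per ranked pattern, 1 kb region windows, 1 Mb
#' chromosome windows, three-state cutoffs 70% / 20% (fixed in
#' [three_state()]), binomial call parameters p0 = 0.01 / alpha = 0.05.
#'
#' @param ... overrides by name.
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function(...) {
  th <- list(max_af = 0.001, qual = 100, min_reads = 5L, p0 = 0.01,
             alpha = 0.05, min_cpg_per_tile = 5L, min_snps_per_pattern = 10L,
             window_region = 1000L, window_chrom = 1e6, top_k = 20L,
             min_tiles = 10L, bottom_k = 20L)
  utils::modifyList(th, list(...))
}

.write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  path
}

#' Run the analysis pipeline
#'
#' With no `inputs`, generates a complete synthetic dataset under
#' `config`, writes the generated inputs under `out_dir/inputs/`, then
#' runs every analysis stage and writes its tables under `out_dir`:
#' filter report, classified catalog, type proportions, per-stage
#' site-level mutability profiles with trend and chi-squared tests,
#' dynamic-pattern tables, the regression table, regional and chromosomal
#' correlation tables, promoter statistics and expression correlations,
#' plus `manifest.json` (configuration, thresholds, output checksums,
#' package version).
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()] driving the generator.
#' @param thresholds a [pipeline_thresholds()] list.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         thresholds = pipeline_thresholds(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  th <- thresholds

  say("simulate: generating synthetic dataset (seed ", config$seed, ")")
  ds <- simulate_dataset(config)
  autosomes <- names(ds$genome$seq)
  write_fasta(ds$genome, file.path(out_dir, "inputs", "genome.fa"))
  write_vcf(ds$variants, file.path(out_dir, "inputs", "variants.vcf"),
            contigs = seq_lengths(ds$genome))
  for (s in germline_stages())
    write_methylation_table(ds$methylomes[[s]],
                            file.path(out_dir, "inputs",
                                      paste0("meth_", s, ".tsv")),
                            comments = paste0("stage=", s))
  for (nm in names(ds$annotations))
    write_bed(ds$annotations[[nm]],
              file.path(out_dir, "inputs", paste0(nm, ".bed")))

  say("classify: filtering and typing variants")
  flt <- filter_variants(ds$variants, autosomes, max_af = th$max_af,
                         qual_exact = th$qual)
  catalog <- classify_mutations(flt$variants, ds$genome)
  jsonlite::write_json(as.list(flt$report),
                       file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE)
  .write_tsv(catalog, file.path(out_dir, "catalog.tsv"))
  props <- type_proportions(catalog)
  .write_tsv(data.table::data.table(type = names(props),
                                    proportion = as.numeric(props)),
             file.path(out_dir, "type_proportions.tsv"))

  say("site: methylation calls and stage profiles")
  called <- lapply(ds$methylomes, function(m) {
    call_methylated(depth_filter(m, th$min_reads), p0 = th$p0,
                    alpha = th$alpha)
  })
  profiles <- list(); tests <- list()
  for (s in germline_stages()) {
    pr <- suppressWarnings(stage_bin_profile(called[[s]], catalog))
    pr[, stage := s]
    profiles[[s]] <- pr
    tr <- tryCatch(bin_trend_correlation(pr), error = function(e) NULL)
    mv <- tryCatch(meth_vs_unmeth_test(pr), error = function(e) NULL)
    tests[[s]] <- data.table::data.table(
      stage = s,
      pearson_r = if (is.null(tr)) NA_real_ else tr$r,
      pearson_p = if (is.null(tr)) NA_real_ else tr$p_value,
      chi2 = if (is.null(mv)) NA_real_ else mv$chi2,
      chi2_p = if (is.null(mv)) NA_real_ else mv$p_value)
  }
  profile_dt <- data.table::rbindlist(profiles)
  .write_tsv(profile_dt, file.path(out_dir, "site_profiles.tsv"))
  .write_tsv(data.table::rbindlist(tests),
             file.path(out_dir, "site_tests.tsv"))

  say("patterns: common sites and dynamic-pattern mutability")
  cs <- common_sites(ds$methylomes, min_reads = th$min_reads)
  lmat <- level_matrix(ds$methylomes, cs)
  pats <- enumerate_patterns(lmat)
  pm <- pattern_mutability(pats$patterns, catalog,
                           min_snps = th$min_snps_per_pattern,
                           top_k = th$top_k)
  .write_tsv(pm$full, file.path(out_dir, "patterns_full.tsv"))
  .write_tsv(pm$top, file.path(out_dir, "patterns_top.tsv"))

  say("regress: per-site linear model across stages")
  design <- build_design(lmat, snp_positions(catalog))
  full <- fit_ols(design)
  stepped <- stepwise_select(design)
  reg_tab <- regression_table(full, stepped)
  .write_tsv(reg_tab, file.path(out_dir, "regression_table.tsv"))

  say("regional: tiled correlations by region class and chromosome")
  ann <- build_region_annotation(ds$annotations$genes, ds$annotations$exons,
                                 ds$annotations$cgi,
                                 ds$annotations$enhancers,
                                 ds$annotations$repeats,
                                 seq_lengths(ds$genome))
  tiles_r <- tile_region_classes(ann, th$window_region)
  ts_r <- tile_stats(tiles_r, ds$genome, ds$methylomes, catalog,
                     min_cpg = th$min_cpg_per_tile)
  cor_r <- region_correlations(ts_r, min_tiles = th$min_tiles)
  .write_tsv(ts_r, file.path(out_dir, "tiles_regional.tsv"))
  .write_tsv(cor_r, file.path(out_dir, "correlations_regional.tsv"))
  tiles_c <- tile_chromosomes(seq_lengths(ds$genome), th$window_chrom)
  ts_c <- tile_stats(tiles_c, ds$genome, ds$methylomes, catalog,
                     min_cpg = th$min_cpg_per_tile)
  cor_c <- region_correlations(ts_c, min_tiles = 1L)
  .write_tsv(cor_c, file.path(out_dir, "correlations_chromosomal.tsv"))

  say("promoter: CpG O/E, SNP density and expression proxy")
  pstats <- suppressWarnings(promoter_stats(ds$annotations$genes,
                                            ds$genome, catalog))
  .write_tsv(pstats, file.path(out_dir, "promoter_stats.tsv"))
  ec <- expression_correlations(ds$expression$expr,
                                ds$expression$truth$promoter_meth,
                                ds$expression$tissues,
                                bottom_k = th$bottom_k)
  .write_tsv(ec, file.path(out_dir, "expression_correlations.tsv"))

  say("manifest")
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  outs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                       "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, outs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("methmut")),
    config_md5 = unname(tools::md5sum(cfg_json)),
    thresholds = th,
    checksums = as.list(stats::setNames(unname(sums), outs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = ds, filter = flt, catalog = catalog,
                 called = called, profiles = profile_dt,
                 tests = data.table::rbindlist(tests),
                 common = cs, level_matrix = lmat, patterns = pm,
                 design = design, fit = full, stepwise = stepped,
                 regression_table = reg_tab, annotation = ann,
                 tile_stats = ts_r, correlations_regional = cor_r,
                 correlations_chromosomal = cor_c,
                 promoter_stats = pstats, expression = ec))
}
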