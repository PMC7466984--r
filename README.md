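# methmut

Methylation dynamics and germline CpG mutability across human germline
development.

`methmut` is an R package for asking how the DNA methylation state of the
germline — sperm, oocyte, pre-implantation embryos, and primordial germ
cells (PGCs) sampled across gestational weeks, thirteen stages in all —
relates to the germline CpG mutation rate. It is written for genomicists
and statistical geneticists who have per-cytosine whole-genome bisulfite
sequencing (WGBS) count tables, a population VCF, and standard annotation
tracks, and who want the complete analysis chain from raw inputs to
correlation and regression tables, plus a synthetic-data generator with
known ground truth for validating every step.

## The statistics at its core

Rare variants (allele frequency < 0.1%, from a large population call set)
proxy de novo germline mutations. The package:

* filters variants (SNV, single alt, autosomal, AF < 0.1%, QUAL = 100)
  and classifies each SNP into **9 mutation types** from reference
  context, collapsing strands: CpG C>T / C>A / C>G and non-CpG
  C>T / C>A / C>G / T>C / T>G / T>A;
* estimates the mutation rate as **SNP density** — sites carrying a
  CpG-context SNP over eligible sites — per stage, per methylation
  category (methylated / unmethylated by exact binomial test with BH
  correction; five level bins over methylated sites), with Pearson trend
  and chi-squared contrasts;
* enumerates **dynamic methylation patterns** (the 13-character H/M/U
  string of a site's state across stages, H ≥ 70%, U < 20%) over sites
  covered ≥ 5× in all stages, and ranks patterns by mutability
  (≥ 10 SNPs required);
* fits a **linear probability model**: per-site mutation indicator
  (0/1) on the 13 raw stage methylation levels, with AIC stepwise
  selection to find the most informative stages;
* builds disjoint genomic region classes (promoter, CGI, enhancer,
  exon, intron, intragenic, intergenic; repeats excluded from all), cuts
  them into 1 kb tiles (1 Mb for chromosomes), and correlates per-tile
  **weighted methylation** (Σ methylated reads / Σ total reads) with
  CpG C>T and non-CpG C>T density (Spearman);
* computes promoter **CpG O/E** = (N<sub>CpG</sub> · L) /
  (N<sub>C</sub> · N<sub>G</sub>) and promoter SNP density, and
  correlates each with gene expression per tissue — expression being a
  negative proxy for promoter methylation — to ask whether germline
  tissues show the strongest methylation–mutation coupling.

## Worked example

Everything below runs in seconds on the built-in generator (1 Mb toy
genome, ~20,000 CpGs, 13 stage methylomes, methylation-dependent
variants):

```r
library(methmut)
ds  <- simulate_dataset(sim_config(seed = 1))
flt <- filter_variants(ds$variants, autosome_names = "chr1")
flt$report
#>        structural             indel      multiallelic     non_autosomal
#>                 0                 0                 0                 0
#> frequency_unknown  allele_frequency           quality          retained
#>                 0               224               197              4004

ctl    <- classify_mutations(flt$variants, ds$genome)
called <- call_methylated(depth_filter(ds$methylomes$sperm))
pr     <- stage_bin_profile(called, ctl)
pr
#>        category n_sites n_snps    density
#> 1:          all   19927   2201 0.11045315
#> 2:   methylated   18719   2177 0.11629895
#> 3: unmethylated    1208     24 0.01986755
#> 4:        0-20%     697     16 0.02295552
#> 5:       20-40%    1220     54 0.04426230
#> 6:       40-60%    2069    169 0.08168197
#> 7:       60-80%    3338    377 0.11294188
#> 8:      80-100%   11395   1561 0.13698991

bin_trend_correlation(pr)
#> $r
#> [1] 0.9965616
#> $p_value
#> [1] 0.0002419034
```

Reading the output: 4,004 of 4,425 simulated variants survive the
rare-SNP filters (224 lost to the 0.1% AF cutoff, 197 to QUAL ≠ 100). In
the sperm stage, methylated CpGs mutate at 11.6% versus 2.0% for
unmethylated ones (chi-squared = 106.4, p ≈ 6e-25), and density rises
monotonically across the five methylation bins (Pearson r = 0.997) — the
generator's causal sperm effect, recovered by the pipeline. The remaining
stages, the pattern ranking, the regression table, the regional
correlation tables and the expression proxy come from `run_pipeline()`,
which writes every table plus a manifest:

```r
run_pipeline("out", config = sim_config(seed = 1))
```

A thin command-line wrapper is installed at
`inst/cli/methmut.R` (`Rscript methmut.R all --out out --seed 1`).

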