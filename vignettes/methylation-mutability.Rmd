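---
title: "Methylation dynamics and germline CpG mutability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation dynamics and germline CpG mutability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Spontaneous deamination converts 5-methylcytosine to thymine; uncorrected,
a methylated CpG becomes a TpG and the change is inherited if it happens in
the germline. The deamination rate of methylated cytosine is roughly 2-3
times that of unmethylated cytosine, so the *dynamic* methylation state of
the germline — sperm, oocyte, the pre-implantation embryo, and primordial
germ cells (PGCs) across gestational weeks — should shape where germline
point mutations accumulate. `methmut` implements a complete analysis of
this question at three scales (single site, dynamic pattern, genomic
region), plus an expression-based promoter proxy, using rare population
variants (allele frequency < 0.1%) as a stand-in for de novo germline
mutations: at such frequencies selection and biased gene conversion have
had little opportunity to act, so rare-variant density approximates the
mutation rate.

# The estimators

**Mutation rate as SNP density.** For a set of eligible CpG sites, the
mutation-rate estimate is the fraction of sites carrying at least one
CpG-context SNP (types CpG C>T, C>A, C>G). Multiple records at a cytosine
count once, so the density is a per-site probability mass and stays in
[0, 1]. A CpG dinucleotide contributes two cytosines — the plus-strand C
and the minus-strand C (the reference G); a SNP at either belongs to the
same CpG site, and `snp_positions()` collapses the G-side record to the C
position so that site keys line up with the methylome, which reports the
plus-strand C.

**Nine mutation types.** Every filtered SNP collapses to the pyrimidine
strand (G>A is C>T read from the other strand, and so on) and is typed by
reference context: three CpG types (C>T, C>A, C>G) and six non-CpG types
(C>T, C>A, C>G, T>C, T>G, T>A). Context comes from the reference genome
only, never from methylation tables. A SNP whose deciding neighbour base
is N or off the chromosome end is UNCLASSIFIED and counted in a skip
report, keeping denominators auditable.

**Methylation level and calls.** A site's level is methylated reads over
total reads; only sites with at least 5 reads are used. Methylated sites
are identified by a one-sided exact binomial test against a background
rate `p0` (default 0.01, a typical bisulfite non-conversion/error rate),
Benjamini–Hochberg corrected across the sites of a stage at `alpha = 0.05`.
The background rate, alpha, and the correction are parameters because no
standard fixes them; the defaults are the package's reproducible choice.
Methylated sites are binned into five level classes ([0,0.2), [0.2,0.4),
[0.4,0.6), [0.6,0.8), [0.8,1]); bins are left-closed with a closed top so
they partition [0,1]. The three-state code used for dynamic patterns is
H (level ≥ 0.7), U (level < 0.2), M otherwise.

**Dynamic patterns.** Over the sites covered with ≥ 5 reads in *all* 13
stages (the common set, which removes coverage bias between stage
samples), each site's pattern is its 13-character H/M/U string in fixed
stage order (sperm, oocyte, 8cell, morula, ICM, then PGCs by week and
sex). Pattern mutability is the CpG SNP density over the pattern's member
sites; only patterns with ≥ 10 SNPs enter the ranking. Ties are broken by
descending site count, then lexicographic code, for determinism.

**Stage regression.** Over the common sites, the binary mutation state
(1 if a CpG-type SNP lies at the site) is regressed on the 13 raw stage
levels with OLS — a linear probability model, chosen because the
coefficient table of interest is plainly an OLS table and coefficients
read directly as additive changes in mutation probability per unit
methylation (a logistic option exists). Stepwise selection starts from
the full model and takes add/drop steps minimising AIC (direction both,
`stats::step`) until no move helps; an intercept is always included.

**Regional association.** The genome is split into disjoint region
classes with an explicit precedence: repeats are removed from everything;
then promoter (strand-aware TSS −1000 to +200) > CpG island > enhancer
(the promoter–enhancer and CGI–enhancer common regions are removed from
the enhancer class); exon and intron are the gene body minus all higher
classes; intragenic is their union (the one permitted containment); and
intergenic is the complement of every annotated track. Repeats are
subtracted last; since set subtraction commutes here, the order only
matters for documentation. Each class is cut into 1 kb tiles (1 Mb for
chromosome-scale analysis) from each merged interval's start, terminal
partial tiles retained; tiles with fewer than 5 fully contained CpGs are
dropped. Per tile: weighted methylation (sum of methylated reads over sum
of total reads — read-weighted, not site-averaged), CpG C>T density (CpG
C>T SNPs over C/G bases at CpG sites; a CpG straddling a tile edge
contributes only its in-tile base), and non-CpG C>T density (non-CpG C>T
SNPs over non-CpG C/G bases). Spearman correlations (average ranks for
ties, t-transform p-values) relate per-tile methylation to each density
per class × stage.

**Promoter proxy.** Promoter CpG O/E uses the Gardiner–Garden form
`(N_CpG × L) / (N_C × N_G)` with N bases excluded from counts and length
(an `L − 1` dinucleotide normalisation is available as an option); low
values record historical methylation-driven CpG loss, i.e. an
evolutionary-timescale mutation-rate readout. Promoter SNP density uses
all three CpG SNP types by default (C>T-only is an option, since the
source analyses are not explicit). Expression is used strictly as a
*negative proxy* for promoter methylation — promoter methylation
represses transcription — so per-tissue Spearman correlations between
expression and a promoter statistic are computed and tissues ranked by
rho; the count of germline tissues among the 20 most negative
correlations is the summary of interest. No methylation values are ever
inferred from expression.

# The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised
end-to-end against known ground truth, with no downloads. Its defaults
encode the emulated study conditions and are deliberately fixed:

* **Genome**: 1 chromosome × 1 Mb (the recovery analyses use 10 Mb),
  CpG dinucleotides placed at 2% per position against a CG-free
  background (so the CpG position list is exact), with CGI blocks
  (10 per Mb, 2 kb, 10% CpG rate).
* **Methylomes**: latent site levels follow a hierarchical model. Each
  stage has a background mean (sperm 0.85 — sperm stays over 80%
  genome-wide; oocyte 0.55; cleavage/ICM stages ≈ 0.4, reflecting
  post-fertilisation demethylation; PGC stages 0.08–0.30, reflecting PGC
  erasure). CpG islands are scaled to 15% of the background mean in every
  stage. A per-1 kb-block Gaussian effect (sd 1.5 on the logit scale)
  gives the regional coherence real methylomes have — without it,
  tile-level methylation is nearly constant and regional correlations are
  untestable — and site levels are Beta-distributed around the block mean
  (concentration 8). Read depth is negative-binomial (mean 30, shape 2),
  the overdispersed coverage of real WGBS, so a realistic fraction of
  sites falls under the 5-read filter; methylated counts are binomial
  with a symmetric bisulfite error of 0.005.
* **Mutations**: a CpG site mutates with probability
  `b0 + Σ_s β_s m_{i,s}` (clipped to [0,1]); defaults `b0 = 0.01`,
  `β_sperm = 0.15`, all other β = 0, so the sperm stage is the causal
  stage. A mutated CpG draws C>T with probability 0.8, else C>A/C>G
  equally, and is reported at the C or the G of the CpG with equal
  probability (exercising strand collapse). Non-CpG C/G and T/A
  positions mutate at 0.002 with uniform type choice. The linear effect
  is the default so the regression model is correctly specified in
  recovery tests; a multiplicative deamination-fold mode was considered
  and rejected for the default because it would conflate model
  misspecification with estimator error in every recovery check.
* **Variants**: allele frequencies are drawn below 0.1% with a 5%
  contamination above it, and QUAL is 100 with a 5% fraction at other
  values, so the AF and QUAL filters are genuinely exercised.
* **Expression**: a standalone panel of 2,000 genes × 40 tissues (20
  germline, 20 somatic); expression is `c_t · meth_g + noise` with
  `c_t = −0.5` for germline tissues and 0 for somatic ones (noise sd
  0.3). The panel is independent of the toy genome because a ~20-gene
  toy annotation cannot support rank correlations.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: hg19 base composition and repeat content,
selection and biased gene conversion, shared regional methylation
structure *across* stages (block effects are drawn independently per
stage, islands excepted), sex chromosomes, and alignment/calling
artefacts. In particular, real sperm methylomes are more uniformly
hypermethylated than the simulated one; at toy scale the pattern ranking
is dominated by small-count patterns (a winner's-curse effect), so
sperm-H enrichment among top-ranked patterns is quantitative here rather
than absolute.

# Numerical and design choices

* **Intervals**: GenomicRanges (1-based closed) internally; BED's
  0-based half-open dialect converted only at the I/O boundary, VCF and
  methylation positions kept 1-based.
* **QUAL filter**: exact equality with 100 by default (the convention of
  the emulated call set), with a minimum-quality mode for other callers.
* **Errors-in-variables**: regressing on observed (read-sampled) levels
  attenuates coefficients; at depth ~30 the attenuation is several times
  the coefficient's standard error at the scales used here. Recovery
  tests therefore regress on the generator's latent levels and
  ground-truth mutation labels — they validate the regression machinery,
  not the read-noise bias, which is documented as a known property of
  the observed-data pipeline.
* **Stepwise calibration**: with AIC, a pure-noise term is retained with
  probability ≈ 0.157 per fit (inflated slightly by linear-probability
  heteroskedasticity), so across 20 replicates a noise stage is expected
  to be dropped ~16/20 times; individual stages can land lower by
  sampling variation.
* **Degenerate inputs**: empty site categories, empty pattern rankings,
  constant correlation vectors, zero denominators, and missing stages
  all produce warnings/`NA`s or named errors rather than silent results.
* **Problem sizes**: unit tests run at 0.05–0.5 Mb; recovery analyses at
  10 Mb × 20 replicates with ~200,000 CpG sites each, the package's
  chosen full-scale study condition.

# Limitations

The analysis is correlational; it cannot separate methylation's causal
contribution from co-varying genomic features (replication timing, GC
content, chromatin state) that are not modelled here. The rare-variant
proxy inherits the ascertainment of the source call set. The X chromosome
and sex-stratified analyses are out of scope, as is any reprocessing of
raw bisulfite or variant data: the package starts from per-cytosine count
tables and a VCF.
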