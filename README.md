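# pcharm

Tools for building and analysing a **harmonized multi-study prostate cancer
resource** in R: per-study containers for expression, copy-number and
mutation assays under a shared clinical data dictionary, gene-symbol
harmonization across platforms, prognostic and androgen-receptor (AR)
signature scoring with a simulated gene-dropout robustness benchmark,
cross-study moderated-t differential expression, somatic-alteration
mutual-exclusivity statistics, and score-stratified survival analysis.

The package is aimed at cancer genomics analysts who work across several
independent cohorts — each with its own platform, gene universe and clinical
annotation conventions — and who need the cross-study steps (harmonize,
score, combine, stratify) to be reproducible and testable. A seeded
synthetic multi-study generator emulates the structure of real cohorts
(Gleason grade groups, biochemical-recurrence follow-up, partially
overlapping gene universes, GISTIC-style copy-number calls, MAF-like
mutations), so the entire pipeline runs and is tested without any external
downloads.

## Methods at the core

**Signature scoring.** A signature is a set of genes *g₁…g_m* with
directions *dᵢ*, weights *wᵢ* and optionally groups. Per-gene expression is
normalized across samples (z-score *(x−x̄)/s*, fractional percentile rank,
or centering) and combined: mean *(1/m)Σ dᵢx̃ᵢⱼ*, weighted sum
*Σ wᵢdᵢx̃ᵢⱼ*, grouped linear *Σ_G w_G · mean_{i∈G}(dᵢx̃ᵢⱼ)*, or signed
percentile mean (mean percentile of up-markers minus that of down-markers).
Built-in research transcriptions: the 20-gene AR activity score (z-score +
mean), a 12-gene 4-module score, a 34-gene cell-cycle progression score and
a 20-marker signed genomic classifier. Signature genes are matched to
matrix rows through an alias dictionary and bucketed *single* (1-to-1,
usable), *multiple* (1-to-many, excluded) or *missing*.

**Gene-dropout benchmark.** For dropout sizes *k = k_min…k_max*, distinct
*k*-subsets of the signature are removed, the score recomputed, and the
Pearson correlation with the full-gene score recorded — quantifying how
robust a score is on platforms missing some of its genes.

**Cross-study differential expression.** Per study, logFC = mean log₂
expression of Gleason grade ≥8 samples minus the ≤6 mean; a moderated
t-statistic shrinks each per-gene variance *s²_g* (with *d_g* df) towards
an empirical-Bayes prior *(d₀, s₀²)* fitted by moment-matching the log-
variance distribution (trigamma inversion), giving
*s̃²_g = (d₀s₀² + d_g s²_g)/(d₀+d_g)* and *t̃ = logFC/(s̃√(1/n_h+1/n_l))* on
*d₀+d_g* df. Studies are combined per gene with Fisher's method
(*−2Σln pᵢ* vs χ² with 2k df), BH-adjusted across genes, and selected only
when the logFC sign agrees in every study.

**Alterations.** A sample is *altered* in a gene iff its GISTIC call is
non-zero or it carries a non-silent mutation. For a gene pair the odds
ratio is the count formula OR = (Both·Neither)/(A-only·B-only) with a
two-sided Fisher exact p, BH across the screened pairs.

**Survival.** Scores stratify samples into the top tertile (⌈n/3⌉ by rank,
ties broken by sample id) vs bottom two-thirds; Kaplan-Meier curves,
log-rank tests and univariate Cox fits (Efron ties) relate strata, scores
or grade groups to biochemical recurrence or overall survival.

## Worked example

```r
library(pcharm)

cfg <- sim_config(n_studies = 4, n_samples = 150, n_genes = 800,
                  de_genes = 40, seed = 42)
studies <- simulate_multistudy(cfg)
studies[[1]]
#> study bundle 'study1'
#>   gex: 150, cna: 150, mut: 86, primary: 150

# cross-study meta-differential expression between grade groups
de  <- lapply(studies, differential_expression)
res <- meta_de(de, q_threshold = 0.01)
res
#> meta-DE over 4 studies, 800 common genes; q < 0.01: 20 up, 20 down

# AR signature scoring and its robustness to missing genes
sv <- score_signature("ar", studies[[1]]$expression)
sv
#> signature 'ar' scores for 150 samples using 20 genes
bench <- benchmark_missingness("ar", studies[[1]]$expression,
                               k_min = 1, k_max = 5, seed = 42)
summarize_missingness(bench)
#>   k n_combinations mean_corr median_corr       q05       q95
#> 1 1             20 0.9761731   0.9761064 0.9759488 0.9766500
#> 2 2            100 0.9517723   0.9522364 0.9440389 0.9590624
#> 3 3            100 0.9272049   0.9278128 0.9155460 0.9389668
#> 4 4            100 0.8981382   0.8987286 0.8774500 0.9180710
#> 5 5            100 0.8730567   0.8726834 0.8529157 0.8979674

# latent "endothelial-like" program: top tertile vs rest for recurrence
ms     <- marker_score(attr(studies[[1]], "truth")$markers,
                       studies[[1]]$expression)
labels <- stratify_top_tertile(ms$score)
sd     <- survival_data(studies[[1]]$clinical, "bcr", covariate = labels)
cox_univariate(sd)
#> univariate Cox fit (efron ties): HR = 3.081 [2.022, 4.693], p = 1.61e-07, n = 150 (105 events)
```

The meta-DE line reports how many genes are significant (BH q < 0.01 on the
Fisher-combined p) *and* consistently up- or down-regulated in all four
studies — here the 40 planted genes and nothing else. The benchmark table
shows the mean/median correlation between the AR score computed on an
incomplete gene list and the full 20-gene score: dropping 5 of 20 genes
still leaves r ≈ 0.87. The Cox fit recovers the planted association between
the latent program and time to biochemical recurrence.

A command-line front end mirroring these steps
(`simulate`, `harmonize`, `validate`, `score`, `coverage`,
`benchmark-missingness`, `meta-de`, `mutex`, `survival`) is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pcharm.R", package = "pcharm"))')"
```

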