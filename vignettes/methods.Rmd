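---
title: "Methods: harmonized multi-study prostate cancer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized multi-study prostate cancer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcharm)
```

This vignette is the package's own account of its models and the design
choices behind them: what each component assumes, which parameters matter,
what the synthetic-data generator does and does not emulate, and the
numerical conventions used throughout.

## Study containers and the clinical data dictionary

A `study_bundle` binds up to three assays — a log2 expression matrix, a
GISTIC-style thresholded copy-number matrix with calls in −2 (deep loss) to
+2 (amplification), and a MAF-derived mutation table — to a clinical table
under one sample namespace. Clinical tables follow a fixed data dictionary
(identifiers, sample type, Gleason fields, biochemical-recurrence and
overall-survival endpoints in months). `validate_clinical()` reports every
dictionary violation as *data* rather than throwing, because curation work
needs the full list of problems at once; case-only vocabulary mismatches
get a normalization hint. Expression matrices are taken as arriving
pre-normalized; no normalization is applied here.

Gleason information arrives in different granularities across cohorts, so
`map_gleason()` resolves whatever is present to the shared grade groups
≤6 / 7 / ≥8 with the precedence *reported sum* over *primary+secondary*
over *ISUP group* (1→≤6, 2–3→7, 4–5→≥8). The precedence order prefers the
field closest to the original pathology report; all-missing input yields a
missing group rather than an error because missingness is data.

## Gene harmonization

Platforms disagree on gene symbols, so row symbols are resolved through an
alias dictionary: known aliases are renamed to their canonical symbol, rows
that then share a symbol are collapsed (mean by default — the conventional
treatment of replicate probes — with a keep-the-most-variable-row
alternative), unknown symbols are kept verbatim and logged, and an alias
that maps to more than one canonical symbol is dropped and logged unless
the dictionary marks a priority target. Dropping is deliberate: inventing a
resolution for a genuinely ambiguous symbol would silently contaminate
downstream scores, whereas the coverage report (below) makes the loss
visible. The operation is idempotent, which the suite checks directly.

## Signature scoring

A `signature_model` holds components (gene, aliases, direction ∈ {+1,−1},
weight, optional group), a per-gene normalization and a combination rule.
Coverage classification buckets each signature gene by how many matrix rows
match it or an alias: `single` (usable 1-to-1), `multiple` (1-to-many) or
`missing`. 1-to-many genes are excluded from scoring — a duplicate row
makes the intended measurement ambiguous — and scoring proceeds on
available genes provided at least `min_fraction` (default 0.5) of the
signature has a single match; the dropout benchmark quantifies what partial
coverage costs.

Normalizations: z-score uses the sample standard deviation (n−1); the
percentile rank is the fractional average rank in (0,1] with ties sharing
the mean rank; centering subtracts the gene mean. A zero-variance gene
under z-scoring contributes 0 and is logged rather than producing NaN.
Distribution-based normalizations require at least 3 samples.

The four built-in models are research transcriptions from the original
publications, shipped as versioned JSON under `inst/extdata/signatures/`:
the 20-gene AR activity list combined as the *mean* of z-scores (mean
rather than sum so the score's scale does not depend on how many genes a
platform happens to carry; at full coverage the two differ only by the
factor 1/20), the 12-gene score in four biological modules with the
published module weights, the 34-gene cell-cycle list as a centered mean,
and the 20-marker signed classifier as a signed percentile mean. The
scoring *engine* is the contract here — the constants live in data files,
are never used at commercial report scales, and the non-coding markers in
the signed classifier are expected to be missing from gene-level matrices,
which the coverage report makes visible instead of hiding.

## Gene-dropout robustness benchmark

`benchmark_missingness()` removes `k = k_min … k_max` signature genes at a
time, rescoring and correlating against the full-gene "ground truth"
score. Subsets are distinct (sampled without replacement of combinations;
fully enumerated when C(m,k) is below the requested count). Defaults
follow the published benchmark design: 100 combinations per k, 50 for the
34-gene cell-cycle score. Pearson correlation is the default because
scores are continuous; Spearman is a flag recorded in the output. Per-k
RNG streams derive from the root seed so extending the k range never
perturbs existing rows. For a signature of m i.i.d. equal-weight genes the
squared correlation at dropout k concentrates near (m−k)/m, which the
acceptance checks verify by Monte Carlo.

## Cross-study differential expression

Per study, logFC is the mean log2 expression of grade ≥8 samples minus the
≤6 mean. The moderated t shrinks each pooled per-gene variance s²_g
(d_g = n_h + n_l − 2 df) towards a prior (d₀, s₀²) estimated by
moment-matching the log-variance distribution: with
e_g = log s²_g − ψ(d_g/2) + log(d_g/2), the excess variance
var(e) − ψ′(d_g/2) equals ψ′(d₀/2), inverted by Newton iteration on the
trigamma function (tolerance 1e-8); a non-positive excess falls back to
d₀ = ∞ (all variances shrunk to the prior, normal reference). The posterior
variance (d₀s₀² + d_g s²_g)/(d₀+d_g) is a convex combination of the two, and
t̃ = logFC/(s̃√(1/n_h+1/n_l)) is referred to d₀+d_g df, two-sided. The
implementation exposes both classical limits (d₀ = 0 gives the ordinary
pooled t, d₀ = ∞ the normal test), and the suite checks it against both a
literal independent transcription of these formulas and the established
empirical-Bayes implementation in `limma`. With unequal per-gene residual
df (missing values), the prior is fitted at the modal df and each gene is
shrunk with its own df.

Study-level p-values are combined per gene with Fisher's method over the
genes common to *all* studies (requiring common genes matches the design
of a fixed cross-study gene universe; a ≥k-of-n relaxation is deliberately
not the default because it changes the null df per gene). Combination uses
two-sided p-values; direction is enforced separately by the
sign-consistency filter (selected genes must have logFC of one sign in
every study), which avoids double-counting directionality. BH adjustment
runs across genes, with q < 0.01 as the default selection threshold.

## Alteration co-occurrence and mutual exclusivity

A gene is altered in a sample iff its copy-number call is non-zero — the
definition is read literally, so shallow ±1 calls count — or it carries at
least one non-silent mutation. Samples lacking one assay stay in the
denominator and are flagged: their combined alteration frequencies are an
acknowledged undercount, reported rather than imputed. Pair tests use the
odds-ratio count formula OR = (Both·Neither)/(A-only·B-only) — the sample
OR, not the conditional-MLE OR that `fisher.test` reports — with a
two-sided Fisher exact p. A zero discordant cell yields OR = +∞/0 without
continuity correction, with a Haldane-corrected OR (+0.5 per cell)
alongside for plotting. Screens BH-adjust across all unordered pairs and
star pairs at p < 0.05 following the oncoprint-panel convention.

## Survival analysis

The top-tertile split takes the ⌈n/3⌉ largest scores (descending-score
rank, ties broken by ascending sample id) — a ceiling rule on ranks rather
than an interpolated quantile, removing quantile-definition ambiguity
between languages. Kaplan-Meier estimation, the log-rank test and the
univariate Cox fit are delegated to the `survival` package; ties use the
Efron approximation by default (Breslow by flag), convergence is tightened
to 1e-10, and Wald confidence intervals and p-values are reported with the
tie method recorded in the output. Grade groups enter ordinally
(≤6→0, 7→1, ≥8→2) so the hazard ratio is per unit increase. Monotone
likelihood (complete separation) flags the fit instead of failing. Samples
with missing time or event are dropped with a logged count. For a binary
covariate without ties the Cox score test coincides with the log-rank
statistic, which the suite uses as a cross-check between the two routes.

## The synthetic multi-study generator

`simulate_multistudy()` emulates exactly the structure the analysis
modules consume: several studies over a (partially) shared gene universe;
per-gene variances drawn from a scaled-inverse-chi-square (inverse-gamma)
prior with d₀ = 8, s₀² = 0.25 by default — deliberately the moderated-t
model's own assumption, so calibration tests are well-posed, with a
log-normal misspecified mode available for robustness checks; planted
grade-associated genes (full logFC shift in ≥8, half in 7, default
δ = 1 log2 units); a single latent "endothelial-like" factor with Gaussian
marker loadings (loading 0.8 over 20 markers) driving exponential
recurrence times with hazard ∝ exp(β·latent), β = ln 2 by default;
censoring by a uniform cutoff whose scale is solved numerically to hit the
target fraction (30%); and a copy-number/mutation block whose first gene
pair is planted at a target odds ratio through the exact joint Bernoulli
distribution (p₁₁ solved by monotone root-finding on log OR). Default
cohort sizes (4 studies × 120 samples, 1000 genes) keep every test and the
acceptance script comfortably fast while leaving group sizes realistic for
grade-stratified contrasts; individual tests state larger sizes where a
law-of-large-numbers check needs them. The gene universe begins with the
built-in signature genes — real cohorts contain them, and it keeps the
built-in scores computable on simulated data — padded with synthetic
symbols.

What the generator does *not* emulate: platform-specific probe behaviour,
microarray noise models, batch effects, correlated gene-gene structure
beyond the single latent factor, and copy-number segment structure along
the genome. Passing tests therefore demonstrate correctness of the
statistical machinery under its stated assumptions, not performance on any
real cohort; the published per-cohort numbers (e.g. specific inter-study
correlations or hazard-ratio ranges) depend on external datasets and are
out of scope here.

## Numerical conventions and degenerate inputs

Missing tokens in TSV matrices are a literal `NA` or empty cell,
case-sensitively. Symbols match case-sensitively; the validator hints at
case-only mismatches. Correlations need ≥3 observations; constant vectors
yield missing correlations, logged. Fisher's method requires p ∈ (0,1];
p = 0 is a domain error rather than silently mapped to +∞. All stochastic
functions take explicit seeds, and child seeds are derived arithmetically
from the root so results are bit-reproducible across runs and platforms.
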