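---
title: "Differential co-expression network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicoexnet)
```

## The problem

In a two-phenotype transcriptome comparison (tumour versus matched normal
tissue, say), most single-gene analyses ask whether a gene's *mean*
expression shifts between phenotypes. Differential **co-expression**
analysis asks a complementary question: which *pairs* of genes change how
strongly they move together. A pair can keep identical means in both
phenotypes and still flip from tightly correlated to independent — a
signature of rewired regulation that mean-based statistics cannot see.
`dicoexnet` implements this analysis as a reusable pipeline for two or more
cohorts, each a genes × samples matrix with `disease`/`control` labels,
plus the downstream stages that make the result actionable: prognostic
evaluation of the detected module, drug-signature reversal ranking, and a
literature-novelty score for the ranked drugs.

## Stage 1: per-cohort differential expression and meta-intersection

Each cohort is analysed independently: a two-sample Welch t-test per gene
(a pooled-variance mode is available via `var_equal = TRUE`),
Benjamini–Hochberg adjustment across genes, and a gene is called
differentially expressed when its adjusted p-value is below `alpha`
(default 0.05) and its absolute log2 fold change is at least
`log2(fc_threshold)` (default fold change 2, i.e. |log2FC| ≥ 1). Input
matrices are assumed log2-scale, so the fold change is a difference of
phenotype means; the linear two-fold reading and the |log2FC| ≥ 1 reading
coincide under this convention, which is why the package fixes it. Genes
with a fold change of exactly zero have no up/down direction and are
excluded.

The meta-analysis step is deliberately simple and conservative: only genes
called in **every** cohort (`intersect_common_degs()`) go forward.
Direction consistency across cohorts is reported (as an attribute) but not
enforced, since a direction flip between cohorts is itself information the
analyst may want to inspect. Over-representation of the common genes
against a GMT collection uses the one-sided hypergeometric tail with BH
adjustment across sets; the universe defaults to the genes present in the
expression data, since an unstated larger universe would only make every
set look more enriched.

## Stage 2: condition-specific correlation and the two thresholds

Before correlating, each cohort is z-scored per gene across its own
samples (sample standard deviation, n−1). Z-scoring within study rather
than across the pooled data is what removes cohort-level location/scale
(batch) differences; pooling first would leave them in and manufacture
spurious correlation. Duplicate gene symbols are collapsed to their
element-wise mean *before* z-scoring, because duplication is a property of
the raw expression rows. The z-scored samples of all cohorts are then
concatenated per condition, and Spearman's rank correlation (average ranks
at ties) is computed once per unordered gene pair per condition over the
restricted common-gene set, giving SCCd (disease) and SCCh (control).

Two thresholds turn the two correlation matrices into a network:

1. **The critical cutoff.** Rather than a fixed correlation threshold, the
   cutoff adapts to the empirical distribution of the coefficients:

   `pcritic = mean(SCC) + 1.96 · sd(SCC)`

   computed over all off-diagonal values of one condition (each pair
   counted once, sample sd). A pair is *significant* in that condition
   when |SCC| exceeds the cutoff. The signed coefficients feed the formula
   by default; `use_abs = TRUE` switches to absolute values for analysts
   who prefer a magnitude-based reference distribution. Applying the
   single-valued cutoff to |SCC| covers both correlation tails without
   privileging a sign.

2. **The differential criterion.** A significant disease pair is
   *differentially co-expressed* when its correlation changes enough
   between conditions: |SCCd − SCCh| > ε with ε = 0.5 by default. The
   absolute value is used so that a gain of positive correlation and a
   gain of negative correlation are treated symmetrically.

Both thresholds are computed on the pooled correlations (one SCCd and one
SCCh per pair), not per cohort: after within-study z-scoring there is one
correlation structure per condition to estimate, and pooling maximises the
sample size behind each coefficient. A t-approximation p-value for a
Spearman coefficient (`scc_pvalue()`) is provided as an optional
pre-filter but is off by default, because the adaptive cutoff supersedes a
fixed-α filter.

## Stage 3: network, modules, density and patterns

Retained pairs form a simple undirected graph with `scc_d`, `scc_h` and
`epsilon` edge attributes (exported as GraphML and SIF). Module detection
works per connected component: a component whose density
`2E/(N(N−1))` already meets the density bar is taken whole — a dense
quasi-clique is exactly the object the analysis looks for, and
partitioning it further would fragment it (greedy modularity maximisation
provably splits near-cliques: on simulated data the planted 20-gene module
was split 12 + 8 by a pure partition). Only components below the bar are
partitioned by deterministic greedy modularity maximisation
(`igraph::cluster_fast_greedy`), and each resulting community is filtered
by the same criteria: at least `min_size` nodes (default 5) and density at
least `density_threshold` (default 0.5). Node order is fixed by sorting,
so detection is deterministic.

For a detected module, `correlation_pattern_summary()` counts pairs with
SCC above `+pcritic` (positive pattern) and below `−pcritic` (negative
pattern) per condition. Percentages are reported against *two*
denominators — the per-condition significant-pair count and the module's
total pair count — because summary percentages of this kind are ambiguous
unless the denominator is stated; both are labelled in the output.

A note on "density": the standard simple-graph formula is implemented. A
21-node, 45-edge module has density 45/210 ≈ 21.4% under this formula;
any report of a much larger percentage for such a module must be using a
different, undefined metric, and this package does not attempt to guess
it.

## Stage 4: prognostic evaluation

The module is summarised per patient as the mean z-scored expression of
its available genes (`module_score()`); the mean-of-z is the simplest
scale-free summary and keeps every module gene's weight equal. Patients
are split at the median score (ties to the low group), per-group
Kaplan–Meier curves are estimated (`survival::survfit` product-limit;
events precede censorings at tied times), and the groups are compared by
the log-rank test (`survival::survdiff`). The module is flagged
*prognostic* when the log-rank p-value is below `alpha` (default 0.05).

Because disease stage is the dominant clinical prognostic factor, the
stage-aware run (`stratify_by_stage = TRUE`) adds two complementary
analyses on the samples with known stage: a log-rank across stage groups,
and a stage-stratified log-rank of the score split (observed-minus-
expected pooled within stage). Both are reported, and neither is asserted
as "the" analysis, because how stage should be combined with a module
score is a genuine analysis choice. Samples of unknown stage are excluded
from the stage-involving analyses only. When the score split is constant
within every stage (as happens when stage is itself a deterministic
function of the score, e.g. in simulation), the stratified test is
degenerate and is reported as absent rather than as a spurious number.

## Stage 5: drug reversal and literature novelty

The module signature partitions module genes into up/down sets with log2
fold changes as weights. Against a user-supplied library of per-drug
signed gene weights, each drug sharing at least one gene with the
signature receives the score

`score(drug) = − cos(w_signature, w_drug)` on the gene intersection,

so a drug whose effect is the exact opposite of the disease signature
scores +1 and ranks first; the top `top_k` (default 50) are returned.
Cosine reversal is used because it preserves the "inverse effect"
semantics while being independent of the two vectors' scales; signature
genes without weights fall back to +1/−1.

Literature novelty uses a fixed TF-IDF variant: for each of four query
templates — the drug name alone, and the name in documents mentioning
"thyroid cancer", "thyroid carcinoma" or "cancer" — the sub-corpus is the
set of abstracts matching the template context; `tf` is the total count of
case-insensitive whole-phrase occurrences of the drug name in the
sub-corpus, `idf = ln(N/df)` with `N` the sub-corpus size and `df` the
number of sub-corpus documents containing the name, and `tfidf = tf · idf`
with the convention that `df = 0` gives 0. A drug is *novel* when its
score is 0 under **all four** templates — the strictest combination rule,
chosen because requiring all queries to be silent is the only reading
under which "never studied in this context" is safe. Drug names are
matched as exact phrases without stemming; they are proper nouns.

## The synthetic-data generator

`simulate_multistudy_expression()` emulates the structure of a multi-GEO-
cohort design so every stage is testable without downloads. Per cohort,
background genes draw i.i.d. Normal(μ_g, σ) in both phenotypes; planted
DEGs get a ±`deg_log2fc` shift in disease; module genes additionally load
on a per-sample latent factor with loading λ_d in disease and λ_h in
control, scaled so each gene's marginal variance stays σ². Pairwise
correlation between module genes is then ≈ λ² per condition, which is the
direct control knob for the SCCd/SCCh separation the ε criterion targets.

Defaults are the study conditions used throughout the tests: 5 cohorts ×
30+30 samples (300 pooled), 500 genes, 50 planted DEGs at log2FC 1.5
(≈2.8-fold, comfortably past the two-fold threshold at these sample
sizes), a 20-gene module with λ_d = 0.8 and λ_h = 0 (disease correlation
≈ 0.64 Pearson, ≈ 0.62 Spearman; control ≈ 0), noise sd 0.5, and 2% of
genes per cohort shifted as study-specific noise DEGs so the intersection
step has something to remove. Survival times are exponential with hazard
`baseline · exp(β · score)` (β = 1, baseline 0.01/month by default);
censoring times are independent Uniform(0, τ) with τ solved numerically so
the expected censored fraction under the mixture of the samples' hazards
equals `censoring_rate` (default 0.3); stage I–IV is assigned by score
quartile to mimic stage-linked prognosis. The corpus/library generator
plants one exact reverser drug (weights = minus the signature), random
decoys, and a known/novel split of drug mentions.

What the generator does **not** emulate: probe-level microarray noise,
RMA artefacts, annotation ambiguity, correlated background structure
(housekeeping co-expression), non-exponential hazards, or informative
censoring. Passing tests on this generator therefore demonstrate that the
pipeline recovers the structures it is designed to find under its own
model assumptions — not that those assumptions hold in any particular
real dataset.

## Numerical and design choices

- Sample (n−1) standard deviation everywhere (z-scoring, the critical
  cutoff) for a single consistent convention.
- Spearman ties: average ranks, the standard reproducible definition.
- Gene symbols are matched case-sensitively after whitespace trimming;
  silent case-folding would create accidental joins.
- BH adjustment via `stats::p.adjust`; hypergeometric tails via
  `stats::phyper`; Kaplan–Meier and log-rank via the `survival` package;
  the test suite cross-checks each against independent brute-force
  oracles (step-up enumeration, tail enumeration with binomial
  coefficients, hand product-limit, O−E/V loops).
- Degenerate inputs are errors, not guesses: fewer than 3 samples per
  phenotype in a cohort, constant gene rows at z-scoring (dropped with a
  warning), all-equal module scores at the median split, empty drug
  overlap at reversal scoring.
- Determinism: every stochastic component is driven by an explicit seed;
  the pipeline manifest records inputs, thresholds and seed so a re-run
  is byte-identical.

Problem sizes in the shipped tests (3–5 cohorts, 60–500 genes, ≤ 300
pooled samples, 1000-seed log-rank calibration) were chosen as the
smallest at which the statistical properties under test are stable.

## Known limitations

- The meta-analysis is a hard intersection; a gene missed in one cohort
  for power reasons is lost. A vote-counting or p-combination mode would
  be a natural extension.
- The critical cutoff assumes the correlation distribution is roughly
  unimodal; a corpus of pairs dominated by one huge module shifts the
  cutoff upward and can mask smaller modules.
- Module detection below the density bar inherits the resolution limit of
  greedy modularity.
- The reversal score treats the drug library as given; it does not model
  dose, cell line or signature reliability.
- TF-IDF novelty is only as good as the corpus: a drug absent from a
  small corpus is "novel" relative to that corpus, nothing more.
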