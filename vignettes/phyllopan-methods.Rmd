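---
title: "Methods: comparative pangenomics of phyllosphere yeast collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative pangenomics of phyllosphere yeast collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllopan)
```

# The analysis

phyllopan implements the comparative stage of a yeast pangenome study: given
an orthogroup gene-count matrix for a panel of isolates from several genera
and isolation sources (leaf, flower, soil, human, water), it asks which parts
of the gene repertoire are shared, which are tied to an isolation source, and
whether the source signal generalizes across taxa. The inputs are the
standard text outputs of an orthology/annotation pipeline: an OrthoFinder
style `Orthogroups.GeneCount.tsv`, an eggNOG-mapper style `.annotations`
table (COG category letters, `KEGG_ko` sets), and a plain isolate metadata
TSV. Internally the count matrix is oriented isolates x orthogroups, because
every statistic in the pipeline groups by isolate.

# Soft core and strict source-combination partition

An orthogroup is in the **soft core** when its occupancy — the fraction of
isolates in which it has at least one gene — is at least $\tau$ (default
0.95, inclusive). Occupancy can alternatively be counted over distinct group
labels (`soft_core(..., groups = )`), since "present in 95% of the species"
and "present in 95% of the isolates" are both defensible units for a panel
with very uneven genus sizes; the isolate unit is the default because it does
not depend on how genera were delimited.

`partition_by_group()` removes the soft core first and then assigns each
remaining orthogroup to the combination $C$ of groups in which it occurs:
present in at least one isolate of every group in $C$ and absent from all
isolates of every other group. On top of the presence pattern a **strict
fraction** is enforced: the orthogroup must be present in at least
`strict_fraction` (default 0.95) of the isolates of every group in $C$,
otherwise it is *unclassified*. Without this second requirement almost every
orthogroup matches some combination and the unclassified set is nearly empty;
with it, orthogroups that are merely sporadic within a group drop out, which
is what makes "unique to source X" a strong statement. `strict_fraction = 0`
recovers the plain any-presence rule. The three result parts (core,
combination sets, unclassified) are checked to be disjoint and exhaustive on
every run.

# Functional-category enrichment against the soft core

For any orthogroup set, `enrich_vs_core()` counts genes per COG letter — a
gene carrying $k$ letters contributes to all $k$, genes without annotation
count only toward the total — and forms, per category, the 2x2 table

|            | in category | not in category |
|------------|-------------|-----------------|
| target set | $a$         | $b$             |
| soft core  | $c$         | $d$             |

tested with the package's exact Fisher test and BH-adjusted across the
categories of the set. Two effect scales are emitted: the percent deviation
from the core expectation $D = 100\,(p_{obs}/p_{core} - 1)$ and the
representation $R = D + 100$, because published heatmaps alternate between
the two conventions ("215%" is $R$; "> 50% overrepresented" is $D$). A
category is called *over* when $D > 50$ with adjusted $p < 0.05$, *under*
for the mirror image. Categories carried by fewer than `min_gene_support`
(default 200) genes across the comparison are marked `low-support` rather
than dropped, so downstream filtering stays a reporting decision. The
log-odds ratio uses the plain sample estimator $ad/bc$; when a zero cell
occurs the Haldane–Anscombe 0.5 correction is applied for the LOR only and
the row is flagged. BH is applied within each target set by default; a
global scope across sets is available in `enrich_sets()` — the choice
matters only when many sets are scanned at once, and per-set matches how the
per-genus comparisons are usually read.

# Statistical kernels

The kernels are implemented in the package and cross-checked in the test
suite against brute-force enumeration (and against the base R equivalents,
which are never used as the implementation):

* `fisher_exact()` enumerates the hypergeometric support of the $a$ cell
  given the margins, via log-binomial coefficients. The two-sided p-value is
  the sum of probabilities of all tables at most as probable as the observed
  one, with a relative tolerance of `1e-7` for floating-point ties — the
  convention of the mainstream implementations.
* `bh_adjust()` is the step-up FDR adjustment
  $\tilde p_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)$; `bonferroni_adjust()`
  is $\min(1, p\,m)$.
* `mann_whitney_u()` uses $U = \#\{x_i > y_j\} + \tfrac12\#\text{ties}$. In
  exact mode the permutation distribution of $U$ over all relabellings of
  the observed (possibly tied) pooled values is computed by a dynamic
  program over (subset size, doubled-midrank sum) — numerically identical to
  enumerating all $\binom{n_1+n_2}{n_1}$ labelings but cheap enough for
  thousands of orthogroups. The two-sided tail is
  $P(|U - n_1 n_2/2| \ge |U_{obs} - n_1 n_2/2|)$, well defined because the
  permutation distribution is symmetric under value negation. The normal
  mode applies the tie-corrected variance and a 0.5 continuity correction;
  its type-I error at $\alpha = 0.05$ is verified to sit in $[0.03, 0.07]$
  over 10,000 null simulations. `mode = "auto"` switches to the exact tail
  at $n_1 + n_2 \le 12$; `differential_orthogroups()` requests the exact
  tail explicitly up to 30 pooled isolates, where the DP is still essentially
  free and the normal approximation is at its weakest.
* `roc_auc()` is the normalized $U$ (ties one half), with ROC points swept
  over distinct score values; the identity $\mathrm{AUC} = U/(n_1 n_2)$ is
  asserted between the two functions.

# Per-genus differential orthogroups

`differential_orthogroups()` compares raw per-isolate gene counts (not
presence) of each orthogroup between target-source isolates and all others
of one genus, because copy-number differences are part of the signal.
Orthogroups with no gene anywhere in the genus are excluded before the BH
correction — they carry no information and would only dilute the FDR budget;
`test_all = TRUE` restores them. Direction is read from the group means.
`compare_group_metric()` runs all pairwise rank tests on a per-isolate
metric (genome size, glycoside-hydrolase count, ...) with Bonferroni
correction over the pairs and summarizes them as a compact letter display
built by insert-and-absorb; the display is re-checked after construction so
that two groups sharing a letter are never significantly different. Ties in
letter assignment follow the group order of the input.

# Pathway completeness

`parse_pathway_definition()` implements the KEGG-module definition grammar:
space-separated units are required steps (AND, lowest precedence), commas
separate alternatives (OR), `+` joins complex subunits (AND, tightest),
parentheses group, and a leading `-` marks the unit optional. Optional units
are pruned before scoring. Completeness is scored recursively: a KO leaf is
1 if present, AND averages its children, OR takes the maximum — so a
definition with four required steps and two of them satisfied scores 50%.
This mean/max semantics is a deliberate simplification of the external
graph-weighted completeness tool: it preserves the ordering of "more
complete in source X" comparisons that the downstream tests consume, which
is all the pipeline relies on; absolute completeness values are therefore
not comparable with that tool's output. `+` complexes are scored as AND (all
subunits required). Per-isolate KO sets are unions over the isolate's genes
— completeness depends on presence, not copy number. An all-optional
definition has no defined score and propagates `NA`.

# Community rules

The amplicon-side rules are deliberately small: per-sample relative
abundance; exclusion of taxa whose *mean* relative abundance stays below
0.1% in every year (per-sample normalization first, mean second — the usual
amplicon convention); a per-year core defined by presence (any nonzero
count) in at least 80% of that year's samples, inclusive; and a recovery
estimate, the percentage of abundance-filtered amplicon-detected genera that
appear in the culture collection. All thresholds sit in
`community_config()`.

# Classification harness

`make_labels()` binarizes isolation source (target source = 1).
`repeated_stratified_cv()` deals each class round-robin into folds, so fold
class counts deviate from proportionality by at most one item, and
aggregates accuracy over all `n_splits * n_repeats` evaluations; the
reported SD is taken across those folds (published "0.84 ± 0.07" style
values do not state their SD unit; this choice is documented rather than
guessed at). `logo_cv()` holds out each genus in turn — train and test sets
are asserted disjoint, and the test set is exactly one genus — reporting
per-genus accuracy and AUC (AUC is `NA` when the held-out genus is
single-class). Learners are pluggable behind a fit/predict-score contract;
the bundled backends are a 100-tree random forest (randomForest) and a
linear-kernel SVM (e1071), since the contribution here is the evaluation
design, not the learners. Feature attribution uses model-agnostic
permutation importance (mean accuracy drop over `n_perm` within-column
shuffles, ties broken by feature id) instead of SHAP: it is reproducible
from base infrastructure and directly testable against planted signal.
Features are raw orthogroup counts by default, with binary and `log1p`
transforms available.

# The synthetic generator

`simulate_study()` emulates the structure of a multi-genus isolate panel:

* a shared soft core (default 1,200 orthogroups) present in every isolate;
* genus backbones (default 600 per genus) present only within their genus —
  taxonomy deliberately dominates the variance structure, as it does in real
  panels, which is what makes the genus-confounded classifier fixture
  realistic;
* shared accessory orthogroups present in a random half of isolates;
* planted source-associated orthogroups whose target-source isolates carry
  an **additive shift** of `planted_effect` (default 5) extra gene copies on
  top of the baseline count model;
* source-unique orthogroups present only in target-source isolates, whose
  genes carry one COG category (default `Q`) at three times its baseline
  frequency, and which host the KOs of a designated pathway so that it is
  complete only in target-source isolates.

Present cells draw `1 + Poisson(mu - 1)` gene counts (mean `baseline_mu`,
default 2; presence implies at least one gene); a global dropout probability
(default 0.02, a realistic annotation/assembly miss rate) zeroes present
cells at random. Poisson-with-dropout was chosen over a negative binomial as
the simplest model consistent with joint presence/absence and copy-number
analyses. The default panel is four genera x 15 isolates (4 leaf / 3 flower
/ 3 soil / 3 human / 2 water), about 60 isolates and 4,000 orthogroups,
generated in about a second. Everything is a deterministic function of the
seed, and the emitted files are byte-stable given the seed.

What the generator does **not** emulate: phylogenetic correlation within a
genus (isolates are exchangeable draws), overdispersed counts, annotation
errors correlated with genome quality, and orthogroup-size heterogeneity.
Recovery tests on this generator therefore demonstrate that the statistics
find what they claim to find under their own assumptions — not that those
assumptions hold for any particular real panel.

The recovery experiments run at deliberately desk-sized problems: the
differential experiment uses one genus with 8 target and 8 other isolates
and 50 planted among 2,000 orthogroups over 20 seeds; the enrichment
experiment uses 50 replicates of a ~60-isolate panel with the planted COG
category in 50 source-unique orthogroups; the classification fixtures use
64 isolates in 4 genera. One property of the differential experiment is
worth stating plainly: at 8-vs-8 the smallest attainable exact two-sided
p-value is $2/\binom{16}{8} \approx 1.6\times10^{-4}$, while the largest BH
cutoff with at most 50 true discoveries among 2,000 tests is
$0.05 \cdot 50/2000 = 1.25\times10^{-3}$. A single inverted isolate pair —
for instance a dropout-zeroed target cell — already pushes the exact
p-value past that cutoff, so under the default dropout of 0.02 the measured
sensitivity settles around 0.86 rather than above 0.9; the false discovery
rate stays near 0.01. The dropout default was fixed as a study condition and
is not tuned around this behaviour.

# Numerical choices

* Reported percentages are rounded half-up to one decimal
  (`round_half_up()`); all internal computation is at full precision.
* Inclusive `>=` at every threshold (occupancy, prevalence, abundance,
  strict fraction).
* Fisher two-sided tie tolerance `1e-7` (relative), exact-MWU tail tolerance
  `1e-9` (absolute on the deviation), both matching enumeration oracles to
  `1e-10` in the tests.
* Identifiers are opaque, case-sensitive strings; no normalization anywhere.
* Degenerate inputs fail loudly and early: zero-total samples, duplicated
  ids, `Total` column mismatches (named by row), unknown source labels,
  unbalanced parentheses (with position), one-sided group memberships.

# Limitations

The partition's strict-fraction reading of "unique" is one of several
defensible conventions; it is exposed as a parameter rather than hidden.
Pathway completeness values are ordinal, not calibrated percentages of
biochemical capability. The classification harness measures predictability,
not mechanism — a high reference accuracy with a LOGO collapse is evidence
of confounding, and the package's confounded fixture reproduces exactly that
signature. Community rules operate on genus-level tables and deliberately
exclude ASV inference, taxonomy assignment and differential-abundance
modelling, which belong to the upstream tools that produce the inputs.
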