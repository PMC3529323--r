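---
title: "Methods: comparing transcriptional responses to mitochondrial and chloroplast perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing transcriptional responses to mitochondrial and chloroplast perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrosig)
```

This vignette documents the statistical model behind `retrosig`, the
parameters that matter, and the design choices made where the methodology
was genuinely open. The setting is a meta-analysis of expression
compendia: a set of perturbation experiments, each a replicated
treatment-versus-control contrast targeting either mitochondrial or
chloroplast function, analysed per experiment and then integrated by
recurrence across experiments.

## Per-experiment differential calling

### Presence filter and the fold-change-1 rule

Detection ("present/absent") calls are taken as input, one flag per gene
and chip. A gene is retained in an experiment when some condition group of
that experiment has at least `ceiling(min_fraction * group_size)` present
calls (`min_fraction = 0.5`): the gene must *not* be called absent on at
least half the chips of one group. The ceiling reading implements "at
least half" faithfully for odd group sizes (2 of 3 chips pass, 1 does
not). Filtering is applied per experiment, because compendium studies are
normalised dataset by dataset; a gene may legitimately pass in one
experiment and fail in another. Genes failing the filter are assigned a
fold change of exactly 1 (log2 fold change 0) in that experiment — they
contribute "no change" rather than missing values to every downstream
stage, which keeps the feature space complete for clustering and makes
recurrence counts conservative.

Fold changes are ratios of geometric means: `2^(mean treatment log2 −
mean control log2)`. On log-normalised intensities this is the standard
choice; an arithmetic-mean variant is available (`mean_fun =
"arithmetic"`) because the averaging convention is not fixed by the
problem, and the two differ when replicate variance is large.

### Regularized t statistic

With 2–3 replicates per group, per-gene variance estimates are unstable.
Each group's variance is therefore shrunk toward a local background: genes
are ranked by group mean intensity, the background variance is the mean
replicate variance over the `window` (default 101) genes nearest in rank
(clamped at the extremes so the window always spans 101 genes), and

$$\tilde\sigma^2_g \;=\; \frac{\nu\,\sigma^2_{bg} + (n-1)\,s^2_g}{\nu + n - 1},$$

with `prior_df` $\nu = 10$ pseudo-replicates by default. The intensity-
ranked window captures the strong mean–variance dependence of array data;
101 genes and 10 prior degrees of freedom are the conventional defaults of
Bayesian-regularized t analysis and are exposed as arguments. The test
statistic pools the two regularized group variances with weights
$n_i + \nu - 1$ and uses $n_1 + n_2 - 2 + 2\nu$ degrees of freedom, so
with $\nu = 0$ and raw variances it reduces exactly to the ordinary
pooled-variance two-sample t (a property the test suite checks to 1e-10
against `t.test`). If the pooled standard error vanishes while the means
differ (possible only with $\nu = 0$ and degenerate replicates), the
p-value is set to the smallest representable positive number and the gene
flagged via the `zero_se` column rather than silently producing NaN.

### PPDE via a beta-uniform mixture

Each experiment's p-values are modelled as
$f(p) = \pi_0 + (1-\pi_0)\,a\,p^{a-1}$ with $0 < a < 1$: a uniform null
component of weight $\pi_0$ plus a beta alternative spiked at zero. The
fit maximises the likelihood directly (BFGS on logit-transformed
parameters, relative tolerance 1e-8) from a small grid of starting values
($a \in \{0.1, 0.3, 0.5\}$, $\pi_0 \in \{0.5, 0.9\}$), which avoids the
stalling behaviour of EM on flat likelihoods and is deterministic.
P-values of exactly zero (possible after underflow) are clamped to the
smallest positive double. The reported posterior is the *cumulative*
PPDE,

$$\mathrm{PPDE}(p) = P(\mathrm{DE} \mid P \le p) = 1 - \frac{\pi_0\,p}{F(p)},
\qquad F(p) = \pi_0 p + (1-\pi_0)p^a,$$

which is monotone non-increasing in $p$ and equals $1-\pi_0$ at $p = 1$.
The cumulative form matches the "PPDE (≤ p)" convention of the
regularized-t framework; the density-based local posterior is not used.

### Significance rule

A gene-experiment pair is significant when the fold change is strictly
more than twofold in either direction *and* PPDE strictly exceeds 0.95. A
fold change of exactly 2.0, or a PPDE of exactly 0.95, fails. Both
thresholds are arguments throughout (`fc_threshold`, `ppde_threshold`).

## Recurrence, responsive sets and markers

The response matrix holds ternary calls (up/down/ns). Recurrence counts
tally, per gene and experiment class, the experiments with a significant
call *irrespective of direction* — the defining property is "responds to
perturbations of this class", and in practice planted-truth simulations
show the direction is almost always consistent anyway. A
`consistent_direction` mode restricts counting to the majority sign for
sensitivity analyses.

Responsive sets are genes significant in at least `min_experiments`
(4 by default, 6 for the stricter marker analyses) experiments of a
class. Marker classification uses four thresholds
(`marker_thresholds()`): *common* markers recur ≥ 6 times in **both**
classes; *mito-specific* markers recur ≥ 7 times under mitochondrial
perturbation and ≤ 1 time under chloroplast perturbation;
*chloro-specific* symmetrically with ≥ 6 (the classes have different
experiment counts, 14 vs 13, hence the asymmetric defaults). Requiring
`specific_max_other < common_min` makes the three label sets provably
disjoint; the classifier additionally gives *common* precedence. The
common-marker cut is ≥ 6 (not > 6): marker tables in this literature list
6/6 genes as common markers, so the inclusive reading is adopted.

## Overlap and category enrichment

For a foreground set $A$ and category $B$ in universe $N$, the expected
chance overlap is $|A||B|/N$ and the effect size the observed/expected
ratio, computed on the **unrounded** expectation (tables round for
display: an observed 177 against expected 58.39 prints as 58 but yields
ratio 3.03, not 3.05). Tail probabilities come from the hypergeometric
distribution — `P(X ≥ obs)` for over-representation, `P(X ≤ obs)` for
under-representation — equivalent to one-sided Fisher tests. The analytic
null is cross-checked two ways in the test suite: exhaustive enumeration
of all draws for every universe of size ≤ 12, and a seeded permutation
null (`permutation_null()`, add-one smoothing) required to agree within
three Monte-Carlo standard errors at 10,000 permutations.

`category_scan()` applies the same arithmetic over a category map and
retains categories with either tail below `p_threshold` (0.05) and a
ratio at least `min_ratio`-fold (2) away from 1 in either direction,
mirroring standard functional-category over-representation reports. The
universe defaults to the annotated gene set; compendium studies sometimes
imply slightly different backgrounds per class, so the universe is always
an explicit argument.

## Clustering experiments

Experiments are clustered on log2 fold-change profiles over the pooled
responsive gene set. Fold changes rather than intensities are used
because experiments span tissues and labs, and the absent-filtered
entries are already 0 under the fold-change-1 rule, so all experiments
share a complete feature space. Distance is `1 − Pearson r`; linkage is
average (UPGMA), the default of the clustering viewers used for such
figures. `stats::hclust` provides the merge algorithm (deterministic for
a given input), and `to_newick()` serialises trees ultrametrically with
each child edge spanning half the parent–child height difference, so the
leaf-to-leaf path length equals the merge height; labels with characters
outside `[A-Za-z0-9_.-]` are single-quoted.

## Promoter motifs

`scan_motif()` counts distinct forward-coordinate start positions where
the IUPAC consensus or (by default) its reverse complement matches;
overlapping occurrences count, a position matching on both strands
(palindromes such as CACGTG) counts once, and `N` in the sequence matches
no motif letter, so masked bases never inflate counts. Matching is
delegated to `Biostrings::matchPattern(fixed = "subject")`. The shipped
`motif_library()` (W-box TTGACY, T-box ACTTTG, G-box/ABRE CACGTG, ABRE
ACGTGKC, Evening Element AAAATATCT, I-box GATAAG, GCC-box GCCGCC, MYB
core WAACCA) is an editable input: consensus definitions for several of
these elements vary between resources, so the library is data, not ground
truth. Enrichment offers two modes: `promoter_presence` (hypergeometric
on promoters containing ≥ 1 occurrence, pooled foreground + background as
universe) and `occurrence_rate` (one-sided binomial on total foreground
occurrences against the background per-base rate, with a 0.5
pseudo-occurrence keeping the background rate positive).

## The synthetic-data generator

`simulate_compendium()` emulates the statistical structure of a
perturbation compendium: per-gene baseline log2 intensities
(Normal(8, 2)), a shared responsive block, mitochondria- and
chloroplast-specific blocks and non-responsive background; planted signed
effects of magnitude `effect_size_log2` appearing in any experiment of
the gene's class with probability `respond_prob`; i.i.d. Normal replicate
noise; i.i.d. per-chip absent calls; and planted compartment annotations
in which a fraction `frac_compartment_biased` (0.8) of class-specific
genes is annotated to the matching organelle while all other genes follow
genome-wide base rates taken from the reference annotation sizes
(2198/1178/287/1661 of 22810). Effect signs are fixed per gene across
experiments by default — marker genes respond consistently — with a
per-experiment random-sign option for robustness checks. An `n_other`
group of "mixed" experiments perturbing only the shared block emulates
generic stress conditions and gives clustering benchmarks a third planted
group. A `n_forced_absent` mode forces whole-experiment absence to
exercise the fold-change-1 rule.

Defaults are the benchmark study conditions used throughout the tests: 14
mitochondrial + 13 chloroplast experiments, 3 replicates per condition,
|log2 FC| = 2, replicate noise 0.25, response probability 0.7, absent
probability 0.05, and 6% of genes per responsive block. Fractions were
chosen once as a realistic regime (responsive blocks a few percent of the
transcriptome, comfortably above the recurrence thresholds' detection
floor); they are parameters, not estimates.

What the generator does **not** emulate: probe-level effects and
normalisation artefacts, gene–gene correlation within pathways,
expression-dependent absent calls (real absence concentrates in
low-intensity genes), batch and tissue effects, and heavy-tailed noise.
Passing recovery tests therefore demonstrates that the statistics are
implemented correctly and behave as designed under the stated model — not
that real compendia meet these assumptions.

## Problem sizes and runtime choices

The test suite runs the full stack on a 2000-gene, 32-experiment
(14 + 13 + 5 mixed), 3-replicate compendium — large enough that the
recurrence thresholds, the mixture fit (2000 p-values per experiment) and
the clustering benchmark operate in their intended regime, and small
enough that the whole suite completes in about a minute. Null
calibration uses 1500 genes at noise 0.5; mixture parameter recovery uses
5000 p-values. These sizes are the package's benchmarking choices and are
trivially scaled up through `synthetic_config()`.

## Known limitations

* PPDE is fitted per experiment; very small gene universes (< 50
  p-values) destabilise the mixture and trigger a warning.
* The regularized-t implementation follows the published formulas, not
  any specific web implementation bit-for-bit; window edge handling
  (clamped full-width windows) is one of several defensible conventions.
* `occurrence_rate` motif enrichment treats positions as independent
  trials, ignoring overlap dependence; for the short, rare motifs it is
  meant for this is a second-order effect.
* Probe-set-to-gene deduplication is out of scope; all counts are at the
  probe-set/gene-id level of the input tables.
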