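# retrosig

Meta-analysis of nuclear transcriptional responses to mitochondrial and
chloroplast perturbations.

Chloroplasts and mitochondria signal their functional state back to the
nucleus (retrograde signaling), and a recurring question is how much of the
transcriptional response to a mitochondrial perturbation overlaps with the
response to a chloroplast perturbation — and whether the cell can tell the
two apart. `retrosig` packages the statistical machinery for answering this
across a compendium of expression experiments (chemical inhibitors and
mutants, each contrasted against its own control):

* **Per-experiment differential calling.** Genes failing the Affymetrix-style
  presence filter (present on at least half the chips of some condition
  group) are assigned fold change 1. For the rest, a Bayesian-regularized
  t statistic is computed with gene variances shrunk toward a local
  background,

  σ̃²ᵍ = (ν·σ²_bg + (n−1)·s²ᵍ) / (ν + n − 1),

  where σ²_bg is the mean replicate variance over a window of genes of
  similar mean intensity and ν the prior degrees of freedom. P-values from
  the pooled-variance t (df = n₁+n₂−2+2ν) are converted to a posterior
  probability of differential expression (PPDE) by fitting a beta-uniform
  mixture f(p) = π₀ + (1−π₀)·a·p^(a−1) and taking the cumulative posterior
  P(DE | P ≤ p). A gene is called significant when its fold change exceeds
  2 in either direction and PPDE > 0.95 (both strict).
* **Recurrence meta-analysis.** Calls are tallied per gene across the
  experiments of each perturbation class; "responsive sets" are genes
  significant in ≥ k experiments of a class, and marker genes are
  classified as *common* (recurrent in both classes), *mito-* or
  *chloro-specific* (recurrent in one class, at most once in the other).
* **Overlap and compartment enrichment.** Observed overlaps are compared
  with the independence expectation |A||B|/N (obs/exp ratio) and tested
  with hypergeometric tails; a permutation null is included as a
  Monte-Carlo cross-check, and `category_scan()` applies the same
  arithmetic across arbitrary category maps.
* **Experiment clustering.** Experiments are clustered on log2 fold-change
  profiles of the pooled responsive set with Pearson-correlation distance
  and average linkage (UPGMA), exportable as Newick.
* **Promoter motif scanning.** IUPAC consensus motifs (W-box, G-box/ABRE,
  I-box, GCC-box, Evening Element, ...) are counted in promoter sets on
  both strands with palindrome de-duplication, and tested for
  over-representation by promoter presence (hypergeometric) or occurrence
  rate (binomial).
* **Synthetic compendia with planted truth.** `simulate_compendium()`
  generates replicated log2 intensities with shared, organelle-specific
  and background gene blocks, per-chip absent calls and planted
  compartment annotations, so every stage can be validated against known
  ground truth; `simulate_promoters()` does the same for motif scanning.

Everything is tibble-in / tibble-out and composes with the pipe;
`run_pipeline()` orchestrates the stages over a directory of TSV/FASTA/
Newick/JSON artifacts with a checksummed manifest.

## Worked example

Simulate a compendium under the default study conditions (14 mitochondrial
and 13 chloroplast perturbation experiments, 3 replicates, planted |log2
fold change| 2, replicate noise 0.25, response probability 0.7) and run the
meta-analysis:

```r
library(retrosig)

cfg  <- synthetic_config(n_genes = 1000, seed = 1)
comp <- simulate_compendium(cfg)

de     <- call_differential(comp$expression, comp$presence, comp$samples)
counts <- recurrence_counts(response_matrix(de, comp$samples))

classify_markers(counts) |> dplyr::count(label)
#>   chloro_specific  common  mito_specific  none
#>                59      59             58   824

set_algebra(responsive_set(counts, "mito", 4),
            responsive_set(counts, "chloro", 4))
#>   n_a n_b n_intersect n_union
#> 1 120 120          60     180

category_scan(responsive_set(counts, "chloro", 4),
              category_map_from_truth(comp$truth), comp$truth$gene_id)
#>               category category_size observed expected ratio   p_over
#> 1         chloroplasts           136       51    16.32 3.125 1.66e-17
#> 2         mitochondria            99        2    11.88 0.168 1.00e+00
#> 3           peroxisome            11        1     1.32 0.758 7.57e-01
#> 4 transcription_factor            62        5     7.44 0.672 8.87e-01
```

The generator planted 60 genes per label class; the marker classifier
recovers essentially all of them, the two responsive sets overlap in the
shared block (60 of 120 each), and the chloroplast-responsive set is
strongly enriched for chloroplast-annotated genes (observed 51 vs 16.3
expected, ratio 3.1) while the other compartments sit at or below
expectation — the targeted-response structure the statistics are built to
detect. `plot_markers()`, `plot_enrichment()` and `plot_response_matrix()`
visualise these results; `autoplot()` on a `fit_ppde()` object shows the
fitted p-value mixture.

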