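# clonofocus

Analysis of bulk T-cell receptor β-chain (TCRβ) repertoires from paired
tissue and blood samples, built around the question that motivates such
studies: **are T cells at a disease site clonally restricted?** When an
antigen drives a local immune response — in our motivating setting,
resected epileptogenic brain tissue from pediatric epilepsy surgery —
the repertoire concentrates onto few clones, abundant clonotypes recur
between compartments and across surgeries, and some of them resemble
T-cell receptors with known viral specificity.

The package covers the full pipeline:

* **Curation and aggregation** — read AIRR Rearrangement or
  immunoSEQ-style TSV exports, remove junctions that cannot be CDR3
  amino-acid clonotypes (no framework cysteine at IMGT position 104,
  stop codons, frameshifts, non-productive), and aggregate by CDR3
  amino-acid sequence into per-sample clonotype tables with
  template-weighted frequencies.
* **Clonality** — Shannon-entropy clonality index,

  `H = −Σ Pᵢ log₂ Pᵢ`, `H_norm = H / log₂ N`, `clonality = 1 − H_norm`,

  ranging from 0 (maximal diversity) to 1 (monoclonal), with an exact
  paired Wilcoxon signed-rank test for small brain-vs-blood cohorts.
* **Clonotype tracking** — top-N lists with deterministic tie-breaks,
  Venn partitions of 2–4 clonotype sets, and two-proportion Pearson
  chi-squared tests (1 df, depth-aware) classifying each clonotype as
  up / down / no-change between compartments or timepoints.
* **Public/private classification and epitope matching** — calls
  against a local public-clonotype snapshot, and unit-cost Levenshtein
  alignment of CDR3s to virus-specific reference CDR3s with a
  canonical edit script annotating substitutions, insertions and
  deletions.
* **Immune gene signature** — log2 transform, PCA + Ward clustering of
  samples, one-vs-rest Welch marker selection, median-based modified
  z-scores, and correlation of cell-type signature scores.
* **Synthetic data** — a generator for repertoires, reference
  databases and expression matrices with ground-truth labels for every
  planted effect, so the whole pipeline is testable offline.

`run_study()` orchestrates all stages from a config (R list or YAML)
and writes deterministic TSV reports plus a JSON summary.

## Worked example

Simulate a paired brain/blood subject in which 20 clones are enriched
tenfold in brain, then recover the planted structure:

```r
library(clonofocus)

p <- sim_params(seed = 42, n_brain_enriched = 20, brain_enrichment = 10,
                n_expanded = 0, expanded_mass = 0, depth = 1e5)
s <- simulate_subject(p)

brain <- aggregate_clonotypes(curate(s$samples$brain_t1)$kept, s$meta$brain_t1)
blood <- aggregate_clonotypes(curate(s$samples$blood_t1)$kept, s$meta$blood_t1)

clonality_index(brain)
#> Clonality: 0.3163  (H = 8.8566 bits, H_max = 12.9547, N = 7939)

top_n(brain, 50)
#> Top 50 clonotypes of sample sim042_brain_t1: 52.3% of the sampled repertoire

enr <- track(blood, brain,
             universe = s$truth$cdr3_aa[s$truth$brain_enriched])
head(enr[, c("cdr3_aa", "freq1", "freq2", "p", "direction")], 3)
#>           cdr3_aa   freq1   freq2             p direction
#> 1        CPQHIYYF 0.00123 0.01177 4.536874e-189        up
#> 2 CSAMKFVCHNFSWNF 0.00095 0.00996 1.002932e-164        up
#> 3 CEAAQCAFVWTIPRF 0.00028 0.00250  1.680053e-40        up
sum(enr$direction == "up")
#> [1] 20        # all 20 planted enrichments recovered
```

The clonality index of ~0.32 reflects the top-heavy Zipf background
(the top clone alone holds 12.2% of templates); the top 50 clonotypes
account for 52% of the sampled repertoire, and every planted
brain-enriched clone is called `up` at α = 0.05.

Aligning a repertoire CDR3 to a known virus-specific CDR3 annotates
how the reference differs from the query (lowercase = substitution,
`-` = deleted residue, brackets = inserted residue):

```r
edit_align("CASSFFTNTEAFF", "CASSFFGNTEAFF")
#> CDR3 alignment, edit distance 1
#>   query: CASSFFTNTEAFF
#>   ref:   CASSFFGNTEAFF
#>   rendered reference: CASSFFgNTEAFF
#>   substitution at query position 7 (G -> T)
```

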