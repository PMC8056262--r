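---
title: "Methods: repertoire clonality, clonotype tracking and immune signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire clonality, clonotype tracking and immune signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonofocus)
```

## What this package models

`clonofocus` analyses bulk TCRβ-chain repertoires from paired tissue and
blood samples — the typical design when asking whether T cells at a
disease site (here, resected epileptogenic brain tissue) are clonally
restricted, i.e. whether an antigen-driven response has concentrated the
local repertoire onto few clones. The unit of analysis is the
**clonotype**: all rearrangements sharing one CDR3 amino-acid sequence.
Identity is deliberately CDR3-only (V/J calls are carried as
annotation), because public-clonotype sharing and epitope-similarity
comparisons operate on the CDR3 amino-acid sequence.

The pipeline has five analysis stages plus a generator:

1. **Curation and aggregation** (`read_rearrangements`, `curate`,
   `aggregate_clonotypes`). Junctions that do not begin with the third
   framework cysteine (IMGT position 104) cannot be valid CDR3s and are
   removed, as are empty junctions, stop-codon (`*`) or frameshift
   (`_`) sequences, and non-productive rearrangements. Each removal is
   tallied once, under the first matching reason, so the report
   partitions the input exactly. Frequencies are template-weighted by
   default (template counts approximate cell counts in
   immunosequencing assays); `weighted = FALSE` counts each
   rearrangement once instead. A missing template count becomes 1 with
   a warning — a sequenced rearrangement implies at least one input
   molecule — rather than an error.
2. **Clonality** (`shannon_entropy`, `clonality_index`,
   `paired_signed_rank`).
3. **Clonotype tracking** (`top_n`, `overlap`, `compare_frequency`,
   `track`).
4. **Public/private classification and epitope matching**
   (`classify_public`, `edit_align`, `match_viral`,
   `annotate_top_clonotypes`).
5. **Immune gene signature** (`log2_transform`, `pca_cluster`,
   `select_markers`, `modified_z`, `signature_correlation`).

`run_study()` composes stages 1–5 from a config and writes
deterministic TSV/JSON reports.

## The clonality index

For a sample with $N$ unique clonotypes at frequencies $P_i$,

$$H = -\sum_i P_i \log_2 P_i, \qquad
  H_{\max} = \log_2 N, \qquad
  \text{clonality} = 1 - H/H_{\max}.$$

The index is 0 for a maximally diverse sample (all clonotypes equally
frequent) and 1 for a monoclonal one, and the $H_{\max}$ normalisation
makes it comparable across sequencing depths. A single-clonotype sample
has $H_{\max} = 0$ and an undefined ratio; we define its clonality as 1,
honouring the oligoclonal endpoint, since the formula alone does not
decide the case.

Paired brain/blood comparisons use a two-sided Wilcoxon signed-rank
test. Because these studies have few pairs (here nine), the p-value is
**exact** up to 25 effective pairs: zero differences are dropped,
absolute differences receive average ranks at ties, and the null
distribution of the rank sum is computed over all $2^n$ sign
assignments. We evaluate that distribution by convolving the rank terms
(on $2\times$-scaled ranks so tied midranks stay integral) — an
algebraically identical but memory-bounded form of full enumeration;
the test suite checks it against literal $2^n$ enumeration for
$n \le 10$. Above 25 pairs a normal approximation with continuity
correction and tie-corrected variance takes over, and the result object
records which branch ran. Sidedness: two-sided is reported; on the
nine-pair clonality data both sidednesses round to the same
two-decimal p-value, so downstream conclusions do not hinge on the
choice.

## Tracking clonotype frequency changes

For one clonotype with $x_1$ of $n_1$ templates in sample 1 and $x_2$
of $n_2$ in sample 2, we test equality of proportions with the Pearson
chi-squared statistic on the 2×2 table (1 df, no continuity correction
by default; a Yates option exists). This equals the squared pooled
two-proportion $z$ statistic — an identity the tests verify to $10^{-9}$
— and properly accounts for unequal sequencing depths. Direction calls:
`up`/`down` when $p < \alpha$ (default $\alpha = 0.05$, two-sided),
`no_change` otherwise.

Three policies worth making explicit:

* **No multiplicity correction by default.** Per-clonotype raw
  $\alpha = 0.05$ calls match how such tables are conventionally read
  (a p of 0.0496 counts); `adjust = "BH"` is available and off by
  default.
* **Absence policy.** A clonotype absent from one sample still gets a
  test but carries a flag; `strict_absent = TRUE` withholds the
  p-value instead ("not determined"), reproducing the stricter
  reporting convention. Absent from both samples → `not_tested`.
* **Determinism.** `top_n` breaks template-count ties by lexicographic
  CDR3, so ranked lists are reproducible under any input order; the
  rank-50 boundary is otherwise arbitrary.

`overlap()` computes full Venn partitions for 2–4 clonotype sets
(region counts always sum to the union), covering paired
brain/blood and two-surgery designs.

## CDR3 edit alignment

Near-matches between repertoire CDR3s and virus-specific reference
CDR3s are scored by unit-cost Levenshtein distance, computed by dynamic
programming with a **canonical traceback** (match/substitution
preferred over deletion over insertion at equal cost) so that exactly
one edit script is reported among co-optimal alignments — the printed
rendering convention for such pairs (substituted residues highlighted,
inserted residues marked, deleted residues as hyphens) presumes a
single alignment. Our text rendering writes the reference against the
query with substitutions in lowercase, reference-side insertions in
brackets and deletions as `-`:

```{r}
edit_align("CASATALNYGYTF", "CASASANYGYTF")
```

The edit script is sound (applying the ops to the reference
reconstructs the query; see `apply_edit_ops`), and distance properties
(symmetry, triangle inequality, zero iff equal) are property-tested.
One published pair (`CASSPLVDNYGYTF` vs `CASSGLVDNGYTF`) is described
in prose as differing by a single amino acid but requires one
substitution plus one deletion under unit costs; we report the full
edit script (distance 2) rather than counting substitutions only.

`match_viral()` returns all reference rows within `max_distance`
(default 2, which covers the published pairings), sorted by distance,
then epitope, then sequence; an optional HLA filter restricts
candidates to a patient's typed alleles first. Public/private calls
(`classify_public`) are made against a **local** reference snapshot
(CDR3 → number of individuals observed), never a live database, so
results are reproducible and versionable by file checksum (recorded in
the `run_study` log).

## Immune gene signature

The expression stage consumes an already-normalised genes × samples
matrix (platform normalisation and batch correction are upstream and
out of scope). Values are log2-transformed once
(`log2(x + 1)`; double transformation is a state error), samples are
projected onto principal components (gene-wise centred), and Ward
agglomeration (`ward.D2` on Euclidean distances between PC
coordinates) is cut at `k = 3` clusters. Two conventions make the
result deterministic and interpretable: the number of PCs defaults to
the smallest set explaining 80% of variance (the source analysis does
not state how many coordinates fed the clustering), and cluster labels
are renumbered by ascending mean total expression so "cluster k" is
always the high-signature group.

Cluster markers are selected one-vs-rest with Welch's unequal-variance
t-test at $\alpha = 10^{-4}$, keeping genes higher in the target
cluster. The underlying study does not name its test; Welch is chosen
for robustness to unequal cluster sizes and variances, with a
Kruskal–Wallis option, and no multiplicity correction is applied at
this stringent threshold (the null false-positive rate is
property-tested). Heatmap scaling uses median-based modified z-scores,
$z = 0.6745\,(x - \tilde x)/\mathrm{MAD}$, falling back to
mean-absolute-deviation scaling ($z = (x-\tilde x)/(1.253314\,
\mathrm{meanAD})$) for zero-MAD rows and to all-zeros for constant
rows. Signature correlation scores each sample by the unweighted mean
log2 expression of a gene set (the aggregation is not specified in the
source; per-sample means are the simplest interpretable choice) and
reports Pearson's $r$ with a two-sided p.

## The synthetic-data generator

Every stage is testable without downloads because the generator plants
known structure and returns the ground truth alongside the data:

* **Clone sizes**: Zipf-law masses $\propto i^{-s}$ with $s = 1.05$
  over 10,000 background clones by default, randomly assigned to
  sequences, plus `n_expanded` clones explicitly carrying
  `expanded_mass`. This regime puts top-50 repertoire fractions in
  the 5–70% range reported for inflamed tissue. Note that a Zipf
  background with $s$ just above 1 is itself quite top-heavy (the
  largest background clone holds ~13% of mass), so background-only
  clonality sits near 0.3, not near 0; the diversity floor is a
  property of the law, and planted expansions raise clonality above
  it (property-tested as a monotone trend).
* **Public clonotypes** are spiked by sequence identity to a
  simulated pool (10% of clones by default) — convergent
  recombination is not modelled, identity is sufficient for testing
  classification.
* **Compartment enrichment** multiplies selected clones' masses in
  brain before renormalisation; **longitudinal folds** multiply
  masses at timepoint 2. Unnamed folds are planted on established
  clones (expected ≥ 20 templates at the configured depth, the
  analogue of tracking clones drawn from top-N universes); a fold
  planted on a clone too small to be sampled is undetectable by any
  method and would measure the multinomial, not the tracker.
* **Sampling**: each sample is one multinomial draw of `depth`
  templates (default $10^5$). Simulated CDR3s are `C…F`-anchored and
  pass curation by construction, so round trips lose nothing.
* **Expression**: `value(g,s) = baseline(g) + load(g)·infiltration(s)
  + N(0, σ)`, with positive loads only on T-cell / microglia /
  macrophage markers (60/60/55 by default, a 175-gene signature over
  a 577-gene panel, 53 samples). Infiltration levels (default 0/3/6
  log2 units at σ = 1, i.e. 3-SD separation) define the planted
  clusters; because both T-cell and microglia sets load on the same
  factor, their signature scores are positively correlated by
  construction. The generator does not emulate batch effects,
  count-distribution noise, or correlated gene modules beyond the
  single infiltration factor — passing tests show the stages recover
  planted structure, not that real tissue data are this clean.

All randomness flows from one seed; identical parameters give
byte-identical AIRR output files.

## Numerical and scale choices

* Exact signed-rank cutoff at $n = 25$; beyond it the tie-corrected
  normal approximation (checked to agree with `wilcox.test`).
* Frequencies must sum to 1 within $10^{-9}$ per table ($10^{-6}$
  tolerance on entropy input); $0\log 0 = 0$.
* Chi-squared tests use double arithmetic throughout (the 2×2
  cross-product overflows 32-bit integers at realistic depths).
* Levenshtein oracle tests run exhaustively on all pairs of strings up
  to length 3 over a 3-letter alphabet (1,600 pairs against a
  brute-force recursion) plus 500 random pairs up to length 8 against
  an independent implementation; full exhaustion at length 8
  (~$10^8$ pairs) buys no additional coverage for unit-cost DP.
* Null calibration of tracking uses 1,000 replicate pairs of
  multinomial draws (100 clonotypes, depth $10^4$); clonotype masses
  are chosen so expected counts satisfy the chi-squared
  approximation's usual validity range.
* Property-test problem sizes (repertoires of 600–10,000 clones,
  depths $10^3$–$10^5$, 53 × 577 expression matrices) were chosen to
  exercise the asymptotic behaviour each test targets while keeping
  the default suite quick.

## Known limitations

* Clonotype identity ignores V/J genes and nucleotide-level
  convergence; two distinct rearrangements with one amino-acid CDR3
  are one clonotype.
* The chi-squared test is asymptotic; for very rare clonotypes at low
  depth an exact test would be preferable (Fisher's exact is not
  currently wired in).
* Public/private calls are only as good as the local reference
  snapshot; there is no modelling of sharing probability.
* The expression stage assumes a normalised, batch-corrected matrix
  and makes no attempt at cell-type deconvolution.
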