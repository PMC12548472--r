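---
title: "From spot tests to receptor types: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spot tests to receptor types: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagepanel)
library(dplyr)
```

phagepanel turns raw phage spot-test data into receptor-requirement
profiles and receptor types, designs minimal discriminatory host panels,
clusters phages from mixed phenotype data or phylogenetic trees, and
quantifies how well competing classification schemes agree. This vignette
explains the models and conventions behind each stage, the parameters that
matter, and the choices made where the methodology was genuinely open.

## Efficiency of plating and the reduction call

The efficiency of plating (EoP) of a phage on a test strain is its
plaque-forming titer on that strain divided by its titer on the wild-type
reference; we work with `log_eop = log10(EoP)`. A spot test with no plaques
at any dilution is *not detected* (ND) and is treated as complete loss of
infectivity — EoP 0, `log_eop = -Inf` — never as missing data. The
reference titer itself must be countable (positive, not ND); `eop_table()`
errors otherwise rather than guessing.

Replicates are aggregated in log space: ND replicates are dropped and the
remaining finite values averaged, with the number of discarded NDs reported
(`n_nd_dropped`); a pair whose replicates are all ND stays ND. This
generalizes the common practice of averaging the detectable trials when a
spot test intermittently fails.

A pair is called **reduced** when plating efficiency drops more than
10-fold: `log_eop < -1`, with a strict inequality. The strictness matters
at the boundary: a pair sitting exactly at a 10-fold drop is *not* called
reduced, so boundary tests are unambiguous. The adsorption-assay companion
call uses the same convention: a strain is a target-receptor mutant when
its adsorption rate `100 * (1 - plaques_t10 / plaques_t0)` is strictly
below 20%.

## Receptor-requirement profiles

`derive_receptor_profile()` converts reduction calls on resistant mutants
into a phage-by-gene 0/1 requirement matrix. For each phage:

1. **Candidates** are the union of the mutated-gene sets of the strains that
   block it.
2. **Exoneration**: a strain that does *not* block the phage, and whose
   mutated genes are a subset of some blocking strain's genes, clears all
   its genes from the candidates. The canonical case: a double mutant
   `{flhD, bcsG}` blocks, the single `{bcsG}` mutant does not — so `bcsG`
   is exonerated and only `flhD` is retained. Exoneration requires such an
   observed strain; nothing is inferred from gene annotations.
3. **Ambiguity**: a surviving candidate that no blocking strain pins down
   to a single gene (after exoneration) is kept as required but flagged
   `ambiguous`. Two overlapping double mutants such as `{nfrB, ompA}` and
   `{nfrB, tolA}`, both blocking, leave all three genes required and
   flagged: the screen alone cannot separate them.
4. **Overrides** (external evidence: single-gene knockout libraries,
   complementation assays) are applied last and clear the flags. The
   published 13-phage matrix shipped as `wec_receptor_matrix()` reflects
   exactly such evidence for its double-mutant attributions, which is why
   it is curated rather than recomputed from reductions alone.

The inference is monotone in the reassuring direction: adding a
non-blocking single-gene strain can only *clear* requirement bits, never
set them.

`assign_receptor_types()` letters identical profile rows (flags ignored)
`a`, `b`, `c`, ... in order of first appearance along the phage ordering,
so type labels are deterministic and row order is meaningful end to end.

## Greedy discriminatory panels

Given a binary phage-by-strain infection matrix, the discriminatory power
of a strain subset is the number of distinct phage infection patterns it
induces (`pattern_count()`; the empty set induces one pattern).
`greedy_panel()` repeatedly adds the strain with the largest marginal gain,
breaking ties by input column order, and stops at saturation (zero gain
everywhere) or at `max_strains`. Both stopping modes exist because a user
may want either the natural saturation point or a fixed panel size;
`pattern_count` is monotone under subset inclusion, so cumulative counts
never decrease. Greedy selection is not globally optimal in general — the
package makes no such claim — but its first pick is provably the best
single strain, a property the test suite verifies exhaustively on small
instances.

## Clustering mixed phenotypes

Host-range phenotypes mix binary columns (infects strain X or not) with
quantitative physiology measurements, so distances use Gower's coefficient
rather than Euclidean distance:

$$d_{ij} = \frac{\sum_f w_f\,\delta_f(i,j)}{\sum_f w_f}$$

over the features observed in both items. Binary features contribute a 0/1
mismatch, quantitative features `|x_i - x_j|` divided by the feature's
observed range. Conventions, each chosen to keep the distance well defined
on real assay tables:

* missing cells → pairwise deletion with weight renormalization;
* zero-range features → contribution 0 (they carry no signal but keep
  their weight, leaving distances in [0, 1]);
* a pair sharing no observed feature is an error, not a silent NA.

Clustering is complete-linkage agglomeration (`hclust_complete()`), with
equal-distance merge candidates resolved to the lexicographically smallest
cluster-index pair so that merge sequences are reproducible. Cutting at
`k` removes the `k - 1` highest merges; cluster labels follow first
appearance in the item order.

The number of clusters is chosen by silhouette: for each candidate `k`,
the partition's average `s(i) = (b_i - a_i)/\max(a_i, b_i)` is computed
and the maximizing `k` selected. Items in singleton clusters score 0 (the
standard convention), as does the degenerate `a_i = b_i = 0` case, and
silhouette ties go to the smallest `k` (parsimony). The default sweep is
`k = 2..min(10, n - 1)`; both bounds are arguments, since practice varies
between sweeping to 9 and to 10 and the choice can matter on small panels.

Tree-based classifications enter the same chain through
`patristic_dist()`: leaf-to-leaf sums of branch lengths on a Newick tree
(read with `read_newick()`, which refuses trees with missing branch
lengths rather than assuming a default). Patristic distance is one of
several defensible tree-to-distance conversions (cophenetic ultrametric
heights and identity-based distances being alternatives); it is the one
implemented here because it uses the tree's own edge lengths directly and
requires no re-estimation.

## Concordance between classification schemes

Agreement between two partitions of the same phages is the Adjusted Rand
Index,

$$ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E},
\qquad E = \frac{\sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}}{\binom{n}{2}},$$

computed from the label contingency table. When both partitions are all
singletons or both a single cluster the formula is 0/0; `adjusted_rand()`
then returns 1 for identical partitions and 0 otherwise, with a warning.
`compare_partitions()` canonicalizes labels by first appearance before
comparing — a deliberate no-op for ARI (which is relabeling-invariant),
kept so that the partitions it prints are consistently labeled. Raw values
are always retained; 2-decimal display values are reported alongside.

The package ships the published receptor matrix and cluster memberships of
a 13-phage *E. coli* collection (plus three validation phages) as built-in
tables; re-deriving their concordance is the package's worked example:

```{r wec}
adjusted_rand(wec_receptor_partition(include_validation = FALSE),
              wec_physiology_partition(include_validation = FALSE))
adjusted_rand(wec_receptor_partition(include_validation = TRUE),
              wec_physiology_partition(include_validation = TRUE))
```

## The synthetic-data generator

`simulate_phage_panel()` exists so the entire chain can be validated
against a known ground truth. It plants receptor types and emits every
input the pipeline consumes:

* phages are assigned to `n_types` round-robin; each type carries a
  distinct gene-requirement vector, with types 1 and 2 *nested* (type 2
  requires one extra gene) so the near-identical-type scenario — two types
  separated by a single gene — is always exercised;
* knockout strains are single-gene mutants covering every gene plus random
  double mutants; blocked phage-strain pairs read ND with probability
  `p_nd_given_blocked` and otherwise a large finite drop; permissive pairs
  draw log-EoP from a normal truncated to `(-1, 0]`, so that with
  `p_spurious_drop = 0` no permissive pair is ever called reduced and
  zero-noise recovery of the planted profile is exact by construction —
  false positives enter only through `p_spurious_drop`;
* the phenotype table pairs type-specific binary host-range patterns
  (distinct by construction via a binary-code prefix, corrupted at
  bit-flip rate `epsilon`) with quantitative features drawn around
  type means separated by `delta` with within-type scatter `sigma`.

Defaults are the conditions of the built-in worked example: 13 phages in 6
types, reference titer 1e7 PFU-equivalents, 3 replicates, blocked pairs
mostly ND (`p_nd_given_blocked = 0.7`), 16 binary host columns (the size
of the optimized panel) and 4 physiology features. The noise defaults
(`noise_sd = 0.3`, `p_spurious_drop = 0.02`, `epsilon = 0.05`) are chosen
to be discriminating in tests — small enough that recovery usually
succeeds, large enough that it can fail — not as estimates of any
particular assay's error.

What the generator does *not* emulate: correlated errors across replicates
or strains, partial-resistance intermediates, phenotype features whose
within-type distribution is non-Gaussian, and tree topologies (trees for
the patristic path are hand-written fixtures). Passing the recovery suite
therefore demonstrates the pipeline's internal consistency, not robustness
to every failure mode of real spot-test data.

```{r synthetic}
cfg <- sim_config(n_phages = 12, n_types = 4, noise_sd = 0,
                  p_spurious_drop = 0, epsilon = 0, sigma = 0, seed = 7)
b <- simulate_phage_panel(cfg)
cl <- cluster_phages(gower_dist(b$phenotypes))
glance(cl)
adjusted_rand(cl$partition, b$truth)
```

## Numerical and scale choices

All algorithms here are exact at the problem sizes the package targets
(tens of phages, tens of strains): the complete-linkage implementation is
the O(n^3) textbook agglomeration, silhouette and Gower are direct
evaluations, and the greedy panel loop is O(strains^2 x phages) — there is
no approximation to tune. The test suite consequently validates against
brute-force oracles at n up to 50 items and runs Monte-Carlo recovery
sweeps at 50 replicates per noise level, sizes chosen to exercise every
code path while keeping the suite quick to run routinely. Determinism is
explicit everywhere randomness appears: the generator consumes a single
seed and restores the caller's RNG state, and all tie-breaks (greedy
column order, merge pairs, silhouette argmax, type lettering) are
documented input-order rules rather than accidents of implementation.

## Known limitations

* Receptor inference sees only the genes mutated in the screen: genes
  essential for infection but never mutated are invisible, and an all-zero
  profile row means "untouched by this panel", not "receptor-less".
* Subset-exoneration cannot resolve overlapping multi-gene mutants; that
  is what the ambiguity flags and the override mechanism are for.
* Greedy panels are heuristics; for matrices small enough, an exhaustive
  check is feasible and the test suite performs one for the first pick.
* ARI between two schemes says nothing about which scheme is right — it
  measures agreement, not accuracy against biology.
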