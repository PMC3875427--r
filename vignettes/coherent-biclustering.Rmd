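---
title: "Coherent-column biclustering by maximal frequent itemset mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherent-column biclustering by maximal frequent itemset mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A *coherent-column bicluster* of an expression matrix (genes in rows,
experimental conditions in columns) is a pair (G, C) of a gene set and a
condition set such that, within every selected condition, the selected
genes' expression values differ by at most a per-column width `MAX_DIFF`.
Genes in such a bicluster move in the same direction with similar
magnitude under each selected condition, the classic signature of
co-regulation that holds only under part of the measured conditions —
which is why global clustering of rows misses it.

fimbic enumerates these biclusters *exhaustively* by reduction to frequent
itemset mining:

1. **Discretization into items.** Each column is processed independently.
   Values are clipped into `Mean ± 3 SD` (statistics computed on the
   original values; SD is the population form, dividing by *n*).  Because
   clipping pins the effective extremes at `Mean ± 3 SD`, the window width
   `(MAX − MIN)/BIN` is identically `6·SD/BIN`.  Values within
   `SD_COEFF·SD` of the column mean are discarded as undifferentiated.
   The retained genes are sorted by value and a window of width `MAX_DIFF`
   slides over them gene-wise: each retained gene anchors one *item*, the
   set of retained genes in the closed interval
   `[v_anchor, v_anchor + MAX_DIFF]`.  Before deduplication the number of
   items in a column equals its retained gene count.

2. **Mining.** A gene's *transaction* is the set of items containing it.
   A set of items is *frequent* when at least `MIN_ROW` genes carry all of
   them — those supporting genes are exactly the genes coherent in every
   touched column, so a frequent itemset *is* a bicluster.  fimbic
   enumerates the *maximal* frequent itemsets (those with no frequent
   strict superset) with a depth-first set-intersection search over gene
   bitsets, using support-ascending child ordering, parent-equivalence
   pruning and subsumption pruning.  Itemsets spanning fewer than
   `MIN_COL` distinct conditions are then dropped.

3. **Scoring.** Coherence alone does not imply biological signal, so each
   bicluster receives an empirical p-value.  The statistic is the average
   pairwise Pearson correlation over the bicluster's row vectors,

   `T = 2/(R(R−1)) · Σ_{i<j} r(x_i, x_j)`,

   a shape-invariant quantity in [−1, 1].  The null draws `n_perm`
   submatrices of the same shape — `R` distinct rows and `C` distinct
   columns sampled uniformly and independently from the full matrix — and
   `p` is the fraction of null draws with `T` at least the observed value.
   Biclusters with `p ≤ alpha` survive.

4. **Merging.** Maximal itemsets still overlap heavily (`MIN_ROW`-sized
   shavings of one biological block are all maximal).  Biclusters with an
   *identical* condition set that are connected through gene overlap form
   a merge group; each group is replaced by one bicluster grown from its
   lowest-p member by adding candidate genes (ranked by correlation with
   the seed's per-condition mean profile) as long as the empirical
   p-value stays at or below `alpha`, the prefix length being found by
   binary search.

5. **Gene set networks.** Genes are partitioned by their *membership
   signature* — the exact set of merged biclusters containing them.  Each
   signature class is one node; two nodes are joined by an edge weighted
   by the number of biclusters their signatures share, so each bicluster
   induces a clique.  Connected components are reported largest-first,
   with per-node degree statistics, hub-neighborhood extraction and
   GraphML/TSV export for downstream enrichment tools.

## Parameters

| name        | default | meaning |
|-------------|---------|---------|
| `bin`       | 7       | window width is `6·SD/bin` per column; larger values demand tighter coherence |
| `sd_coeff`  | 0.7     | half-width (in SDs) of the discarded band around the column mean |
| `min_row`   | 30      | minimum genes per bicluster; the mining support threshold |
| `min_col`   | 3       | minimum conditions per bicluster |
| `alpha`     | 0.05    | significance ceiling on empirical p-values |
| `n_perm`    | 100000  | null draws per bicluster shape |
| `n_perm_merge` | 10000 | cheaper null draws inside the merge binary search; final results are rescored at `n_perm` |
| `rng_seed`  | 1       | run seed; all randomness derives from it |

All defaults except `n_perm_merge` are the established defaults of this
method family; `n_perm_merge` trades permutations for speed only inside
the search and never affects reported scores.

## Design choices in the open corners

Several details of the procedure admit more than one reading; the package
fixes them as follows.

* **Window inclusion is the closed interval** `[v, v + MAX_DIFF]`.  This
  keeps equal-valued genes together and matches the coherence constraint
  `max − min ≤ MAX_DIFF` exactly.
* **SD is the population standard deviation.**  The `6·SD/bin` identity
  then holds without a small-sample correction, even for very short
  columns.
* **SD-filtered genes are excluded from windows entirely**, both as
  anchors and as members: a value judged undifferentiated cannot support
  coexpression.
* **Degenerate columns** (SD = 0) contribute no items rather than
  aborting the run; a matrix whose every column is degenerate is a
  degenerate input and errors.
* **An itemset may contain several items of one column** (overlapping
  windows); the bicluster's condition set is the set of *distinct*
  columns.  Maximality naturally pulls every item that covers the support
  genes into the itemset, and coherence still holds because support is an
  intersection.
* **Upper-tail p-values.**  The statistic is largest for internally
  correlated biclusters, and significant biclusters are those *few* null
  draws reach; `p = #(null T ≥ observed)/n_perm`, with no smoothing, so a
  bicluster that beats every null draw reports exactly 0.
* **Zero-variance rows** contribute `r = 0` to each of their pairs —
  neutral rather than undefined.
* **Merge groups are order-free**: condition-set equality plus connected
  components of the share-a-gene relation, one merged bicluster per
  component.  Merged biclusters of one partition have disjoint gene sets,
  which is what makes merging idempotent.
* **The merge predicate need not be monotone** in the prefix length:
  adding one more well-correlated gene can, in principle, move the
  empirical p-value either way.  Binary search is retained; when the
  predicate is monotone it returns exactly the largest feasible prefix
  (the test suite asserts this agreement against an exhaustive scan), and
  otherwise it returns a feasible prefix.  The final merged bicluster is
  rescored at the full `n_perm`, and the prefix is shortened if that
  rescoring lands above `alpha` — the seed itself always qualifies.
* **Column coherence is not re-imposed after merging**; the p-value
  ceiling is the merge criterion, and per-column ranges of merged
  biclusters can be read off the output.
* **Node conditions** are the union of the signature biclusters'
  condition sets.
* **Determinism.**  Every sort has a total tie-break (p ascending, then
  smallest gene id, then the full gene list), node ids follow the sorted
  signature, and all random streams are derived from `rng_seed` with
  per-shape substream seeds, so null ensembles are cached per bicluster
  shape and identical across evaluation orders.  Two runs with the same
  seed produce byte-identical outputs.

## The synthetic-data generator

`simulate_expression()` draws background cells from `N(0, noise_sd²)` and
overwrites implanted blocks with a per-condition center level plus uniform
jitter.  Default levels are spaced evenly over 2–3.5 background SDs:
far enough from the column mean that the `sd_coeff = 0.7` filter retains
the block, and *varying across conditions* so that block rows share a
strong common profile — the same-direction, different-magnitude shape the
method targets.  A block with one flat level across its conditions would
be coherent per column yet have near-zero row correlations, and the
scoring stage would rightly discount it.  After generation the block
spread is checked against `6·SD/bin` per implanted column, so implanted
ground truth is guaranteed minable at the intended `bin`.

The generator emulates the geometry of implanted-bicluster benchmarks,
not real microarray noise: there are no probe effects, batch effects,
heavy-tailed noise or correlated background.  Tests passing on these
fixtures demonstrate correctness of the algorithms under their stated
model, not performance on any particular real dataset.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite completes
in a few minutes: miner-versus-oracle equivalence on matrices up to 8 × 6
(where exhaustive enumeration over gene subsets is feasible), implant
recovery on a 200 × 20 matrix with a 15 × 4 block at `n_perm = 1000`, and
null calibration with 200 sampled submatrices at `n_perm = 500`, where the
Kolmogorov–Smirnov distance of the p-values from Uniform(0, 1) is checked
against 0.1.  Production runs on compendium-scale matrices would use the
full `n_perm = 100000` default.

## Known limitations

* Maximal frequent itemsets are maximal in *itemset* space.  A maximal
  coherent submatrix (G, C) is only recoverable when no item overlaps G
  in `min_row`-or-more genes without containing it; otherwise mining
  fragments the block and the merging stage is what reassembles it.  On
  dense data with permissive `min_row` the two notions of maximality can
  diverge.
* Enumeration is exact and exhaustive; there is no top-k or approximate
  mode, so item-dense inputs (low `bin`, low `sd_coeff`, low `min_row`)
  can be combinatorially expensive.
* The null model samples rows and columns independently and without
  structure; correlated backgrounds (e.g. batch effects) would make it
  anti-conservative.
* Only the coherent-column bicluster type is supported — no quantile or
  rank discretizations, and no additive/multiplicative coherence models.
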