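---
title: "Methods: gene-metabolite integration with gmlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-metabolite integration with gmlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmlink)
```

## Scope and data model

gmlink integrates a transcriptomics and a metabolomics experiment measured
on the same samples, after each omic has been analyzed separately: the
expected inputs are tables of *significant* features (differentially
expressed genes, differentially abundant metabolites) in wide format —
features in rows, samples in columns, one unique-ID column — plus a design
file mapping samples to groups. gmlink performs no normalization and no
differential testing; those belong to upstream tools. All statistics here
are second-moment methods (correlation, PCA, PLS), so any consistently
scaled input (log counts, normalized abundances) is acceptable.

Two analysis arms share this data model:

* a **knowledge-driven arm**: map features to KEGG, cluster metabolites
  into correlation modules, summarize each pathway's transcription as a
  metagene, and regress modules on metagenes by sparse PLS;
* a **data-driven arm**: rank all gene-metabolite correlations and keep
  the strongest as a bipartite network, with no annotation involved.

## KEGG annotation

Annotation runs against a *snapshot* — a frozen flat-file copy of KEGG
compound synonyms, gene symbols/aliases and pathway membership
(`load_snapshot()`, dialect documented there). The snapshot is
authoritative: the optional live fetch (`fetch_kegg_snapshot()`) only
writes the same files as a cache. This keeps annotation deterministic and
offline, and pins results against KEGG content drift.

Metabolite names are free text, so matching is a cascade
(`match_metabolite()`):

1. **exact** equality of normalized names — score 1.0, and only exact
   matches can score 1.0;
2. **token-subset**: all tokens of the query appear in a synonym's token
   set or vice versa, scored by the Jaccard index of the token sets
   (capped at 0.999 so a reordered name can never tie an exact match).
   This stage is gated by the subset condition itself rather than by
   `min_score`: a reordered or partially qualified name ("valine l") has
   a low Jaccard against a stereo-stripped synonym yet is still an
   unambiguous token match;
3. **edit distance**: normalized Levenshtein similarity
   `1 - d/max(len)`, kept only at `min_score` or above. The default 0.85
   is deliberately conservative — stages 1-2 already absorb the common
   case/stereo/punctuation variation, and a high threshold prevents
   short, unrelated names from pairing.

Normalization (`normalize_name()`) lowercases, collapses whitespace,
unifies dashes and quotes, spells out Greek letters, and by default
strips leading stereo-descriptors ("L-", "D-", "DL-", "(S)-", "(R)-"),
repeatedly and longest-first so the function is idempotent — a property
the tests fuzz with 1,000 random strings. Stripping is on by default
because stereo prefixes are the dominant mismatch between measured names
and KEGG synonyms; raw names are always preserved in the output.

Formula-ambiguous lipids (e.g. all sphingomyelins) are collapsed by
user-supplied rules into a metabolite *class* carrying one class-level
KEGG id (`assign_metabolite_class()`); the first matching rule wins and
overlaps are logged. Gene symbols match primary symbols before aliases,
case-insensitively; a symbol hitting several KEGG genes is reported once
per gene and flagged ambiguous. Annotation never drops rows: unmatched
features keep an empty KEGG id, and features whose KEGG id belongs to no
pathway keep an empty pathway list but remain available to the
annotation-free tools.

## Modulated modularity clustering (MMC)

Metabolites are clustered on their correlation structure. The
correlation matrix (Pearson by default; Spearman available — the choice
is exposed because rank correlation is preferable for heavy-tailed
abundances) is mapped to edge weights through a sigmoid

$$ w_{ij} = \frac{1}{1 + e^{-s(|r_{ij}| - t)}}, \qquad w_{ii} = 0, $$

and the weights are partitioned by maximizing weighted Newman modularity

$$ Q = \frac{1}{2m}\sum_{ij}\Bigl(w_{ij} - \frac{k_i k_j}{2m}\Bigr)
      \,\delta(c_i, c_j). $$

The "modulated" part is the grid over the transform: for every
$(s, t)$ in `s_grid` × `t_grid` (defaults $s \in \{1,2,4,8,16,32\}$,
$t \in \{0.3,\dots,0.7\}$) the weights are rebuilt, partitioned and
scored, and the sharpest-separating transform — the one with maximal
$Q$ — wins. Ties break toward fewer modules, then smaller $s$, then
smaller $t$, so the result is deterministic. Absolute correlation is
used so anti-correlated metabolites co-cluster (modules routinely
contain both signs); a `signed` flag disables this.

The partitioner is recursive leading-eigenvector bisection of the
(generalized) modularity matrix, each split refined by single-node
Kernighan–Lin flips, followed by a global greedy phase of single-node
moves and module merges until no step increases $Q$. Eigenvector sign
indeterminacy is canonicalized, and all scans run in fixed index order.
On exhaustive enumeration of all 4,140 partitions of 8-node random
graphs the refined spectral result attains the global optimum in over
90% of trials and by construction never exceeds it.

Numerical notes: $Q$ is recomputed from the stored weights and partition
(tests require agreement to 1e-12); module labels are relabeled by
decreasing size; the heatmap ordering keeps modules contiguous and sorts
members by mean intra-module $|r|$. With no true structure (independent
features) the chosen partition stays fragmented — several modules, none
close to the full feature set — but $Q$ sits near 0.5, not near 0:
optimized modularity of a sparse random graph is substantially positive
(the usual modularity inflation), so $Q$ must not be read as calibrated
evidence of structure. The tests assert the fragmentation property, not
a near-zero $Q$.

## Pathway metagenes

A pathway metagene is the leading principal component of the pathway's
standardized expression submatrix: genes are centered and scaled to unit
*population* variance (constant genes dropped with a log message rather
than erroring — filtered significant-gene inputs often carry ties), and
the samples-by-genes matrix is decomposed by SVD. Components are
retained until cumulative explained variance reaches `var_target`
(default 0.5, always at least one); pathways with fewer than `min_genes`
(default 3) genes in the data are skipped. A coherently regulated
pathway concentrates its variance in component 1, which is therefore the
default (and usually only) predictor exported to integration; additional
components are available via `metagene_matrix(components = ...)`.

PCA signs are arbitrary, so each component is oriented to correlate
positively with the majority of its pathway's gene profiles; an exact
tie falls back to making the loading of the lexicographically first gene
id positive. The id-based (not row-based) tie-break makes the output
invariant to the order in which genes appear in the input — a property
the tests verify by permuting rows.

## Sparse PLS integration

Each metabolite module is related to the pathway metagenes by sparse
PLS in regression mode: predictors $X$ = metagene scores, responses
$Y$ = the module's metabolite abundances (the raw profiles, not a
module summary, so individual metabolite-pathway relationships remain
visible in the output). Per component the leading singular pair of
$X_h^\top Y_h$ is found by alternating power iterations (tolerance
1e-9, at most 500 iterations), with $u$ soft-thresholded each iteration
so exactly `keepX` predictors keep nonzero loadings (largest absolute
values; ranking ties break by column order, and a tie exactly at the
threshold keeps its unshrunk value so the selected-set size is exact).
Scores are $\xi_h = X_h u$, $\omega_h = Y_h v$; both blocks are deflated
by regression on $\xi_h$, which makes X-scores mutually orthogonal.
Components are oriented so the largest-|loading| predictor is positive.
Columns are centered and unit-scaled internally, so selection is
invariant to positive rescaling of any column.

With `keepX = p`, `keepY = q` the algorithm reduces to dense PLS and is
tested against an independent sequential-SVD oracle (and cross-checked
against mixOmics) to 1e-8. Defaults `ncomp = 2`, `keepX = 10`: module
association heatmaps are legible at roughly ten pathways, and two
components capture a two-condition contrast plus one secondary trend.
No cross-validation is attempted — with ~10 samples, resampling-based
tuning would be noise; the sparsity level is a display budget, not an
inferential claim.

The exported heatmap statistic is
$\mathrm{sim}(i,j) = \sum_h \mathrm{cor}(X_i, \xi_h)\,
\mathrm{cor}(Y_j, \omega_h)$ over retained components, for selected
predictors, clipped to $[-1, 1]$ for display.

## Unbiased correlation network

`all_pairs_correlation()` correlates every gene against every metabolite
over the shared samples (at least 3 required; constant rows excluded
with a warning). `top_k_edges()` keeps the `k` pairs with largest
$|r|$ — default 500 — sorted descending, with ties at any rank broken by
(gene, metabolite) bytewise lexicographic order, never randomly. No
correlation threshold and no p-value filtering is applied: the tool
ranks, it does not test, and multiple-testing control is deliberately
out of scope. Exports: SIF (relation `pos`/`neg` by the sign of $r$),
TSV (signed $r$ to 8 decimals) and GraphML (typed bipartite nodes, via
igraph). `hub_summary()` tabulates per-metabolite degrees with sign
breakdown; high-degree metabolites are the natural candidates for
functional follow-up.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seed-deterministic package code:

* `make_planted_modules()` draws features from a Gaussian factor model
  (`sqrt(between_r)`·global + `sqrt(within_r - between_r)`·block +
  `sqrt(1 - within_r)`·noise), giving expected within-block correlation
  `within_r` exactly; `within_r = between_r = 0` is the pure-noise null.
* `make_pathway_factor_data()` emulates the shape of a two-condition,
  two-omics study — ten samples in two balanced groups of five, mirroring
  paired transcriptomics/metabolomics designs with five replicates per
  condition. Each pathway has a latent activity factor (group shift 1.5
  plus unit noise), genes load on it with U(0.6, 1) loadings and noise
  SD 0.3, and linked metabolites follow a designated factor with a
  chosen sign; unlinked metabolites are pure noise.
* `make_mini_kegg()` writes a fully synthetic miniature KEGG snapshot
  (20 compounds with case/stereo/Greek synonym variants, 30 worm-style
  genes with aliases, 5 pathways) exercising every matching-cascade
  branch offline; a generated copy ships under
  `inst/extdata/mini_kegg/`.

These fixtures are Gaussian with exact factor structure. Real
metabolomics data have heavy tails, batch effects, missingness and
block-diagonal-plus-overlap correlation; real pathways overlap heavily
and are incompletely annotated. Passing the planted-recovery and
driver-recovery tests therefore shows the algorithms are implemented
correctly and have power under clean conditions — it does not certify
recovery rates on real data, where module boundaries are softer and
annotation coverage caps what pathway integration can see.

## Problem sizes and reproducibility checks

The shipped property checks (test suite and `scripts/acceptance.R`) use
desk-scale problems chosen to make each property decidable in seconds:
60 metabolites / 3 blocks / 50 samples for module recovery; 8-node
graphs for exhaustive modularity enumeration (4,140 partitions); 50
random submatrices for the PCA oracle; 30×20 matrices for the top-K
sort oracle; 8 pathways × 10 genes, 10 samples for driver recovery; and
a full simulate→annotate→cluster→metagene→sPLS→network pipeline run
twice and compared byte for byte. All randomness flows from a single
seed argument.

## Known limitations

* The modularity partitioner is a high-quality heuristic, not an exact
  solver; on adversarial weight matrices it can stop short of the
  global optimum (observed in a few percent of random 8-node trials).
* $Q$ is not null-calibrated (see above); comparing $Q$ across datasets
  of different size or density is not meaningful.
* Name matching is synonym-based; it cannot disambiguate true isomers
  (mass-based annotation is upstream and out of scope), and the class
  rules are user policy, not chemistry.
* One metagene per pathway discards within-pathway antagonism unless
  `var_target` is raised to export further components.
* sPLS sparsity levels are fixed by the user; no inferential guarantees
  attach to the selected sets.
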