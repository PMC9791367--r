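---
title: "Cis/trans regulatory pleiotropy in perturbation networks: methods"
author: "pleionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis/trans regulatory pleiotropy in perturbation networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleionet)
```

## The question and the model

Regulatory mutations can act in *cis* (allele-specific, typically local to
the focal gene) or in *trans* (through a diffusible factor). A standing
hypothesis in regulatory evolution is that *cis* mutations are less
pleiotropic — they perturb fewer genes — and therefore less deleterious,
which would help explain the preferential accumulation of *cis* variants
over evolutionary time. Yeast gene-deletion expression compendia allow a
genome-scale test: deleting a gene is an extreme *cis* mutation for that
gene's own expression, and any *other* deletion that significantly changes
the focal gene's expression is a *trans* mutation for it.

`pleionet` encodes this as a **perturbation network**. From a compendium of
per-strain expression profiles (M values, i.e. log2 fold-changes versus wild
type, with FDR-adjusted p-values), a binary directed adjacency matrix is
built with one row per deleted gene and one column per measured gene:

> A[d, g] = 1 iff deletion of *d* significantly changes expression of *g*

where "significant" means |M| >= log2(`fold_change_min`) **and**
p <= `p_max` (defaults 1.7 and 0.05, both inequalities non-strict). The
out-edges of a row are the pleiotropic footprint of a *cis* deletion; the
in-edges of a column identify the *trans* deletions for that focal gene.

A deleted gene qualifies as a **focal gene** if (i) its own deletion shows a
significant *decrease* of its own expression (evidence the deletion is
correct and the gene was expressed), (ii) it is measured on the array, and
(iii) it has at least one trans-regulator. The filters are applied in that
sequence — an unmeasured gene cannot fail the self-decrease test, so it
passes filter (i) and is removed by filter (ii) — and the count removed at
each step is logged.

## Pleiotropy measures

Three measures are computed per deletion or per (trans, focal) pair:

* **Count** — number of significantly differentially expressed genes,
  excluding the deleted gene itself, and for pair-level values also
  excluding the focal gene.
* **Parallel count** — the pair-level count after removing *nested*
  effects, i.e. targets of the trans deletion that are also targets of the
  focal gene's own deletion. Nested effects plus parallel effects
  partition the trans count exactly; this identity is enforced by test.
* **Euclidean distance** — the deletion profile's distance from wild type
  in expression space, `sqrt(sum(M^2))` over all measured genes with *no*
  significance cutoff. On the log2 scale wild type sits exactly at the
  origin, which is why log2 coordinates are the default; a `linear` switch
  instead uses fold changes `2^M` with wild type at the all-ones point,
  for users who read "fold change" literally. By default the deleted
  gene's own (extreme, ~-6) self-coordinate is excluded from its cis
  distance so that the cis and trans measures are comparable; this is a
  configurable choice (`exclude_self`), and pair-level distances likewise
  exclude the trans gene's own and the focal gene's coordinates, mirroring
  the count definition.

Per focal gene, the contrast is `median(trans values) - cis value`
(midpoint median for even counts). The headline statistics are the
one-sample one-sided t test of these differences against zero and the
proportion of focal genes (or of individual pairs) whose cis value is
*strictly* greater than the trans value — ties count as "not greater",
the conservative reading given that small cis-greater fractions are the
signal of interest. Because deletions can only decrease their own gene's
expression, a directional variant restricts pairs to trans deletions that
decrease the focal gene (`focal_decreasing_pairs()`).

## Permutation null models

Two permutation schemes ask whether the cis/trans asymmetry needs specific
wiring or only the degree distribution:

* `preserve_outdegree` — each row of A is independently shuffled
  (self cell included). Out-degrees are conserved exactly; which genes a
  deletion hits is randomized.
* `full_random` — a row-shuffle pass followed by a column-shuffle pass.
  Total edge count is conserved but out-degrees collapse to an
  approximately binomial distribution: the heavy tail is destroyed.

On each replicate the trans-regulator sets are re-derived from the permuted
matrix and the per-focal difference recomputed with the same self/focal
exclusions as on the real network. Focal eligibility keeps the original
self-decrease and measured status (a row shuffle cannot meaningfully
re-create a self-effect) and, by default, re-applies the
at-least-one-trans-regulator requirement within each replicate
(`reapply_trans_filter = FALSE` keeps the original focal set instead). The
top-level seed spawns one substream seed per replicate, so results are
reproducible and independent of evaluation order.

A subtle point checked by test: under `full_random`, excluding the focal
gene from each trans count exactly offsets the size-biased sampling of
trans-regulators for binomial-like degrees, so replicate medians center on
zero — whereas under the degree-preserving scheme the heavy tail keeps them
strongly positive. This is the "friendship paradox" of heavy-tailed
networks: the regulators a gene happens to have are, by the very fact of
their reach, more pleiotropic than the gene itself. For a network whose
edges are *uniformly randomly placed* to begin with (Bernoulli rows, hence
binomial out-degrees), full randomization reproduces the network's own law
and the two schemes become statistically indistinguishable; the test suite
verifies this with a KS check. Note that a *constant* out-degree network
would not behave this way (the two schemes then differ by roughly one
count), which is why "uniform" is read as uniform edge placement, not
constant degree.

## Degree distribution and fitness

Scale-freeness is assessed by the least-squares fit of log10 p(K) on
log10 K, where K is a deletion's out-degree (self-edge included by default,
as the raw row sum; excludable by flag) and p(K) is the empirical
frequency over K > 0. The reported exponent is minus the slope; slope and
R^2 are invariant to the log base (base 10 is used). Zero-degree nodes
cannot enter the fit and their count is reported. The fit is exact on
noiseless power-law input (tolerance 1e-10 in tests) and recovers the
exponent within ±0.1 from 1e5 multinomial draws; on small sparse
histograms (hundreds of nodes) the raw log-log fit is known to be biased
by tail bins of count one, which is why the acceptance report distinguishes
the descriptive network fit from the large-sample recovery.
Maximum-likelihood power-law fitting is deliberately not used: the log-log
least-squares estimator is itself part of the procedure being reproduced.

Deletion fitness (competitive fitness relative to a reference, reference
= 1) enters two ways: an OLS regression of fitness on log10 of the cis
count (zero-count genes excluded as the log is undefined — an alternative
would be a pseudocount, not taken here; their number is logged), and the
per-pair / per-focal comparison of fitness *costs* (1 - fitness; fitness
above 1 gives a negative cost and is retained, no winsorizing). The Welch
two-sample test is exposed generically; the pipeline applies it where two
difference distributions need comparing, most plausibly cis values against
per-focal median trans values.

## The synthetic generator

`synthetic_spec()` defines the study conditions used throughout the tests
and the acceptance script. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `n_genes`, `n_deletions` | 2000, 600 | ~1/3-scale version of a genome-wide compendium (thousands of measured genes, hundreds-to-thousands of strains); large enough for the paradox to emerge, small enough for seconds-scale tests |
| `gamma`, `k_max` | 0.75, 1000 | heavy-tailed out-degree exponent and maximum reach typical of yeast perturbation networks (cis counts up to ~1000) |
| `self_effect_m` | -6 | a deletion abolishes its own transcript; ~64-fold decrease on the log2 scale |
| `edge_effect_mean`, `edge_effect_sd` | 1.5, 0.5 | planted |M| values, truncated at 1.1 x log2(1.7) so planted edges always clear the threshold |
| `edge_sign_prob_decrease` | 0.5 | trans effects go either way |
| `false_positive_rate`, `false_negative_rate` | 0, 0 | with both zero, thresholding recovers the planted adjacency cell-for-cell — the identity the recovery tests rely on |
| `fitness_slope`, `fitness_noise_sd` | -0.1, 0.15 | fitness = 1 + slope x log10(K+1) + noise; the noise sd is about twice the signal sd under the default topology, giving the weak (R^2 ~ 0.2) anti-correlation seen in genome-scale deletion fitness data |

Out-degrees are drawn from a truncated discrete power law on 1..`k_max`;
targets are chosen uniformly without assortativity (the paradox strength
depends on assortativity, so the simplest zero-assortativity model is the
right default for testing whether the degree distribution *alone*
suffices). p-values are assigned directly rather than simulated from
replicate noise, because the analysis consumes only the (M, p) pair and
the threshold rule. All generators are bit-reproducible from `spec$seed`
(degrees/targets, expression and fitness use seed, seed+1, seed+2).

What the generator does **not** emulate: correlated expression changes
(each cell is independent), media conditions, aneuploidy artifacts, the
slow-growth transcriptional signature, or in/out-degree correlation.
Passing tests therefore show that the *algorithms* behave as specified
under the stated statistical structure, not that real compendia satisfy
that structure. The slow-growth re-analysis is supported by pointing the
pipeline at an already-transformed expression file
(`transformed_expression`); computing such a transform is out of scope.

## Numerical and degenerate-input conventions

* Missing M or p never produces a significance call; missing coordinates
  contribute nothing to Euclidean sums. Counts of dropped entries are
  logged rather than silently absorbed.
* p-values are used exactly as stored (they are already FDR-adjusted
  upstream); no re-adjustment.
* File round-trips are exact to 1e-9 (values written at 17 significant
  digits).
* Zero-variance difference vectors are rejected with a pointer to
  sign/permutation alternatives rather than returning an undefined t.
* The exhaustive 4+4 relabelling oracle for the Welch test uses the mid-p
  tie convention, since the permutation distribution is discrete with many
  relabellings tied exactly at the observed difference.
* Degenerate permutation inputs (all-ones matrices, single cells) are
  fixed points of both schemes; empty compendia round-trip as
  header-only files.

## Problem sizes

The test suite runs the full stack at 2000 genes x 600 deletions for the
recovery, paradox and permutation checks (20 replicates per scheme),
200 random networks of up to 100 nodes against brute-force set-algebra
oracles, 1e5 draws for exponent recovery, and n = 1300 for the fitness
r-squared recovery — all seeded, completing in well under two minutes on
one core. `scripts/acceptance.R` re-runs the same pipeline end to end at
the default conditions from a single `--seed`.

## Known limitations

* Trans-regulators are perturbation effects, direct or indirect; no
  attempt is made to infer direct regulation.
* The per-pair cis-greater proportion depends on the in/out-degree joint
  structure of the network; the zero-assortativity generator reproduces
  the qualitative paradox but not any particular empirical percentage.
* The log-log least-squares exponent is biased on small sparse networks
  (see above); it is reported for parity with the estimator under study,
  not as a recommended power-law test.
* Only the two row/column shuffle null models are implemented; no
  Maslov-Sneppen edge swaps.
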