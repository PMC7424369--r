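---
title: "Relative expression orderings and confounding factors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative expression orderings and confounding factors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopair)
```

## The problem

Within a single transcriptome sample, the *relative expression ordering*
(REO) of two genes A and B is the qualitative relation A > B or A < B between
their measured expression values. REOs are remarkably stable across
individuals within a normal tissue type, and because they are rank
statistics they are invariant under any strictly monotone transform of the
measurement scale — normalisation, log-transformation and much of the
batch-to-batch intensity variation leave them untouched. This makes stable
REOs an attractive normal-tissue reference for calling disease-associated
expression changes when matched normal samples are scarce.

That strategy has a weakness: if common confounding factors — age, cigarette
smoking, sex, race — themselves perturb the orderings, a reference built
from one population will misfire on another. `reopair` implements the
analysis pipeline that quantifies such perturbations: stable-pair detection
per sample group, reversal-ratio comparison between groups, a
RankCompV2-style differential-expression caller driven by ordering
disruption, per-pair age association, categorical balance checks and
hypergeometric pathway enrichment. A synthetic-data generator with planted
ground truth makes every stage testable offline.

## The stability test

For a gene pair in a group of samples, let `n` be the number of
*informative* samples (the two values differ) and `k` the number supporting
the majority direction. Under the null that each sample independently shows
either ordering with probability `p0 = 0.5`, the stability p-value is the
one-tailed upper binomial tail

$$p = 1 - \sum_{i=0}^{k-1} \binom{n}{i} p_0^i (1 - p_0)^{n-i}
    = P(X \ge k), \quad X \sim \mathrm{Bin}(n, p_0).$$

Design choices worth stating:

* **Ties are excluded from `n`.** A sample with exactly equal values
  supports neither direction; dropping it keeps the Bernoulli model honest.
  Pairs with `n = 0` are untestable, but still count in the multiple-testing
  family (below).
* **The test is one-tailed with `k` the majority count**, exactly as the
  tail sum above is written. No two-sided doubling is applied.
* **Numerics.** The tail is evaluated through the binomial survival
  function, stable for `n` well beyond 10^4; the two boundary cases are
  patched with their exact closed forms (`k = 0` gives 1, `k = n` gives
  `p0^n`) so that degenerate pairs carry exactly representable p-values.

Benjamini–Hochberg correction is applied across **all** C(G, 2) pairs, not
only the informative ones — the family is the full pair space. Because the
p-value depends only on `(k, n)`, `stable_pairs()` adjusts over the multiset
of distinct `(k, n)` values weighted by their pair counts and maps the
result back; this is algebraically identical to naive BH on the full
p-vector (the test suite checks bit-level agreement) while touching each
pair only twice. Pair enumeration itself proceeds in fixed-size blocks
(default 10^6 pairs) so that peak memory is proportional to the block, not
to the pair count; the canonical pair orientation is `gene_a < gene_b` in
lexicographic order, which makes set intersection between groups
well-defined and tie-free.

## Reversal ratio

Two groups' stable-pair sets are intersected by pair identity: of the `m`
common pairs, `k` with opposite majority directions are *reversal* pairs and
the rest *concordant*. The reversal ratio `k/m` is the headline measure of
how strongly a factor perturbs the ordering structure. An empty intersection
yields an explicit undefined marker (`NA`), not an error. At the scale of
whole microarray transcriptomes the pair space runs to ~2×10^8 pairs; the
pipeline is exercised here at hundreds of genes, where correctness can be
established exhaustively, and `run_reo_pipeline(gene_cap = )` provides a
deterministic top-variance reduction for desk-scale runs of larger
matrices.

## RankCompV2-style DEG calling

A gene that shifts expression between groups drags its orderings with it:
among its common stable partner genes, the split into "partners below the
gene" versus "partners above" changes. For each gene we form the 2×2 table
of that split in group 1 versus group 2 and apply the two-sided Fisher exact
test, BH-adjusted across all genes with at least one partner. Since a
strongly shifted gene also contaminates the tables of every gene it pairs
with, the procedure iterates: genes flagged in one round are removed from
all partner sets, counts are rebuilt and the remaining genes re-tested,
until the flagged set reaches a fixed point (or `max_iter`, default 10, is
hit — non-convergence is reported, never hidden). Flagged genes are called
up- or downregulated in group 2 according to whether their
"partners-below" fraction rose or fell; a gene with equal fractions is never
flagged (no directional evidence).

Two interpretation decisions were open and are resolved as follows. The BH
family at each iteration is the set of genes with at least one remaining
partner — genes with no partners are untestable and keep no nominal
p-value. And p-values are re-adjusted *within each iteration* rather than
once at the end: each round is a complete test of a reduced background, and
flagging decisions must be comparable across rounds. Both choices are
internal to the iteration and do not change the fixed-point property, which
the suite verifies directly.

## Covariates

**Age.** For each pair, samples with known age are split by their REO
direction and the two age distributions compared with a two-sided
Mann–Whitney U test; BH correction runs across tested pairs. Sides smaller
than `min_group` (default 5) make the test powerless and only inflate the
multiplicity, so such pairs are skipped and excluded from the family; the
threshold is configurable. The exact U distribution is used when both sides
have at most 25 samples and the ages carry no ties; otherwise the normal
approximation with tie and continuity correction applies. A degenerate
comparison (all ages equal) carries no evidence and reports p = 1. Ages are
compared on their observed scale; the result is invariant under affine age
transforms and monotone expression transforms, which the suite asserts.

**Categorical balance.** `balance_test()` cross-tabulates two binary factors
after dropping explicit `"unknown"` levels and applies the Fisher exact
test. Missing metadata is encoded as `"unknown"` at load time and never
dropped silently — filtering is visible, per analysis.

## Enrichment

Up- and downregulated DEG lists are tested separately for
over-representation in each gene set by the upper-tail hypergeometric
probability P(X ≥ x) (the observed overlap included, the standard
convention), with BH across sets. The universe is always explicit — default
practice is all genes present in the expression matrix after probe
collapsing — because the p-values depend strongly on it. Sets with fewer
than two universe genes are skipped and excluded from the family.

## The synthetic generator

`simulate_reo_data()` emulates exactly the statistical structure the
analysis assumes, nothing more:

* **Template.** Genes receive a latent rank order; baseline levels are
  geometrically spaced (`log mu` steps of `log_spacing`, default 0.05).
* **Noise.** Samples are `mu_g exp(eps)` with `eps ~ N(0, noise_sigma^2)`,
  default `noise_sigma = 0.1`. Because REOs are monotone-invariant, the only
  property of the noise model that matters is the probability that two
  genes' order flips, which depends on their rank distance alone: adjacent
  ranks flip in roughly a third of samples, ranks five apart in ~4% and
  ranks thirty apart essentially never. This single tunable flip scale is
  why log-normal noise on a geometric template was chosen.
* **Planted DEGs.** In group 2, `n_deg` genes are re-positioned at least
  `rank_shift` ranks away (up or down per `deg_split`), realized
  displacements recorded. The ground truth includes the exhaustive
  reversal-pair count between the two noiseless templates, so the measured
  reversal ratio has an oracle.
* **Confounders** are drawn independently of expression unless a scenario
  couples them; ages are uniform over `age_range`. This lets both null and
  alternative behaviour of the balance and age tests be validated.

The bundled `reo_scenarios()` mirror the magnitudes of the factor analyses
this pipeline is aimed at: `smoking_like` (200 genes, 20+20 samples, 10
planted DEGs shifted ≥ 30 ranks — a factor with many DEGs), `sex_like`
(4 DEGs tagged with sex-chromosome cytobands), `race_like` (2 DEGs) and
`age_null` (100 genes, 30+30 samples, no effect; ages independent of
expression). The problem sizes are deliberately desk-scale: at 200 genes the
pair space (19,900 pairs) is small enough that every fast path can be
validated against exhaustive enumeration, while the planted rank shifts are
large enough that recovery is expected to be essentially complete —
the suite requires sensitivity and precision ≥ 0.9 on `smoking_like`.

What the generator does **not** emulate: probe-level artefacts,
platform-specific intensity distributions, correlated noise across genes,
batch effects, or DEGs that change variance rather than location. Passing
tests on synthetic data therefore demonstrate the *algorithmic* correctness
of the pipeline and its statistical calibration under the stated model, not
robustness to every failure mode of real microarray data.

## Degenerate inputs and tie-breaks

* Duplicate gene or sample identifiers, missing or non-numeric expression
  cells: load errors naming the offender, never silent repair.
* Probes mapping to zero or multiple genes are discarded at collapse time;
  multiple surviving probes of one gene average arithmetically.
* Gene identifiers are opaque strings; every ordering in the package
  (pair orientation, output sorting) is lexicographic, making all results
  deterministic given the inputs.
* Enrichment output sorts by p-value with set name as tie-break.
* All randomness flows from a single seed; simulations are byte-identical
  under the same seed, and the seed travels in the config echo of every
  written run.

## Limitations

The DEG caller is a faithful reimplementation of the published procedure's
description — partner-direction contingency tables over common stable pairs
with iterative background filtering — not a bit-exact clone of any
particular implementation of it; undocumented details (per-iteration
adjustment, the partner-count family) are resolved as described above.
Individual-sample DEG calling against a fixed normal reference (the
ancestor of this population-level method) is out of scope, as are GEO
retrieval, array normalisation and pathway-topology methods.
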