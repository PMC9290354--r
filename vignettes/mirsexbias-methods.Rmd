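---
title: "Methods: comparing sex-biased microRNA expression and chromosomal location between two Drosophila species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-biased microRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsexbias)
```

## The scientific problem

In *Drosophila*, male-biased protein-coding genes are depleted from the X
chromosome — the classic "demasculinization" pattern — while male-biased
microRNAs are, if anything, enriched on the X. A sharp way to probe this
contrast is a species pair in which an ancestral autosome fused to the X:
in *D. pseudoobscura*, Muller element D became the right arm of the X
(the neo-X) roughly 13 Ma. If demasculinization acted on microRNAs, genes
on the neo-X should have moved off it or lost male bias; if not,
sex-biased expression and chromosomal location should simply be
conserved.

`mirsexbias` implements the complete comparative analysis this question
requires, as reusable, tested functions:

1. sex-bias calling from small-RNA count tables under a batch + sex
   model (`run_dge()`);
2. cross-species homology-group inference from sequence similarity
   (`find_hits()`, `build_groups()`) with neighbor-joining trees on
   uncorrected distances for inspection (`neighbor_joining()`);
3. collapsing of clustered microRNAs (10-kb rule) to their
   highest-expressed representative (`call_clusters()`,
   `collapse_clusters()`);
4. Muller-element translocation detection between species
   (`detect_translocations()`);
5. rank-based two-factor testing of expression bias by evolutionary age
   and chromosomal context (`scheirer_ray_hare()`).

Because the sequencing data behind such a study are large and external,
the package pairs every stage with a seeded synthetic-data generator
(`simulation_config()` and friends) that plants known effects, so the
whole pipeline is testable end to end, offline.

## Differential expression model

Counts are normalized with median-of-ratios size factors (the classic
count-data estimator; `median_of_ratios()`), or alternatively TMM
(`tmm_factors()`, via edgeR, converted to the same size-factor
convention with geometric mean one). The expression filter keeps a locus
only if it has at least one read in at least one sample of *each* sex
and a base mean (mean normalized count, always computed with
median-of-ratios factors) of at least one.

Instead of stacking two external model families, the package fits one
transparent stand-in for both: ordinary least squares on
`log2(normalized count + 0.5)` with intercept, batch indicators (paired
design) and a sex indicator. The reported `log2fc` is the sex
coefficient, male minus female, so positive values are male-biased.
Residual variances are then moderated with an empirical-Bayes scaled
inverse chi-square prior whose parameters `(d0, s0^2)` come from a
method-of-moments fit on the log variances, and the moderated t is
referred to `d0 + df` degrees of freedom. In the `d0 = 0` limit this is
the ordinary t test; at `d0 = Inf` every locus uses the pooled prior
variance. This is justified by the observation that fold-change
estimates agree closely across reasonable model families on such data
(the package tests require correlation above 0.95 with a naive
normalized-mean estimator), and recovery of planted effects — not
emulation of any specific external tool — is the acceptance standard.

A locus is called sex-biased at FDR 10% (Benjamini–Hochberg,
`bh_adjust()`) with an expression difference of at least 25%
(`|log2fc| >= log2(1.25)`, boundary inclusive). Both thresholds are
arguments.

Choices worth noting:

* **Pseudocount 0.5** before the log; the smallest standard choice. Its
  bias on log2 fold-changes is below 0.05 at mean counts of 100 or
  more, which the tests verify on noise-free input.
* **"FDR" = Benjamini–Hochberg.** The step-up estimator is implemented
  directly and cross-checked against `p.adjust`.
* **Raw, unshrunken fold-changes** feed the 25% rule and all downstream
  comparative analyses.
* **Unpaired design** simply drops the batch term, for datasets whose
  samples share no batches.
* **Variance floor** `1e-8` guards degenerate all-zero-variance input.

## Homology inference

Hairpin sequences of the two species are compared all-vs-all with a
seeded Smith–Waterman local alignment (affine gaps; defaults match +1,
mismatch −2, gap open −5, gap extend −2, a conservative BLASTN-like
scheme; a gap of length L costs `open + L * extend`). Seeding mirrors a
word-size-10 nucleotide BLAST: a pair is aligned only if it shares an
exact 10-mer. Because the extension is the exact dynamic program over
the full pair, the seeded score can never exceed the exhaustive score
and equals it whenever any seed exists — the property the test suite
checks against the full DP on hundreds of random and mutated pairs.

E-values use the ungapped Karlin–Altschul form `E = K m n e^{-lambda S}`
applied to the gapped scores. `lambda` is solved numerically from the
scoring scheme under uniform base composition. `K` has no closed form
for gapped scores, so it is calibrated once per scheme by fitting the
Gumbel location of optimal local scores of random sequence pairs
(deterministic internal seed, cached); since true homolog scores sit
far above threshold and the package's null tests bound the false-hit
rate directly, the approximation's residual error is immaterial in
practice, and the thresholds are configurable in any case. Pairing uses
`E <= 0.1`; genome-scan mode uses `E <= 0.01` and additionally requires
alignment length ≥ 60.

Hits become edges of an undirected graph over all loci of both species;
connected components are the similarity (potential homology) groups,
classified one-to-one / one-to-many / many-to-many / unpaired from
per-species member counts. Edges are *inclusive* (every hit above
threshold), not reciprocal-best-only; with inclusive edges, chance
word matches occasionally merge true one-to-one pairs into larger
groups — such pairs then simply drop out of the one-to-one analyses, a
conservative behaviour the pipeline tests assert (no translocation is
ever invented). Manually curated ortholog pairs can be injected as
extra edges via `pipeline_config(ortholog_overrides = ...)`, mirroring
how curated but sequence-divergent ortholog assignments are usually
kept for consistency.

For each multi-member group, pairwise global alignments
(Needleman–Wunsch, same scoring family) give uncorrected p-distances
(mismatches over gap-free columns; `N` columns count as mismatches
since `N` matches nothing), and a classic neighbor-joining tree is
built. Ties in the Q-matrix argmin break by label order; negative
branch lengths are clamped to zero and flagged. Newick output is
canonical: children sort by their smallest leaf label, so identical
trees serialize identically.

## Clusters, translocations, and cross-species comparison

Clustered microRNAs tend to share a transcript, so their expression is
not independent. Loci on one chromosome merge into a cluster by single
linkage with a boundary-gap rule: the gap between two intervals is
`max(0, next_start − prev_end − 1)` and gaps up to 10 000 bp
(inclusive — the most permissive reading of "within 10 kb") merge. Each
cluster is represented by its highest-base-mean member, ties broken by
lexicographically smallest ID for determinism.

Interchromosomal movement is judged on Muller element *letters*
(element labels like `A (XL)` and `a` normalize to `A`), which makes
the test robust to arm naming across species. Pairs with an unknown
element on either side are excluded and counted separately. The package
ships two curated tables of predicted, newly discovered
*D. pseudoobscura* orthologs (26 one-to-one pairs, of which exactly one
— dme-mir-2281 — is on different elements, an autosome-to-autosome
case; and two microRNAs with two copies each, all on concordant
elements) both as worked examples and as exact regression anchors.

For expression conservation, one-to-one groups whose members pass the
expression filter in both species are paired by their log2
fold-changes, stratified by the species-2 chromosomal context (ancestral
X = element A, neo-X = element D, otherwise autosome) and age class,
and summarized with ordinary least-squares fits per stratum
(`linear_fit()`).

## The rank test

The Scheirer–Ray–Hare test extends Kruskal–Wallis to factorial designs:
all values are jointly mid-ranked and a two-way ANOVA is computed on the
ranks; each effect's statistic is `H = SS_effect / MS_total` with
`MS_total = SS_total / (N − 1)`, referred to a chi-square distribution.
Implementation decisions:

* **Type II sums of squares** via model comparisons (`RSS(~B) −
  RSS(~A+B)` and so on), the standard choice for the unbalanced tables
  this analysis produces (few X-linked novel loci). Consequently the
  type II SS need not add up to `SS_total`.
* **Ties** are carried by the mid-ranks; computing `MS_total` from the
  realized rank variance makes the tie correction implicit. In the
  one-factor limit (`factor_b = NULL`) the statistic equals the
  tie-corrected Kruskal–Wallis H *exactly*, which the tests assert to
  1e-10, alongside a brute-force cell-mean decomposition on balanced
  designs.
* **Interaction** is computed and reported by default (the two-factor
  question "does the age effect differ by chromosome" is real); a
  main-effects-only mode (`interaction = FALSE`) is available. Empty
  cells drop the interaction with a warning; a constant factor is an
  error that points to `kruskal_wallis()`.
* Degenerate all-equal input yields `H = 0`, `p = 1` for every term.

Null calibration over 10 000 replicates of exchangeable values in a
balanced 2×2 lands the rejection rate at `alpha = 0.05` close to
nominal (about 0.05), as the acceptance checks require.

## The synthetic study and what it does (not) show

`simulation_config()` encodes the emulated study: two species sharing
six Muller elements (species 1 with the ancestral X = A; species 2 with
X = A plus a neo-X = D), ~120 hairpin loci of 60–150 nt, a quarter of
them species-2-specific ("novel"), loci arranged in clusters that obey
the 10-kb rule with intercluster gaps of 50 kb, ortholog pairs derived
from a common ancestor sequence at 5% substitutions per site per
lineage, and negative-binomial counts (`var = mu + mu^2 * dispersion`,
global dispersion 0.1) for two replicates per sex in a paired layout —
one male and one female per sequencing batch, batches after the first
shifted by 0.5 log2 units, per-sample library-size factors drawn
log-uniformly in [0.5, 2] to exercise normalization.

Planted effects follow the biology the analysis is designed to detect:
conserved ortholog pairs share a true sex effect drawn with spread 1.0
log2 units (real microRNA sex biases span several log2 units; sharing
the value across species is what makes cross-species conservation
estimable); novel loci carry a general male bias of 1.0 log2 units,
and novel loci on X-linked elements the stronger default of 1.5 —
i.e., an age effect plus an age-by-chromosome boost, which is the
qualitative structure the rank test is meant to resolve. A gonad mode
relabels samples testis/ovary with the same effects.

Where a value had to be invented (the real study does not publish its
dispersions or library-size ranges), it is a config field with the
default stated above, chosen once for realism, not tuned.

All randomness flows from the config seed; stage-specific seeds are
derived from it with fixed offsets, so identical configs give
byte-identical annotations, sequences, counts — and, through
`run_pipeline()`, byte-identical output directories, which the tests
verify file by file.

What passing these tests shows: the estimators are unbiased under the
model, calibrated under the null, and exactly faithful to their
combinatorial/algebraic definitions. What it does not show: robustness
to gene-wise dispersion variation (the generator uses a single global
dispersion precisely to keep recovery interpretable), to expression
correlation within clusters beyond cluster membership, to non-uniform
base composition or secondary-structure constraints on hairpins, or to
the read-level artifacts (mapping, adapter trimming, multimapping) that
the package deliberately consumes as upstream-resolved count tables.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately modest
sizes — 500 alignment pairs up to 120 nt, 100 random graphs, 10 000
rank-test replicates, ten 500-locus null simulations (~5 000
locus-tests), ten 200-locus recovery simulations — chosen so the whole
suite runs in a few minutes on one core while keeping Monte-Carlo error
well inside the asserted bands. Tolerances: algebraic identities at
1e-10 or tighter; calibration bands [0.03, 0.07] (DGE type I) and
[0.035, 0.065] (rank test) at nominal 0.05; recovery of a planted
log2FC of 2 within ±0.3 for at least 90% of affected loci under small
dispersion.

## Known limitations

* E-values are approximate (ungapped theory on gapped scores with a
  calibrated `K`); thresholds, not E-value precision, drive decisions.
* Full BLAST statistics, progressive multiple alignment, bootstrap
  supports, and gene-wise NB dispersion estimation are out of scope.
* Within-chromosome rearrangements (inversions, local translocations)
  are not detected — only element-level movement is.
* The homology graph's inclusive edges favour sensitivity of group
  discovery over purity of one-to-one calls; reciprocal-best filtering
  can be emulated by pre-filtering the hit table before
  `build_groups()`.
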