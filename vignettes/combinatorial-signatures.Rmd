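---
title: "Combinatorial disease signatures: model, search and validation"
author: "combsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial disease signatures: model, search and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide single-SNP association tests miss genetic effects that only
materialise when particular genotypes co-occur in the same person. In
complex, heterogeneous conditions — post-viral syndromes such as long COVID
or ME/CFS are the motivating examples — individual variants typically show
odds ratios barely above 1 and fail genome-wide significance, while small
*combinations* of exact genotype states can mark patient subgroups with
many-fold elevated disease odds. `combsig` implements the full analysis
chain for this setting: QC of a genotype matrix, symptom-score-based
case/control cohort construction, layered combinatorial mining with
permutation-based false-discovery control, disease-architecture networks,
Random-Forest scoring of critical SNPs, cascade SNP-to-gene mapping,
Expanded Genotypes Analysis (EGA) of causality patterns, ancestry-confounder
screening, phenotype enrichment, and a synthetic-data generator that plants
known epistatic signatures so that every stage can be verified end to end.

## Data model

A **feature** is one exact genotype state at one SNP, written `snp:state`
with the state the count of minor alleles (0, 1, 2). A **disease signature**
of order *k* is a conjunction of *k* features on distinct SNPs; a sample is
a *member* iff it carries exactly those states, and *incomplete* (excluded
from counts) iff any component genotype is missing. Signature effect sizes
are odds ratios **relative to the cohort mean odds**:

$$ \mathrm{OR} \;=\; \frac{a/b}{C/N} $$

where \(a, b\) are member counts among the \(C\) cases and \(N\) controls.
A signature carried by a perfectly representative subgroup therefore has
OR = 1, and membership of *everyone* has OR = 1 by construction. The
association p-value is the two-sided Fisher exact test on
\([[a, C-a], [b, N-b]]\).

### Cohorts from symptom change scores

Each sample's change score is the sum over symptoms of (post − pre)
questionnaire scores, with scales oriented so higher = worse. Cases are
samples at or above the upper quartile of the score distribution; controls
have scores in \([0, \mathrm{median})\); everything else — including net
improvement — is excluded. Quantiles use linear interpolation between order
statistics (R's default type-7 rule); the convention is recorded in the
output since no interpolation rule is canonical for this design. The
fatigue-dominant variant of the cohort uses only the fatigue symptom group.

## The layered search

Mining proceeds in layers of increasing combinatorial order:

1. **Layer 1** evaluates every feature. A candidate must reach
   **case prevalence** ≥ 5% (members among cases / cases). Prevalence is
   anti-monotone under conjunction — adding a feature can only shrink
   membership — so restricting growth to prevalence-passing candidates
   loses nothing (an apriori-style bound).
2. A **beam** of the `beam_width` most associated prevalence-passing
   candidates (smallest Fisher p, ties broken lexicographically by SNP id
   and state) is extended by every feature on a SNP not already in the
   combination. The same set reached through different parents is collapsed
   through an order-independent hash key, so each combination is evaluated
   once per scan.
3. Combinations with p < 0.05 **and** OR > 1 become candidate signatures at
   every layer. Note that candidate *features* are not required to be
   individually significant: interaction-only effects have near-null
   singleton odds ratios, and the filters apply to the combination.

With `beam_width = Inf` and `max_order = 2` the search provably coincides
with exhaustive enumeration of all singletons and pairs, which the test
suite checks against an independent oracle implementation.

## Validation: permutation-calibrated FDR

A search that scans ~10^5 combinations and keeps the nominally significant
ones is an aggressive multiple-testing machine; naive per-candidate
permutation tests are not enough. If a candidate was kept *because* its
observed p was the best of the scan, shuffling labels around that fixed
candidate almost never reproduces so small a p — every selected candidate
looks "significant" against its own permutation null, even on
label-independent data. The selection itself must be repeated under the
null.

`mine_signatures` therefore re-runs the **identical** layered search on
`n_permutations` label-permuted datasets and records the p-values of every
combination the permuted searches discover. For the observed candidates,
sorted \(p_{(1)} \le \dots \le p_{(m)}\), the q-value is the
Benjamini–Hochberg-style step-up

$$ q_{(i)} \;=\; \min_{j \ge i}\;
   \frac{\widehat{E}\,[\#\{\text{null discoveries with } p \le p_{(j)}\}]}
        {j} $$

with the expected null count estimated as the average over permutation
scans. This is BH with the null distribution measured on the procedure
itself rather than assumed uniform. Candidates with q ≤ 0.05 are marked
validated. On null data the observed and permuted scans have the same
distribution, so essentially nothing validates; a planted signature whose p
is far below anything the permuted searches produce gets q ≈ 0. Both
behaviours are asserted in the acceptance tests (20-seed null
false-discovery control and 20-seed planted recovery).

The per-candidate empirical-p formula
\((1 + \#\{p_\text{perm} \le p_\text{obs}\})/(1 + B)\) with BH across
candidates remains available as `permutation_fdr(..., method = "fixed")`;
it is the right tool when the candidate list is specified *independently*
of the data, e.g. when replicating known signatures in a new cohort.

Signatures whose feature sets are nested with identical memberships are
collapsed to the smaller set. At least 19 permutations are required (the
empirical-p resolution needed for a 0.05 level); the default is 199.

## Networks and critical SNPs

Validated signatures are merged into a **disease architecture**: nodes are
features; each signature induces a clique weighted by its case count, and
features of different signatures are linked with weight equal to the number
of cases carrying both signatures. Communities come from greedy modularity
maximisation (`igraph::cluster_fast_greedy`), which is deterministic.

SNPs recurring across signatures are scored two ways. A **Random Forest**
(100 trees, default `randomForest` settings otherwise, for determinism and
comparability rather than tuned accuracy) predicts the case–control split
from the SNP's one-hot genotype states — by default together with its
signature partners' states, since the signal is combinatorial — under
stratified five-fold cross-validation. Separately, a **permutation test**
asks whether the number of filter-passing combinations containing the SNP
(within its observed partner feature space, for tractability) exceeds what
label permutations produce. A SNP is called *critical* when the permutation
p is ≤ 0.05 and the RF accuracy beats the majority-class baseline; the
published method names both checks without stating thresholds, so the
conjunction rule is this package's choice.

## Cascade gene mapping

Critical SNPs map to genes in two stages: a SNP inside an annotated CDS
interval maps `coding_direct` to that gene (all genes, when they overlap);
otherwise genes whose strand-aware window — 2 kb upstream of the 5' end or
0.5 kb past the 3' end, boundaries inclusive — contains the SNP compete,
and the SNP maps `proximal` to the nearest by bp distance (ties map to all
tied genes). "Coding region" is read literally as CDS: an intronic SNP
falls through to the proximal rule, where its distance to the containing
gene span is 0. The 10 kb gene-window selection used for seeded analyses is
deliberately strand-agnostic, matching its "up- or downstream" definition.

## Expanded Genotypes Analysis

For a k-SNP signature (k ≤ 3), every complete-genotype sample is assigned
to one of the 3^k **expanded genotype signatures**. Assignments carried by
fewer than 15 patients are excluded. Orders 4–5 are rejected outright: 81
or 243 cells leave too few patients per cell for direction patterns to rise
above noise.

For a chosen critical SNP, assignments sharing the interacting SNPs' states
form a block; the **EGA odds ratio** divides the disease odds at critical
state 1 (or 2 — computed as separate blocks) by the odds at critical state
0, with a Woolf 95% interval on the log odds ratio. Zero cells make a block
incomplete — no continuity correction is applied, so printed block tables
stay reproducible exactly.

The seven published causality categories are formalised here from their
prose descriptions (the original operational definitions are not public;
these rules are this package's formalisation, not the original platform's):

* **universal**: every complete block shares one direction (OR vs 1; OR = 1
  is consistent with either direction).
* **SNP-specific**: the blocks where at least one interacting SNP carries a
  minor allele agree on a direction, and the all-wild-type block(s) show
  the opposite or are absent; the category takes the direction seen
  alongside interacting minor alleles.
* **combination-specific**: exactly one interacting assignment shows a
  direction and every other complete block opposes it.
* otherwise **ambiguous** (also with fewer than two complete blocks).

Classification is invariant to block order and to relabelling of the
interacting SNPs, and is exercised on planted scenarios (n = 5000) where
the true pattern is known.

## Secondary screens

**Ancestry confounding.** Each signature is retested in a maximum-likelihood
logistic regression `case ~ membership + ancestry` with a binary ancestry
covariate; the Wald p of the membership coefficient is Bonferroni-adjusted
across signatures (as published — despite the name, the published
correction is Bonferroni, with BH available by flag), and signatures with
adjusted p ≥ 0.05 are flagged as confounded false positives. Perfect
separation triggers a Clogg-style penalised refit (half-weight
pseudo-observations of both outcomes per covariate pattern) with a warning.
Each signature is modelled separately.

**Phenotype enrichment** compares signature carriers against the *rest of
the case population*: pooled-variance two-proportion Z for categorical
phenotypes, two-sided Mann–Whitney U (normal approximation, tie-corrected)
for continuous ones, BH across all phenotypes; groups below 5 are flagged
underpowered but reported.

**Seeded mining** restricts the candidate space to combinations containing
at least one feature on a pre-specified seed SNP (from another cohort or a
related disease); FDR calibration runs within the reduced space, which is
what gives replication analyses their power. Seeding every SNP reproduces
the hypothesis-free search exactly.

## The synthetic cohort generator

`simulate_cohort` emulates the study conditions the pipeline targets, with
every default chosen once:

* ~1,300 samples (default `n_samples = 1300`), `n_snps = 2000` at desk
  scale, ancestral MAF uniform on [0.05, 0.5], genotypes in Hardy–Weinberg
  proportions, 1% uniform missingness.
* Optional populations perturb allele frequencies by a Balding–Nichols Beta
  draw with an Fst-like divergence; per-SNP, per-population frequency
  overrides allow deterministic confounding scenarios.
* Disease: baseline odds 0.25 (a ~20% attack rate, matching a cohort where
  roughly a quarter of samples become severe cases), multiplied by the
  `odds_multiplier` of each planted signature the sample carries **in
  full** — interaction-only penetrance, so component SNPs are individually
  near-null, the motif the miner must handle. An `odds_modifier` hook
  supports stratum-dependent effects (used for the EGA scenarios).
* Symptoms: seven symptoms in three groups (respiratory, fatigue, mental
  health) on a 0–10 scale; post = pre + deterioration (mean 3 per symptom
  if diseased, 0.5 otherwise, SD 1.5), rounded and clipped. Diseased
  samples thus concentrate in the top quartile of total change scores,
  exercising the cohort rules.

What the generator does **not** emulate: linkage disequilibrium structure
(SNPs are independent, so planted signatures have no LD proxies), realistic
chromosome maps, genotyping-array artefacts, and symptom scales beyond a
single common range. Passing tests therefore demonstrate the statistical
machinery under clean conditions, not robustness to real-array QC problems.

## Numerical choices and problem sizes

* The inner loop uses an exact two-sided Fisher p computed from a
  precomputed hypergeometric table per (membership, case-count) pair —
  identical to `fisher.test` (unit-tested to 1e-10) but usable ~10^7 times
  per run. Near-ties in tail mass use the same 1e-7 relative tolerance as
  `fisher.test`.
* Zero-cell odds ratios relative to mean odds use a Haldane–Anscombe +0.5
  correction and are flagged; EGA blocks instead report zero-cell sides as
  incomplete, because the published block tables use no correction.
* All randomness (simulation, permutations, CV folds, RF) is governed by
  explicit seeds; mining canonicalises sample and SNP order, so results are
  invariant to input ordering.
* Default `beam_width = 25` and `n_permutations = 199` are the desk-scale
  study conditions used throughout the tests; the acceptance suite runs the
  null false-discovery check at 20 seeds × 199 permutations on 500 SNPs ×
  1,000 samples, and planted recovery at 20 seeds on 500 SNPs × 2,000
  samples with 99 permutations (the recovery decision is driven by the
  expected-null-count estimate, which is insensitive to the permutation
  count at these effect sizes).

## Known limitations

* The beam search is a heuristic above order 2: recovery guarantees exist
  only for effects strong enough to surface a sub-combination in the beam.
* The permutation-calibrated FDR controls the false discovery proportion of
  the *procedure as configured*; changing filters between observed and
  permuted runs would void it (the implementation shares one code path).
* EGA classification with noisy small blocks degrades to `ambiguous`
  honestly but cannot distinguish a weak universal effect from a
  combination-specific one at small n.
* The ancestry screen uses a single binary covariate, as published; it is
  not a substitute for principal-component or mixed-model structure
  correction.
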