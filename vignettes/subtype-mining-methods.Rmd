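---
title: "Methods: co-mutation mining and genetic subtyping of R/R DLBCL cohorts"
author: "lymphomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-mutation mining and genetic subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphomine)
```

# The problem

Relapsed/refractory diffuse large B-cell lymphoma (R/R DLBCL) is genetically
heterogeneous, and published whole-exome cohorts of this population are small
and scattered across studies with incompatible mutation-type vocabularies.
`lymphomine` implements a desk-scale analysis chain for such data: harmonize
multi-study somatic calls into one patients-by-genes presence/absence matrix,
mine the co-mutation structure, cluster genes into mutation "Types", assign
each patient a rule-based genetic subtype, and compare therapy response and
overall survival across subtypes. A synthetic-cohort generator with planted
structure makes every stage testable without access to patient data.

# Harmonization model

Calls from different studies are reduced to `(patient, gene, mutation type,
cohort)` tuples. Mutation types map onto a closed six-label vocabulary
(truncating SNV, splice-site SNV, missense SNV, indel, synonymous SNV,
multiple types) through a shipped, editable synonym table; a patient carrying
more than one distinct type in a gene is logged as "multiple types" but sets
a single presence bit. Gene symbols are uppercased and de-aliased against a
small static table keyed to GRCh37-era symbols — deliberately offline, so
results do not depend on a live annotation service.

Two per-gene exclusion filters guard against cross-study artifacts:

* **Concordance filter.** Patients are split into two groups of similar
  scale (by default the largest contributing study versus the rest). A gene
  whose mutation frequency differs between the groups at a two-sided Fisher
  exact p below `alpha = 0.001` is excluded — frequency differences of that
  size between studies of the same disease are more plausibly platform or
  calling artifacts than biology. The two-sided p is the probability-mass
  definition (sum of hypergeometric table probabilities not exceeding the
  observed table's), which differs from doubling the one-sided tail on
  asymmetric tables; we use it because it is the convention of the standard
  R implementation and is exactly reproducible by enumeration.
* **Frequency filter.** A gene must be mutated in at least `min_freq = 0.03`
  of patients in *both* the whole cohort and the larger group. The
  proportion is per patient, not per call.

Both filters are per-gene predicates, so their order is irrelevant; the
suite asserts this. Synonymous calls set the presence bit by default (the
vocabulary retains them); `excludeSynonymous = TRUE` drops them.

# Association mining

The binary matrix is treated as a transaction database: patients are
transactions, mutated genes are items. Frequent itemsets are mined with the
apriori algorithm — level-wise candidate generation with the
downward-closure prune — and rules `antecedent set -> single consequent` are
scored by

* support: fraction of patients carrying all genes of the rule,
* confidence: support of the rule over support of the antecedent,
* lift: confidence over the consequent's support; lift 1 is in-sample
  independence, lift > 1 co-mutation, lift < 1 avoidance.

Defaults are `min_support = 0.03` (mirroring the harmonization frequency
floor), `min_confidence = 0.1`, antecedents of at most two genes. These keep
the rule list near the scale where the top-300-by-lift rule graph is
readable; all three are exposed. Lift is computed in-sample with no
continuity correction, and a never-co-occurring pair has lift 0 rather than
undefined. Top-k selection breaks ties deterministically (higher support,
then the lexicographic rule string) so exported graphs are reproducible.
The correctness anchor is exhaustive: on matrices of up to 12 genes the
mined itemsets and rules are compared with enumeration of all 2^G − 1
itemsets.

# Gene clustering

Patients are clustered with k-means (Lloyd, squared Euclidean on the 0/1
rows, best of 25 seeded restarts; `stats::kmeans` supplies the algorithm)
and the per-cluster gene frequency table is reported. Cluster numbers are
canonicalized by decreasing size, then lexicographic first member, so labels
are seed-stable.

For gene-level structure, each non-anchor gene is represented by its
pairwise lift against four anchor genes — SOCS1, KMT2D, TP53, MYD88, the
high-frequency representatives of the four recurrent mutation groups — and
these four-dimensional profiles are clustered on a self-organizing map. The
SOM is a 4 × 4 rectangular grid (16 units; configurable) trained online: per
step the best-matching unit (minimum Euclidean distance, ties to the lowest
unit index) and its grid neighbourhood are pulled towards the input with
Gaussian distance weighting. Training uses the conventional two phases: an
ordering phase (first 20% of steps, radius shrinking linearly from half the
larger grid dimension, learning rate from 0.5 to 0.05) and a fine-tuning
phase (BMU-only updates under a linearly vanishing rate). Default 200
epochs. Map quality is the mean distance of inputs to their BMUs. Lift
vectors enter raw by default — their scale *is* the signal — with a z-score
switch for cohorts where anchor marginals differ wildly. Unit-to-Type
merging is an explicit user-supplied map (disjoint unit sets, unlisted units
stay unassigned), because naming biological Types is an interpretive step we
do not automate.

Grid topology (rectangular), epoch count and schedule are package decisions;
the procedure's validity is established by recovery properties — planted
co-mutation blocks must land on distinct units and training must not degrade
map quality relative to initialization — rather than by reproducing any
particular published unit layout, which depends on unpublished
hyperparameters and data.

# The five-subtype classifier

Patients are labelled by explicit grouping rules on normalized gene symbols:

| group | rule (basic) |
|---|---|
| JAK-STAT related | SOCS1 or STAT6 (extended mode adds ITPKB, GNA13, CIITA) |
| BCL2-CREBBP | BCL2 or CREBBP |
| MCD | MYD88 or CD79B |
| TP53 | TP53 |

Membership is multi-label — the groups genuinely overlap, and group sizes
may sum to more than the cohort. A single primary label is resolved by the
precedence JAK-STAT > BCL2-CREBBP > MCD > TP53-independent; a TP53-mutant
patient is "TP53-independent" only when no named group claims them, and
patients held by no rule are the sparse (undefined) group. The "SOCS1,
STAT6" rule is read as OR, consistent with the or-phrasing of the other
groups; a `combine = "all"` switch implements the conjunctive reading.
Assignment is monotone (adding mutations never removes a label), which the
suite checks by property.

# Clinical statistics

Response tables report complete-response rates per group and therapy line
(induction, salvage, CAR-T), excluding untreated patients from
denominators. Each group is tested against all other patients pooled —
group-versus-rest 2 × 2 tables under Pearson chi-square without continuity
correction, with an automatic fall back to the exact Fisher test when an
expected count drops below 5. Percentages are printed
rounded-half-away-from-zero to one decimal, but all tests consume the exact
fractions. Survival comparisons are likewise subtype-versus-rest: a standard
two-group log-rank test per group (via `survival::survdiff`) plus
Kaplan-Meier step coordinates for plotting. Expression-level screening
dichotomizes a cohort at a gene's mean expression (ties go to the low
group), applies the log-rank test, and multivariate prognostic value is
assessed with a Cox proportional-hazards fit (Efron ties, Wald intervals,
likelihood-ratio global p). The high/low indicator is the default Cox
encoding, matching the mean-cutoff screen; continuous expression is the
caller's option. No multiple-testing correction is applied by default —
the reported thresholds are raw — and Benjamini-Hochberg can be applied
downstream by the user.

# The synthetic-cohort generator

`defaultCohortConfig()` fixes the study conditions the suite runs under: 96
patients, about 250 gene columns, five latent subtypes drawn once per
patient with weights (JAK-STAT 0.12, BCL2-CREBBP/EZB 0.23, MCD 0.25, TP53
0.14, sparse 0.26 — chosen to echo the published composition of a 96-patient
targeted cohort). Each subtype plants a co-mutation block
(SOCS1/STAT6/ITPKB/CIITA/GNA13/B2M/ACTB; KMT2D/CREBBP/BCL2/EZH2/TNFRSF14;
MYD88/CD79B/PIM1/PRDM1; TP53) whose genes fire with probability 0.7 in
carriers — 0.9 for TP53, whose group is defined by the single gene — against
a 0.02 background elsewhere, so block membership is recoverable but noisy.
TTN (0.37), IGLL5 (0.27) and DMD (0.15) are high-frequency independent
background genes, and 230 filler genes at 0.03–0.12 complete the panel.
Mutation-type labels are drawn uniformly over the five elementary canonical
labels, because every downstream analysis binarizes them. Complete-response
probabilities follow the printed operating points where stated (JAK-STAT
induction 0, TP53 CAR-T 0.214, sparse CAR-T 0.55) and field-plausible values
where not (induction 0.30–0.40 elsewhere, salvage 0.10–0.20, CAR-T about
0.40). Overall survival is exponential per subtype (hazards 0.03–0.08 per
month — medians of roughly 9–23 months, with TP53 worst and sparse best)
under exponential censoring at rate 0.02 capped at 60 months.

The generator is single-membership in its latent subtype even though the
classifier is multi-label: observed overlap arises naturally from background
mutations, which is the simplest generative story that still produces
overlapping groups. What the generator does **not** emulate: mutual
exclusivity beyond block structure, allele fractions or read-level data,
panel-specific coverage gaps, non-exponential survival, and correlated
treatment assignment. Passing recovery tests therefore demonstrates the
pipeline recovers planted first-order co-occurrence and outcome structure —
not that it would reproduce any particular real cohort's full joint
distribution.

The fixture builder is the deterministic complement: given printed marginal
and pairwise counts it constructs a matrix reproducing them exactly (greedy:
pair overlaps first, then remaining marginals, never disturbing a requested
pair), or raises an infeasibility error. Only marginal plus pairwise
constraints are supported, since published tables print nothing
higher-order.

# Numerical choices and degenerate inputs

* Fisher exact p: hypergeometric mass summation with the `(1 + 1e-7)`
  relative slack standard in R when comparing table probabilities.
* Expression correlation p: t transform of Pearson r with n − 2 degrees of
  freedom; constant genes are an error naming the gene.
* Mean-cutoff dichotomization errors on constant genes and on cuts that
  empty a group.
* Zero-frequency genes are an error in lift computations (lift is undefined
  there), while never-co-occurring pairs give lift 0.
* K-means restarts make empty-cluster pathologies negligible; the canonical
  relabelling removes label arbitrariness from all reported outputs.
* All stochastic entry points take explicit seeds and restore the caller's
  RNG state; the pipeline manifest records seeds, parameters and output
  digests, and identical configs produce byte-identical artifacts.

# Problem sizes used by the validation suite

The suite validates at desk scale, chosen so that exhaustive oracles stay
exact: apriori against full enumeration on up to 12 genes × 40 patients (50
seeded draws), Fisher against enumeration on all 2 × 2 tables with row
margins ≤ 15, recovery properties on 20 default 96-patient cohorts, Cox
calibration on 50 replicates at n = 2000, and log-rank type-I error on 1000
null replicates at 50 + 50.

# Known limitations

* The classifier implements only this rule system, not probabilistic
  classifiers of the LymphGen family; agreement with them is out of scope.
* The concordance filter assumes exactly two comparable study groups;
  finer batch structure is not modelled.
* "CR rate" and "remission rate" are treated as one boolean per therapy
  line; partial responses are not distinguished.
* Expression analyses assume a loaded, normalized matrix; no array or
  RNA-seq preprocessing is provided.

# A worked run

```{r, eval = FALSE}
cfg <- defaultPipelineConfig(outputDir = "lymphomine_demo", seed = 1)
res <- runPipeline(cfg)
res$classified$composition$groups
res$stats$response$cart
```

See the README for the printed output of this run and its interpretation.
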