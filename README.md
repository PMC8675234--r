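# lymphomine

Mutation co-occurrence mining and genetic subtyping for relapsed/refractory
diffuse large B-cell lymphoma (R/R DLBCL) cohorts.

Published exome and targeted-sequencing cohorts of R/R DLBCL are small and
fragmented across studies. `lymphomine` is for analysts who want to pool
such call sets and ask: which genes co-mutate, do the co-mutation groups
reproduce the known genetic subtypes, and do those subtypes differ in
therapy response and survival? The package provides the full chain as
tested, reusable functions:

1. **Harmonize** — map study-specific mutation-type labels onto a closed
   vocabulary, normalize gene symbols, binarize to a patients × genes
   matrix, and drop genes that fail a cross-study concordance test
   (two-sided Fisher exact, p < 0.001 between two study groups) or a 3%
   frequency floor.
2. **Mine** — apriori frequent itemsets and association rules over the
   matrix. For a rule A → B: support = P(A ∧ B), confidence =
   P(A ∧ B)/P(A), lift = confidence / P(B), with lift = 1 meaning in-sample
   independence. A pairwise lift matrix and the top-k-by-lift rule graph
   (GraphML/GEXF) are also produced.
3. **Cluster** — k-means over patients' binary profiles; gene-level SOM
   (4 × 4 grid) on each gene's lift against the anchor genes SOCS1, KMT2D,
   TP53 and MYD88, with explicit merging of units into mutation Types.
4. **Classify** — rule-based five-subtype assignment per patient:
   JAK-STAT (SOCS1/STAT6; extended mode adds ITPKB, GNA13, CIITA),
   BCL2-CREBBP, MCD (MYD88/CD79B), TP53-independent, and sparse
   (undefined), with multi-label membership and precedence-resolved
   primary labels.
5. **Compare** — per-subtype complete-response tables (group vs rest,
   chi-square with exact-Fisher fallback), log-rank survival per subtype vs
   rest, mean-cutoff expression dichotomization, and multivariate Cox
   proportional-hazards fits.

A synthetic-cohort generator (`simulateCohort`, `simulateExpression`) with
planted co-mutation blocks and subtype-linked outcomes, plus a deterministic
fixture builder (`buildFixture`) that reproduces printed marginal/pairwise
contingency counts exactly, make every stage verifiable.

## Worked example

```r
library(lymphomine)
cfg <- defaultPipelineConfig(outputDir = "lymphomine_demo", seed = 1)
res <- runPipeline(cfg)

res$classified$composition$groups
#>        group  n proportion n_gcb n_nongcb
#> 1    JAKSTAT 12  0.1250000     9        3
#> 2 BCL_CREBBP 21  0.2187500    14        7
#> 3        MCD 29  0.3020833     5       24
#> 4       TP53 17  0.1770833     8        9
#> 5     SPARSE 21  0.2187500     3       18

res$stats$response$cart
#>        group treated responders      rate rate_pct  p_vs_rest
#> 1    JAKSTAT       6          2 0.3333333     33.3 0.64837050
#> 2 BCL_CREBBP      14          3 0.2142857     21.4 0.73897175
#> 3        MCD      17          2 0.1176471     11.8 0.18711734
#> 4       TP53      10          2 0.2000000     20.0 1.00000000
#> 5     SPARSE      13          7 0.5384615     53.8 0.02669011
```

This simulates a 96-patient cohort with planted subtype structure,
harmonizes and mines it, and reports composition and CAR-T response. The
groups overlap (a patient may carry both BCL2 and MYD88), so `n` sums past
96; `proportion` is of the whole cohort. In the response table each group is
tested against all other patients pooled: here the sparse group's favourable
CAR-T response (53.8% vs the rest) is the only nominally significant
contrast, matching the planted response probabilities. Every artifact
(rules, lift matrix, rule graph, SOM assignment, KM coordinates, manifest
with digests and seeds) lands in `lymphomine_demo/`.

Single patients can be classified directly:

```r
primaryLabels(assignSubtypes(c("TP53", "CREBBP")))
#> patient1
#> "BCL_CREBBP"     # TP53 yields to the named genetic features
```

A thin CLI over the same functions ships in `inst/scripts/lymphomine.R`
(subcommands `simulate`, `harmonize`, `mine`, `cluster`, `classify`,
`stats`, `run-all`).

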