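# simpheny

Phenotype-first patient matching and candidate gene prioritization for
rare-disease diagnostics.

Most undiagnosed rare-disease patients exit standard variant-first pipelines
with a candidate gene list that is too long to review. `simpheny` turns the
problem around: it compares an undiagnosed *query* patient, described by
phenotype-ontology (HPO-style) terms, against a *reference cohort* of already
diagnosed patients, and asks which of the query's candidate genes are carried
as diagnostic genes by phenotypically similar reference patients. It is aimed
at clinical-genomics analysts who already have per-patient HPO term lists and
Exomiser-style candidate gene lists.

## The method

**Similarity.** For two ontology terms *t₁*, *t₂* with self-inclusive
ancestor sets *A(t)* and information content *IC(t) = −log Tfreq(t)*
(*Tfreq* = fraction of annotated diseases carrying the term or a descendant),

```
PhenoSimJaccard(t1, t2) = Σ IC(A(t1) ∩ A(t2)) / Σ IC(A(t1) ∪ A(t2))
```

an IC-weighted Jaccard index in [0, 1] that rewards sharing *specific*
ancestors. Term-set similarity uses the best-match average (*funSimAvg*):
mean over each set of the best per-term score against the other set,
averaged over both directions.

**Match significance.** A *SimPheny Match* is a (query, reference, gene)
triple where a query candidate gene equals a reference patient's diagnostic
gene. Each match gets two Monte-Carlo empirical p-values
(`p = (1 + #exceedances) / (1 + N)`, N = 10,000 by default):

* *pheno p* — probability that a random phenotype list (drawn
  frequency-weighted without replacement from the reference cohort's
  annotation multiset, capped at 10 terms) scores at least the observed
  similarity against the reference's list;
* *gene p* — probability that a random candidate list of the observed
  length (drawn with replacement from the cohort-wide gene-frequency corpus)
  contains the matched gene at all.

The two are combined with Empirical Brown's Method: `X = −2 ln p₁ − 2 ln p₂`
is referred to a scaled chi-square `c·χ²(f)` whose `c = Var(X)/8`,
`f = 32/Var(X)` come from the empirical covariance of the transformed
p-values in a per-reference-dataset calibration (independence gives Fisher's
`(1, 4)`; perfect dependence gives `(2, 2)`). The **SimPheny Score** is
`−log10(combined p)`, with confidence tiers high (≥ 4.5), medium
([2.5, 4.5)), low (< 2.5). Genes are ranked per query by the **Gene Score**,
the mean of their two best match scores. Benchmarking utilities compute
TPR/FPR/FDR over inclusive score thresholds, ROC/auROC, FDR–TPR curves and
top-k recovery.

A synthetic-data module generates ontologies, annotation corpora and cohorts
with controllable phenotypic signal, so the whole pipeline is testable
without protected patient data.

## Worked example

```r
library(simpheny)

# -- tiny bundled ontology: root, branches A and B, leaves A1, A2, B1, D --
obo   <- system.file("extdata", "toy.obo", package = "simpheny")
ann   <- system.file("extdata", "toy_annotations.tsv", package = "simpheny")
graph <- compute_information_content(read_obo(obo), read_annotations(ann))

pheno_sim_jaccard(graph, "SP:0000004", "SP:0000005")   # A1 vs A2
#> [1] 0.2
fun_sim_avg(graph, "SP:0000004", c("SP:0000004", "SP:0000005"))
#> [1] 0.8
```

`0.2` is `ln 2 / (ln 2 + 2 ln 4)`: the two leaves share only branch A
(IC = ln 2) out of a union holding both leaves (IC = ln 4 each). The
set score `0.8` averages a perfect forward match with a reverse mean of
`(1 + 0.2)/2`.

```r
# -- synthetic cohort: 10 genes, 3 references and 2 queries each ----------
cfg    <- synth_config(seed = 1, n_genes = 10, n_decoy_universe = 20)
onto   <- generate_ontology(cfg)
cohort <- generate_cohort(cfg, onto$graph, onto$corpus)
run    <- run_match(cohort$queries, cohort$references, cohort$graph,
                    cohort$gene_corpus, sim_config(n_simulations = 500, seed = 42))

head(run$matches[, c("query_id", "reference_id", "gene", "pheno_sim",
                     "pheno_p", "gene_p", "simpheny_score", "tier")], 4)
#>        query_id  reference_id    gene pheno_sim     pheno_p    gene_p simpheny_score tier
#> 1 QRY_GENE001_1 REF_GENE001_1 GENE001 0.6250000 0.001996008 0.4451098      1.7845527  low
#> 2 QRY_GENE001_1 REF_GENE001_2 GENE001 0.6375909 0.001996008 0.4291417      1.7949771  low
#> 3 QRY_GENE001_1 REF_GENE001_3 GENE001 0.6250000 0.001996008 0.4271457      1.7963076  low
#> 4 QRY_GENE001_1 REF_GENE006_1 GENE006 0.2446423 0.453093812 0.5289421      0.2713712  low

run$ebm
#> ebm_params [run-calibrated]: c = 1.4154, f = 2.8260, rho = 0.2620 (n = 279)
```

The three matches to the true gene `GENE001` sit at the phenotype-p floor
(`1/501` at 500 simulations): no random phenotype list matched that
reference as well as the query did. Their gene p-values are unremarkable
(~0.44 — `GENE001` is common in the candidate corpus), and the calibrated
dependence (`c = 1.42` vs Fisher's 1) correctly deflates the combined
evidence. Ranking and benchmarking:

```r
subset(run$rankings, query_id == "QRY_GENE001_1")[1:3, ]
#>        query_id rank    gene gene_score n_matches
#> 1 QRY_GENE001_1    1 GENE001  1.7956424         3
#> 2 QRY_GENE001_1    2 GENE006  0.1780217         3
#> 3 QRY_GENE001_1    3 GENE009  0.1223776         3

bench <- run_benchmark(run, cohort$truth)
bench$roc$auroc
#> [1] 0.9936834
bench$topk
#>  1  5 10
#>  1  1  1
```

Every query's causal gene ranks first, and true matches outscore false ones
with auROC 0.99 at these generator settings.

A command-line front end wrapping the same functions (subcommands
`match`, `calibrate-ebm`, `benchmark`, `simulate`) ships at
`inst/cli/simpheny.R`.

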