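---
title: "Phenotype-first matching: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-first matching: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpheny)
```

This vignette is the package's own account of its statistical machinery: the
similarity model, the Monte-Carlo nulls, the dependent p-value combination,
and the design choices made where several reasonable options existed. The
README shows the user-facing workflow; here we explain *why* the pieces look
the way they do.

## 1. Ontology model and information content

Phenotype terms form a rooted directed acyclic graph; a term's *ancestor
closure* is reflexive (it always contains the term itself), and the root's
closure is the root alone. Term frequency is **descendant-inclusive**: a
disease annotated to a child counts for every ancestor, consistent with the
true-path rule — an annotation to "focal seizure" implies "seizure". This
guarantees the structural invariant `freq(child) <= freq(parent)` that both
the similarity metric and the category assignment rely on.

Information content is `IC = -log(freq)`. Two numerical choices:

* **Log base** (`base` argument of `compute_information_content()`, default
  natural log). All similarity values are ratios of IC sums and therefore
  base-invariant; absolute IC values, and hence disease-category scores, are
  not. Natural log matches common ontology tooling.
* **Zero-frequency smoothing.** A term with no annotations anywhere below it
  would have infinite IC. We assign it frequency `1/(n_diseases + 1)` —
  slightly rarer than any observed term, finite IC, and vanishing influence
  as the corpus grows.

Disease-category assignment adds each input term's IC once to every
first-level branch in its ancestor closure and takes the argmax. Ties break
to the lexicographically smaller branch id — an arbitrary but deterministic
rule, preferable to input-order dependence. Terms reaching no first-level
branch (the root itself, or terms outside the phenotype subtree) are skipped
with a warning rather than silently dropped.

## 2. Similarity: IC-weighted Jaccard and best-match averaging

The term-pair score divides the IC mass of the shared ancestors by the IC
mass of all ancestors of either term. Because closures are self-inclusive,
a term against its own parent already scores below 1 (the child's private IC
enters only the union), and moving to more distant relatives decays the
score smoothly.

Two degenerate-input rules:

* **Identity wins over the zero-union convention.** A term compared with
  itself scores exactly 1, *including* the root, whose closure carries zero
  IC when every disease is annotated. For *distinct* terms whose ancestor
  union has zero IC mass the score is 0/0 and we define it as 0 (no
  informative shared content). Without the identity rule, a profile
  containing the root could not score 1 against an identical copy of
  itself, breaking the "identical sets score 1" contract that downstream
  significance testing assumes.
* **Set semantics.** Duplicate term ids inside a patient's list are
  collapsed before scoring; each ancestor contributes its IC once per set.

Set-level similarity is the symmetric best-match average: for each term the
best pairwise score against the other set, averaged within each direction,
then across directions. We apply no cap or weighting on set sizes. The
implementation computes cross-similarity matrices from a cached binary
ancestor-closure matrix (one matrix product per call), which is what makes
the Monte-Carlo null affordable; a direct per-pair path
(`pheno_sim_jaccard()`) exists independently and the test suite checks the
two agree with an exhaustive ancestor-set oracle to 1e-12.

## 3. Monte-Carlo nulls

Each match receives two empirical p-values with the add-one estimator
`(1 + #exceedances)/(1 + N)`, bounded in `[1/(N+1), 1]` — never zero, so
`-log10` stays finite.

**Phenotype null.** Only the *query* side is randomized; the reference list
stays observed. Null lists are drawn from the multiset of all reference
cohort annotations, weighted by multiplicity, *without* replacement
(successive draws over distinct terms with probability proportional to
remaining counts), and capped at `max_sim_terms = 10` (shorter observed
lists are matched at their own length). The cap bounds the per-replicate
cost; the frequency weighting preserves cohort-level term-usage bias. The
term corpus is a fixed property of the reference dataset: `run_match()`
accepts it explicitly (`term_corp`) so that adding or removing individual
reference patients does not silently shift the null.

The null treats terms as exchangeable; the ontology's hierarchy induces
correlations among them that the null ignores, so simulated lists can
partially reconstruct a real presentation. No correction is applied — the
p-values are calibrated empirically, not analytically.

**Gene null.** Candidate lists of the observed length are drawn *with*
replacement from the cohort-wide gene multiset, and each replicate records
binary presence/absence of the matched gene, however many times it was
drawn. This adjusts for genes that are frequently prioritized for reasons
unrelated to the patient (gene size, annotation density, tool bias): a gene
seen in half the cohort's candidate lists cannot produce a small gene p.

**Reproducibility.** With a seeded `sim_config()`, every match runs on its
own RNG stream keyed by a stable 31-bit hash of
`(master seed, query, reference, gene)`. Consequences verified by tests:
re-running a configuration is bit-identical; evaluation order is
irrelevant; and deleting a reference patient removes its matches without
changing any surviving match's p-values (given a pinned term corpus).

## 4. Combining dependent p-values

The phenotype and gene p-values are positively dependent — similar
phenotypes raise the chance that phenotype-aware upstream tools put the
diagnostic gene on the candidate list — so Fisher's method would overstate
joint significance. We use the empirical Brown construction: with
`X = -2 ln p1 - 2 ln p2`, `E[X] = 4` under the null, and
`Var(X) = 8 + 2*cov`, where `cov` is the empirical covariance of the
per-pair `(-2 ln p1, -2 ln p2)` samples. Moment matching to `c * chisq(f)`
gives `c = Var/8`, `f = 32/Var`, hence `c*f = 4` exactly (mean
preservation). Independence recovers Fisher (`c=1, f=4`); perfect
dependence gives `c=2, f=2`, under which the combination provably returns
the shared p unchanged. The inverse-normal correlation `rho` of the pairs
is computed and reported alongside but does not enter `c` and `f`; the
covariance estimator is the one that guarantees the two limiting behaviors
above.

Calibration requires at least 10 non-degenerate pairs and is **per
reference dataset**: cohorts differ in phenotyping depth and composition,
which changes the dependence structure. Parameters serialize to a JSON
sidecar (`write_ebm_params()`) and are meant to be fixed once and reused.
Combined p-values are floored at the smallest positive normal double so
scores stay finite.

The SimPheny Score is `-log10(combined p)`; tiers are inclusive as
published: high at `score >= 4.5`, medium at `[2.5, 4.5)`, low below. The
per-gene score averages the two best match scores — one strong independent
replication helps, but ten weak matches cannot masquerade as one strong
one. Benjamini–Hochberg adjustment is applied across *all* matches of a run
(cohort-wide) and reported for completeness; adjusted values depend on run
size and are deliberately not used for tiering, which rests on the portable
score.

## 5. Benchmarking surfaces

Thresholding is inclusive (`score >= t`). TPR, FPR and FDR follow the usual
confusion-matrix definitions with `FDR = 0` when nothing is called (the
empty-call convention; the undefined 0/0 case is never evaluated upstream).
Under the heavy class imbalance typical of candidate lists (>90% of matches
are false), FDR–TPR curves over a 0.5-step score grid (default 1.0–6.0, 11
points) are the primary view; ROC/auROC is also provided, with the area
computed by trapezoid over the threshold sweep and verified in tests
against the exhaustive Mann–Whitney pairwise count (ties half).

## 6. The synthetic-data generator

`generate_ontology()` + `generate_cohort()` emulate the structure this
method needs from real data, at desk scale:

* a rooted DAG with 23 first-level branches (the number of top-level
  disease categories in the human phenotype ontology), depth 4, mean
  branching 2 (~300 terms), with ~10% of deeper terms receiving a second,
  shallower parent within their branch;
* a 200-disease annotation corpus with lognormal per-term popularity, giving
  the right-skewed term-frequency profile of real corpora (few common, many
  rare terms);
* per-gene phenotype pools taken as ontology *subtrees*, so gene-specific
  signal respects the hierarchy; patients draw
  `ceiling(signal_frac * terms_per_patient)` pool terms plus uniform noise.
  The noise quota is set by `signal_frac` alone — a small pool shortens the
  patient's list rather than diluting its signal, so `signal_frac = 1`
  yields (near-)identical same-gene profiles and `signal_frac = 0` a pure
  null;
* candidate lists holding the hidden causal gene among
  popularity-weighted decoys (default 9 decoys from a 40-gene universe),
  and a gene corpus that is exactly the multiset of all candidate entries.

Defaults (20 genes, 3 references and 2 queries per gene, 12 terms per
patient, `signal_frac = 0.75`) were chosen once as a plausible miniature of
a deeply phenotyped cohort. What the generator does **not** emulate:
variant-level evidence, multigenic diagnoses, relatedness between patients,
category-specific enrichment, or the scale of real ontologies (hundreds of
thousands of annotations). Passing recovery tests therefore demonstrates
that the statistical machinery ranks planted signal above frequency-matched
noise under realistic skew — not that real-cohort performance numbers
transfer.

## 7. Problem sizes and numerical tolerances used in validation

The test suite validates end-to-end behavior at reduced simulation counts
(`n_simulations` 200–500 instead of the 10,000 default; the p-value floor
`1/(N+1)` scales accordingly) and cohort sizes of 40–180 queries. The two
headline stochastic properties, both under fixed seeds: with
`signal_frac = 0.75` the pipeline separates true from false matches with
auROC above 0.8 (observed ≈ 0.99), and with `signal_frac = 0` the phenotype
p-values over 500 same-gene matches are near-uniform
(Kolmogorov–Smirnov distance below 0.1). The uniformity check uses
`terms_per_patient = 10`, equal to the simulation cap, so observed and
simulated lists have the same length; with longer observed lists the
estimator is intentionally conservative (the cap is a compute guard, not a
calibration device). Exact identities (Fisher reduction, dependence
collapse, similarity oracles) are asserted to 1e-12; Monte-Carlo quantities
to three binomial standard errors.

## 8. Known limitations

* Exact-ID phenotype curation by default; the descendant-expanding mode
  must be requested explicitly (`include_descendants = TRUE`).
* Gene identity is upper-cased string equality; no alias resolution.
* The phenotype null's independence assumption (Section 3) biases p-values
  for queries whose terms cluster in one branch.
* A gene absent from the reference cohort can never be recovered — the
  method ranks only what the cohort has diagnosed.
* Candidate-list construction (variant filtering, upstream prioritization)
  is out of scope: lists are inputs.
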