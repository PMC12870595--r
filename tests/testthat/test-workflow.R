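# Small synthetic cohort reused across the workflow tests; modest simulation
# counts keep the suite fast while leaving p-value resolution adequate.
local_small_cohort <- function(seed = 81) {
  cfg <- synth_config(seed = seed, n_genes = 6, refs_per_gene = 2,
                      queries_per_gene = 1, n_decoy_universe = 12,
                      decoy_genes_per_query = 5)
  onto <- generate_ontology(cfg)
  c(list(cfg = cfg), onto,
    list(cohort = generate_cohort(cfg, onto$graph, onto$corpus)))
}

test_that("the match pipeline is deterministic and order-independent under a fixed seed", {
  x <- local_small_cohort()
  scfg <- sim_config(n_simulations = 60, seed = 9)
  run1 <- run_match(x$cohort$queries, x$cohort$references, x$graph,
                    x$cohort$gene_corpus, scfg)
  run2 <- run_match(x$cohort$queries, x$cohort$references, x$graph,
                    x$cohort$gene_corpus, scfg)
  expect_identical(run1$matches, run2$matches)
  expect_identical(run1$rankings, run2$rankings)
  expect_named(run1$matches,
               c("query_id", "reference_id", "gene", "pheno_sim", "pheno_p",
                 "gene_p", "combined_p", "simpheny_score", "bh_adjusted_p",
                 "tier"))
  # per-match RNG streams: dropping one reference leaves surviving matches'
  # p-values untouched
  refs_minus <- x$cohort$references[-1]
  run3 <- run_match(x$cohort$queries, refs_minus, x$graph,
                    x$cohort$gene_corpus, scfg,
                    ebm = run1$ebm,
                    term_corp = term_corpus(x$cohort$references))
  kept <- run1$matches$reference_id != x$cohort$references[[1]]$patient_id
  common <- c("query_id", "reference_id", "gene", "pheno_sim", "pheno_p",
              "gene_p")
  expect_equal(
    run3$matches[common],
    run1$matches[kept, common],
    ignore_attr = TRUE
  )
})

test_that("cohorts without gene overlap yield an empty table and No Match manifest entries", {
  x <- local_small_cohort()
  aliens <- lapply(x$cohort$references, function(r) {
    reference_patient(r$patient_id, r$terms, "UNRELATED1")
  })
  run <- run_match(x$cohort$queries, aliens, x$graph,
                   x$cohort$gene_corpus, sim_config(10, seed = 1))
  expect_equal(nrow(run$matches), 0)
  expect_setequal(run$manifest$no_match_queries, names(x$cohort$queries))
})

test_that("a planted perfect match attains the run's maximum score", {
  x <- local_small_cohort(seed = 82)
  q1 <- x$cohort$queries[[1]]
  # identical term lists and a gene at the corpus frequency floor: both
  # p-values bottom out, so no other match can outscore it (monotonicity)
  planted_gene <- "PLANTED1"
  q_planted <- patient_profile("q_plant", q1$terms,
                               c(planted_gene, q1$candidate_genes))
  r_planted <- reference_patient("r_plant", q1$terms, planted_gene)
  queries <- c(x$cohort$queries, list(q_plant = q_planted))
  refs <- c(x$cohort$references, list(r_plant = r_planted))
  gcorp <- x$cohort$gene_corpus
  run <- run_match(queries, refs, x$graph, gcorp,
                   sim_config(n_simulations = 100, seed = 3))
  planted_row <- run$matches$gene == planted_gene
  expect_true(any(planted_row))
  expect_equal(max(run$matches$simpheny_score),
               max(run$matches$simpheny_score[planted_row]))
})

test_that("curation-emptied queries are skipped with a warning", {
  x <- local_small_cohort()
  q <- x$cohort$queries[[1]]
  expect_warning(
    run <- run_match(list(q), x$cohort$references, x$graph,
                     x$cohort$gene_corpus, sim_config(10, seed = 1),
                     exclusion_list = q$terms),
    "skipped"
  )
  expect_equal(nrow(run$matches), 0)
  expect_equal(run$manifest$skipped_queries, q$patient_id)
})

test_that("benchmarking a run produces the metric grid, ROC, and top-k recovery", {
  x <- local_small_cohort(seed = 83)
  run <- run_match(x$cohort$queries, x$cohort$references, x$graph,
                   x$cohort$gene_corpus, sim_config(80, seed = 5))
  bench <- run_benchmark(run, x$cohort$truth)
  expect_equal(nrow(bench$metrics), 11)  # 1.0 to 6.0 in 0.5 steps
  expect_equal(bench$metrics$threshold, seq(1, 6, by = 0.5))
  expect_true(all(bench$labeled$is_tp ==
                    (bench$labeled$gene ==
                       unlist(x$cohort$truth)[bench$labeled$query_id])))
  expect_true(is.null(bench$roc) ||
                (bench$roc$auroc >= 0 && bench$roc$auroc <= 1))
  expect_true(all(bench$topk >= 0 & bench$topk <= 1))
  missing_truth <- x$cohort$truth[-1]
  expect_error(run_benchmark(run, missing_truth), "missing from truth")
})

test_that("phenotype-only mode ranks references by similarity without scores", {
  x <- local_small_cohort()
  out <- run_phenotype_only(x$cohort$queries[1:2], x$cohort$references,
                            x$graph)
  expect_named(out, c("query_id", "reference_id", "pheno_sim",
                      "diagnostic_genes"))
  for (qid in unique(out$query_id)) {
    expect_false(is.unsorted(rev(out$pheno_sim[out$query_id == qid])))
  }
})

test_that("run outputs serialize to the documented TSV and JSON shapes", {
  x <- local_small_cohort()
  run <- run_match(x$cohort$queries[1:2], x$cohort$references, x$graph,
                   x$cohort$gene_corpus, sim_config(20, seed = 2))
  d <- withr::local_tempdir()
  write_tsv(run$matches, file.path(d, "matches.tsv"))
  write_tsv(run$rankings, file.path(d, "rankings.tsv"))
  write_manifest(run, file.path(d, "manifest.json"))
  back <- utils::read.delim(file.path(d, "matches.tsv"))
  expect_equal(nrow(back), nrow(run$matches))
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  expect_equal(man$n_matches, nrow(run$matches))
  expect_equal(man$seed, 2)
})
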