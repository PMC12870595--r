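#' Run the end-to-end matching pipeline
#'
#' For every query: curate terms, enumerate gene-overlap matches against the
#' reference cohort, compute the Monte-Carlo phenotype and gene p-values per
#' match (each match on its own RNG stream keyed by query, reference and
#' gene, so results are independent of evaluation order), combine them with
#' Empirical Brown's Method into a SimPheny Score and confidence tier, apply
#' a run-wide Benjamini-Hochberg adjustment, and rank each query's candidate
#' genes.
#'
#' @param queries List of `patient_profile` objects (with candidate genes).
#' @param references List of `reference_patient` objects.
#' @param graph An `ontology_graph` with IC computed.
#' @param gene_corp A `gene_corpus`; defaults to the multiset of the queries'
#'   own candidate lists.
#' @param term_corp A `term_corpus` for the phenotype null; defaults to the
#'   multiset of the reference cohort's annotations. Pass it explicitly to
#'   pin the null to a fixed reference dataset across runs.
#' @param cfg A [sim_config()]; set its `seed` for reproducible runs.
#' @param ebm An `ebm_params` object, or `NULL` to calibrate from this run's
#'   own (pheno_p, gene_p) pairs (a calibration run).
#' @param exclusion_list Optional character vector of term ids removed from
#'   every query before matching.
#' @param tier_thresholds `c(low_hi, med_hi)` score cut points, default
#'   `c(2.5, 4.5)`.
#' @param exclude_self Drop reference patients whose id equals the query id.
#' @return List with `matches` (one row per match: `query_id, reference_id,
#'   gene, pheno_sim, pheno_p, gene_p, combined_p, simpheny_score,
#'   bh_adjusted_p, tier`), `rankings` (per-query gene ranking table),
#'   `ebm` (parameters used) and `manifest` (run metadata, including queries
#'   with no match).
#' @export
run_match <- function(queries, references, graph, gene_corp = NULL,
                      cfg = sim_config(), ebm = NULL,
                      exclusion_list = NULL,
                      tier_thresholds = c(2.5, 4.5),
                      exclude_self = TRUE, term_corp = NULL) {
  if (is.null(gene_corp)) {
    gene_corp <- gene_corpus(lapply(queries, `[[`, "candidate_genes"))
  }
  tcorp <- if (is.null(term_corp)) term_corpus(references) else term_corp
  no_match <- character(0)
  skipped <- character(0)
  rows <- list()
  for (q in queries) {
    terms <- if (is.null(exclusion_list)) q$terms else {
      suppressWarnings(curate_phenotypes(q$terms, exclusion_list))
    }
    if (length(terms) == 0L) {
      warning("query ", q$patient_id, " has no terms after curation; skipped")
      skipped <- c(skipped, q$patient_id)
      next
    }
    m <- find_matches(q, references, exclude_self = exclude_self)
    if (nrow(m) == 0L) {
      no_match <- c(no_match, q$patient_id)
      next
    }
    ref_by_id <- stats::setNames(references,
                                 vapply(references, `[[`, "", "patient_id"))
    for (i in seq_len(nrow(m))) {
      key <- paste(m$query_id[i], m$reference_id[i], m$gene[i], sep = "|")
      pp <- pheno_p(graph, terms, ref_by_id[[m$reference_id[i]]]$terms,
                    tcorp, cfg, stream_key = paste0("pheno|", key))
      gp <- gene_p(m$gene[i], length(q$candidate_genes), gene_corp, cfg,
                   stream_key = paste0("gene|", key))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = m$query_id[i], reference_id = m$reference_id[i],
        gene = m$gene[i], pheno_sim = pp$observed_sim,
        pheno_p = pp$pheno_p, gene_p = gp, stringsAsFactors = FALSE
      )
    }
  }
  matches <- do.call(rbind, rows)
  if (is.null(matches)) {
    matches <- data.frame(
      query_id = character(0), reference_id = character(0),
      gene = character(0), pheno_sim = numeric(0), pheno_p = numeric(0),
      gene_p = numeric(0), combined_p = numeric(0),
      simpheny_score = numeric(0), bh_adjusted_p = numeric(0),
      tier = character(0), stringsAsFactors = FALSE
    )
    rankings <- data.frame(
      query_id = character(0), rank = integer(0), gene = character(0),
      gene_score = numeric(0), n_matches = integer(0),
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(ebm)) {
      ebm <- calibrate_ebm(matches$pheno_p, matches$gene_p,
                           source_label = "run-calibrated")
    }
    matches$combined_p <- combine_pvalues(matches$pheno_p, matches$gene_p, ebm)
    matches$simpheny_score <- simpheny_score(matches$combined_p)
    matches$bh_adjusted_p <- bh_adjust(matches$combined_p)
    matches$tier <- assign_tier(matches$simpheny_score, tier_thresholds)
    rankings <- do.call(rbind, lapply(
      split(matches, matches$query_id),
      rank_genes
    ))
    rankings <- reset_rownames(rankings)
  }
  manifest <- list(
    seed = cfg$seed,
    n_simulations = cfg$n_simulations,
    max_sim_terms = cfg$max_sim_terms,
    tier_thresholds = tier_thresholds,
    n_queries = length(queries),
    n_references = length(references),
    n_matches = nrow(matches),
    no_match_queries = no_match,
    skipped_queries = skipped,
    ebm = if (!is.null(ebm)) unclass(ebm) else NULL
  )
  list(matches = matches, rankings = rankings, ebm = ebm, manifest = manifest)
}

#' Phenotype-only mode: rank reference patients by similarity
#'
#' For queries without a candidate gene list: returns, per query, the
#' reference patients ordered by set-level similarity. No match significance
#' or SimPheny Scores are computed, as those require gene-level input.
#'
#' @param queries List of `patient_profile` objects.
#' @param references List of `reference_patient` objects.
#' @param graph An `ontology_graph` with IC computed.
#' @return `data.frame` with `query_id`, `reference_id`, `pheno_sim`,
#'   `diagnostic_genes`, ordered by query then descending similarity.
#' @export
run_phenotype_only <- function(queries, references, graph) {
  rows <- lapply(queries, function(q) {
    sims <- vapply(references, function(r) {
      fun_sim_avg(graph, q$terms, r$terms)
    }, numeric(1))
    df <- data.frame(
      query_id = q$patient_id,
      reference_id = vapply(references, `[[`, "", "patient_id"),
      pheno_sim = sims,
      diagnostic_genes = vapply(references, function(r) {
        paste(r$diagnostic_genes, collapse = ";")
      }, ""),
      stringsAsFactors = FALSE
    )
    df[order(-df$pheno_sim, df$reference_id), , drop = FALSE]
  })
  reset_rownames(do.call(rbind, rows))
}

#' Benchmark a run against known diagnoses
#'
#' Labels every match as TP/FP by the truth table, computes confusion
#' metrics on an inclusive-threshold grid, the ROC curve with auROC, and the
#' top-k recovery of diagnostic genes from the rankings.
#'
#' @param run Result of [run_match()].
#' @param truth Named list: query id -> diagnostic gene set (or path read
#'   with [read_truth()]).
#' @param thresholds Ascending grid for [fdr_tpr_curve()], default 1.0-6.0
#'   by 0.5.
#' @param ks Cutoffs for [topk_summary()].
#' @return List with `labeled`, `metrics`, `roc` (or `NULL` when only one
#'   class is present), `topk`.
#' @export
run_benchmark <- function(run, truth, thresholds = seq(1, 6, by = 0.5),
                          ks = c(1L, 5L, 10L)) {
  labeled <- label_matches(run$matches, truth)
  metrics <- fdr_tpr_curve(labeled, thresholds)
  roc <- if (sum(labeled$is_tp) > 0L && sum(!labeled$is_tp) > 0L) {
    roc_curve(labeled)
  } else {
    NULL
  }
  rankings <- split(run$rankings, run$rankings$query_id)
  list(
    labeled = labeled,
    metrics = metrics,
    roc = roc,
    topk = topk_summary(rankings, truth, ks)
  )
}

#' Write the run manifest as JSON
#'
#' @param run Result of [run_match()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
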