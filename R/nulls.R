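#' Monte-Carlo simulation settings
#'
#' @param n_simulations Number of null replicates per match (default 10000).
#' @param max_sim_terms Cap on simulated phenotype-list length (default 10);
#'   shorter observed lists are matched at their own length.
#' @param seed Optional master seed. When set, every match gets its own
#'   deterministic child stream keyed by (query, reference, gene), so
#'   per-match p-values do not depend on evaluation order.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_simulations = 10000, max_sim_terms = 10, seed = NULL) {
  stopifnot(n_simulations >= 1, max_sim_terms >= 1)
  structure(
    list(
      n_simulations = as.integer(n_simulations),
      max_sim_terms = as.integer(max_sim_terms),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Build a term corpus from a reference cohort
#'
#' The corpus is the multiset of all phenotype annotations across the
#' reference patients; duplicates are preserved as per-term weights, so null
#' phenotype lists mirror the cohort's term-usage biases.
#'
#' @param references List of `reference_patient` objects, or a list of
#'   character term vectors.
#' @return A `term_corpus`: named integer counts over distinct term ids.
#' @export
term_corpus <- function(references) {
  terms <- unlist(lapply(references, function(r) {
    if (inherits(r, "reference_patient") || inherits(r, "patient_profile")) {
      r$terms
    } else {
      as.character(r)
    }
  }), use.names = FALSE)
  if (length(terms) == 0L) stop("no terms in reference annotations")
  counts <- table(terms)
  structure(
    stats::setNames(as.integer(counts), names(counts)),
    class = "term_corpus"
  )
}

#' Build a gene corpus from candidate-gene lists
#'
#' Duplicate entries across patients are retained: the multiset counts define
#' each gene's empirical prioritization frequency.
#'
#' @param gene_lists List of character vectors (one candidate list per
#'   patient), or a single character vector of gene symbols with duplicates.
#' @return A `gene_corpus`: named integer counts over distinct symbols.
#' @export
gene_corpus <- function(gene_lists) {
  genes <- toupper(trimws(unlist(gene_lists, use.names = FALSE)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("gene corpus is empty")
  counts <- table(genes)
  structure(
    stats::setNames(as.integer(counts), names(counts)),
    class = "gene_corpus"
  )
}

#' Read a gene corpus from a plain-text file (one symbol per line)
#'
#' Duplicate lines are meaningful: they carry the empirical frequency
#' distribution.
#'
#' @param path Input path.
#' @return A `gene_corpus`.
#' @export
read_gene_corpus <- function(path) {
  gene_corpus(readLines(path, warn = FALSE))
}

# Deterministic 31-bit hash of a string; arithmetic stays exact in doubles.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Child seed for one match's simulation stream.
match_seed <- function(seed, ...) {
  stable_hash(paste(c(seed, ...), collapse = "|"))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# stream is untouched. With seed = NULL the ambient stream is used.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw one null phenotype list from a term corpus
#'
#' Weighted sampling without replacement: successive draws over distinct
#' terms with probability proportional to the remaining multiset counts. The
#' returned list has `min(target_len, max_sim_terms)` distinct terms.
#'
#' @param corpus A `term_corpus`.
#' @param target_len The observed query list length to emulate.
#' @param cfg A [sim_config()]; only `max_sim_terms` is used here. The draw
#'   consumes the current RNG stream (callers seed it).
#' @return Character vector of distinct term ids.
#' @export
simulate_term_list <- function(corpus, target_len, cfg = sim_config()) {
  k <- min(target_len, cfg$max_sim_terms)
  if (sum(corpus > 0) < k) {
    stop("term corpus has fewer than ", k, " distinct terms")
  }
  names(corpus)[sample.int(length(corpus), k, replace = FALSE,
                           prob = as.numeric(corpus))]
}

#' Empirical p-value for observed phenotypic similarity
#'
#' The observed statistic is the best-match-average IC-weighted Jaccard
#' similarity between the query and reference term sets. The null replaces
#' the query side with random phenotype lists drawn from the reference-cohort
#' term corpus (frequency-weighted, without replacement, capped at
#' `max_sim_terms`), keeping the reference list observed. The p-value uses
#' the add-one estimator `(1 + #{sim >= observed}) / (1 + N)`, so it can
#' never reach zero; its floor is `1/(N+1)`.
#'
#' @param graph An `ontology_graph` with IC computed.
#' @param query_terms,reference_terms Non-empty character vectors.
#' @param corpus A `term_corpus`.
#' @param cfg A [sim_config()].
#' @param stream_key Optional character scalar (e.g.
#'   `"query|reference|gene"`) combined with `cfg$seed` to key this match's
#'   private RNG stream.
#' @return List with `pheno_p` and `observed_sim`.
#' @export
pheno_p <- function(graph, query_terms, reference_terms, corpus,
                    cfg = sim_config(), stream_key = NULL) {
  query_terms <- unique(query_terms)
  reference_terms <- unique(reference_terms)
  if (length(query_terms) == 0L || length(reference_terms) == 0L) {
    stop("term sets must be non-empty")
  }
  observed <- fun_sim_avg(graph, query_terms, reference_terms)
  N <- cfg$n_simulations
  # similarity of every corpus term against the observed reference list,
  # computed once; each replicate then just selects rows
  S <- term_similarity_matrix(graph, names(corpus), reference_terms)
  seed <- if (is.null(cfg$seed)) NULL else match_seed(cfg$seed, stream_key)
  exceed <- with_local_seed(seed, {
    k <- min(length(query_terms), cfg$max_sim_terms)
    if (sum(corpus > 0) < k) {
      stop("term corpus has fewer than ", k, " distinct terms")
    }
    w <- as.numeric(corpus)
    n_exceed <- 0L
    for (i in seq_len(N)) {
      idx <- sample.int(length(w), k, replace = FALSE, prob = w)
      Ssub <- S[idx, , drop = FALSE]
      sim <- (mean(apply(Ssub, 1L, max)) + mean(apply(Ssub, 2L, max))) / 2
      if (sim >= observed) n_exceed <- n_exceed + 1L
    }
    n_exceed
  })
  list(pheno_p = (1 + exceed) / (1 + N), observed_sim = observed)
}

#' Empirical p-value for gene-match specificity
#'
#' Simulates candidate gene lists of the observed length by sampling with
#' replacement from the cohort-wide gene corpus (weights = multiset counts)
#' and records per replicate whether the matched gene is present at all
#' (binary presence/absence, however many times it is drawn). The add-one
#' estimator bounds the p-value in `[1/(N+1), 1]`.
#'
#' @param gene Gene symbol.
#' @param list_len Length of the query's filtered candidate list (>= 1).
#' @param corpus A `gene_corpus`.
#' @param cfg A [sim_config()].
#' @param stream_key Optional stream key, as in [pheno_p()].
#' @return The empirical p-value.
#' @export
gene_p <- function(gene, list_len, corpus, cfg = sim_config(),
                   stream_key = NULL) {
  if (list_len < 1L) stop("list_len must be >= 1")
  gene <- toupper(trimws(gene))
  N <- cfg$n_simulations
  target <- match(gene, names(corpus))
  seed <- if (is.null(cfg$seed)) NULL else match_seed(cfg$seed, stream_key)
  n_present <- with_local_seed(seed, {
    draws <- sample.int(length(corpus), N * list_len, replace = TRUE,
                        prob = as.numeric(corpus))
    if (is.na(target)) 0L
    else sum(colSums(matrix(draws == target, nrow = list_len)) > 0L)
  })
  (1 + n_present) / (1 + N)
}
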