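#' Configuration for the synthetic ontology / cohort generator
#'
#' Defaults emulate the structure of a deeply phenotyped rare-disease
#' cohort at desk scale: 23 top-level branches (mirroring the first-level
#' disease categories of the human phenotype ontology), a four-level DAG,
#' a 200-disease annotation corpus with right-skewed term usage, gene-specific
#' phenotype pools drawn from ontology subtrees, and candidate gene lists
#' that contain the causal gene among frequency-weighted decoys.
#'
#' @param seed Master seed; every downstream draw is keyed from it.
#' @param n_top_level First-level branches under the root (default 23).
#' @param depth Maximum node depth below the root (root = depth 0).
#' @param branching Mean number of children of an internal node.
#' @param n_diseases Annotated diseases in the synthetic corpus.
#' @param terms_per_disease Mean annotation count per disease.
#' @param n_genes Number of causal genes with reference patients.
#' @param refs_per_gene Diagnosed reference patients per gene.
#' @param queries_per_gene Query patients per gene.
#' @param terms_per_patient Target phenotype-list length per patient.
#' @param signal_frac Fraction of a patient's terms drawn from their causal
#'   gene's term pool (the rest is uniform noise); 0 = pure null.
#' @param decoy_genes_per_query Decoy genes added to each candidate list.
#' @param n_decoy_universe Total gene universe the decoys are drawn from
#'   (includes the causal genes).
#' @param min_pool_size Minimum subtree size for a gene's term pool.
#' @return A `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_top_level = 23L, depth = 4L,
                         branching = 2L, n_diseases = 200L,
                         terms_per_disease = 6L, n_genes = 20L,
                         refs_per_gene = 3L, queries_per_gene = 2L,
                         terms_per_patient = 12L, signal_frac = 0.75,
                         decoy_genes_per_query = 9L, n_decoy_universe = 40L,
                         min_pool_size = 4L) {
  stopifnot(
    n_top_level >= 1, depth >= 2, branching >= 1, n_diseases >= 1,
    terms_per_disease >= 1, n_genes >= 1, refs_per_gene >= 1,
    queries_per_gene >= 1, terms_per_patient >= 1,
    signal_frac >= 0, signal_frac <= 1,
    decoy_genes_per_query >= 0, n_decoy_universe >= n_genes,
    min_pool_size >= 1
  )
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic rooted-DAG ontology and annotation corpus
#'
#' Builds a root with `n_top_level` first-level children, grows each branch
#' into a tree of the requested depth and branching, and adds occasional
#' second parents within a branch (always to a shallower node, so the graph
#' stays acyclic). Disease annotations are drawn with lognormal per-term
#' popularity weights, producing the right-skewed term-frequency profile of
#' real annotation corpora: a few common terms, many rare ones. Deterministic
#' under the config seed; the caller's RNG stream is untouched.
#'
#' @param cfg A [synth_config()].
#' @return List with `graph` (an `ontology_graph` with IC computed) and
#'   `corpus` (an `annotation_corpus`).
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(match_seed(cfg$seed, "ontology"), {
    ids <- "SP:0000001"
    names_ <- c("SP:0000001" = "phenotypic abnormality (synthetic)")
    parents <- list("SP:0000001" = character(0))
    depth_of <- c("SP:0000001" = 0L)
    branch_of <- c("SP:0000001" = NA_character_)
    counter <- 1L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("SP:%07d", counter)
    }
    add_term <- function(parent, branch) {
      id <- new_id()
      ids <<- c(ids, id)
      names_[id] <<- paste("synthetic term", counter)
      parents[[id]] <<- parent
      depth_of[id] <<- depth_of[[parent]] + 1L
      branch_of[id] <<- branch
      id
    }
    tops <- vapply(seq_len(cfg$n_top_level), function(i) {
      add_term("SP:0000001", branch = as.character(i))
    }, "")
    frontier <- tops
    while (length(frontier)) {
      nxt <- character(0)
      for (node in frontier) {
        if (depth_of[[node]] >= cfg$depth) next
        n_children <- 1L + stats::rpois(1L, cfg$branching - 1)
        for (j in seq_len(n_children)) {
          nxt <- c(nxt, add_term(node, branch_of[[node]]))
        }
      }
      frontier <- nxt
    }
    # sparse second parents: pick a shallower node in the same branch
    for (id in ids[depth_of[ids] >= 2L]) {
      if (stats::runif(1) < 0.1) {
        pool <- ids[!is.na(branch_of[ids]) &
                      branch_of[ids] == branch_of[[id]] &
                      depth_of[ids] < depth_of[[id]]]
        pool <- setdiff(pool, parents[[id]])
        if (length(pool)) {
          parents[[id]] <- c(parents[[id]], sample(pool, 1L))
        }
      }
    }
    graph <- new_ontology_graph(ids, names_, parents)
    annotatable <- setdiff(ids, graph$root_id)
    popularity <- stats::rlnorm(length(annotatable), meanlog = 0, sdlog = 1.5)
    d2t <- lapply(seq_len(cfg$n_diseases), function(d) {
      k <- min(1L + stats::rpois(1L, cfg$terms_per_disease - 1),
               length(annotatable))
      sample(annotatable, k, replace = FALSE, prob = popularity)
    })
    names(d2t) <- sprintf("DIS:%04d", seq_len(cfg$n_diseases))
    corpus <- annotation_corpus(d2t)
    list(graph = compute_information_content(graph, corpus), corpus = corpus)
  })
}

#' Generate a synthetic reference cohort and query set
#'
#' Each causal gene is assigned a characteristic term pool: the subtree under
#' a randomly chosen anchor term, so phenotypic signal respects ontology
#' structure. A patient diagnosed with (or truly caused by) gene g draws
#' `ceiling(signal_frac * terms_per_patient)` terms from pool(g) and fills
#' the rest uniformly from the ontology. Query candidate lists contain the
#' hidden truth gene plus popularity-weighted decoys; the gene corpus is the
#' multiset of all candidate entries.
#'
#' @param cfg A [synth_config()].
#' @param graph An `ontology_graph` with IC computed (from
#'   [generate_ontology()]).
#' @param corpus The matching `annotation_corpus` (kept alongside for
#'   completeness).
#' @return A `synth_cohort`: list with `graph`, `corpus`, `references`,
#'   `queries`, `truth` (named list query id -> truth gene), `gene_corpus`,
#'   and `pools` (named list gene -> term pool).
#' @export
generate_cohort <- function(cfg, graph, corpus) {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(match_seed(cfg$seed, "cohort"), {
    all_terms <- setdiff(graph$term_id, graph$root_id)
    # subtree membership: t is under anchor a iff a is an ancestor of t
    desc_count <- stats::setNames(integer(length(graph$term_id)), graph$term_id)
    for (t in graph$term_id) {
      anc <- graph$ancestors[[t]]
      desc_count[anc] <- desc_count[anc] + 1L
    }
    anchors_ok <- graph$term_id[
      vapply(graph$term_id, function(t) {
        length(graph$ancestors[[t]]) >= 3L  # depth >= 2: below a top-level term
      }, logical(1)) & desc_count >= cfg$min_pool_size
    ]
    if (length(anchors_ok) < cfg$n_genes) {
      stop("ontology has only ", length(anchors_ok),
           " usable subtrees for ", cfg$n_genes, " genes")
    }
    anchors <- sample(anchors_ok, cfg$n_genes)
    genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
    pools <- stats::setNames(lapply(anchors, function(a) {
      graph$term_id[vapply(graph$term_id,
                           function(t) a %in% graph$ancestors[[t]],
                           logical(1))]
    }), genes)

    draw_terms <- function(gene) {
      n_sig <- ceiling(cfg$signal_frac * cfg$terms_per_patient)
      pool <- pools[[gene]]
      sig <- sample(pool, min(n_sig, length(pool)))
      # the noise quota is set by signal_frac, not by how much pool was drawn:
      # a small pool shortens the list rather than diluting the signal
      n_noise <- cfg$terms_per_patient - n_sig
      noise <- if (n_noise > 0) sample(all_terms, n_noise) else character(0)
      unique(c(sig, noise))
    }

    references <- list()
    for (g in genes) {
      for (j in seq_len(cfg$refs_per_gene)) {
        id <- sprintf("REF_%s_%d", g, j)
        references[[id]] <- reference_patient(id, draw_terms(g), g)
      }
    }

    universe <- c(genes,
                  sprintf("DECOY%03d",
                          seq_len(cfg$n_decoy_universe - cfg$n_genes)))
    popularity <- stats::rlnorm(length(universe), meanlog = 0, sdlog = 1)
    names(popularity) <- universe

    queries <- list()
    truth <- list()
    for (g in genes) {
      for (j in seq_len(cfg$queries_per_gene)) {
        id <- sprintf("QRY_%s_%d", g, j)
        others <- setdiff(universe, g)
        n_dec <- min(cfg$decoy_genes_per_query, length(others))
        decoys <- sample(others, n_dec, prob = popularity[others])
        queries[[id]] <- patient_profile(id, draw_terms(g), c(g, decoys))
        truth[[id]] <- g
      }
    }

    structure(
      list(
        graph = graph, corpus = corpus,
        references = references, queries = queries, truth = truth,
        gene_corpus = gene_corpus(lapply(queries, `[[`, "candidate_genes")),
        pools = pools
      ),
      class = "synth_cohort"
    )
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("synth_cohort:", length(x$references), "references,",
      length(x$queries), "queries,", length(x$pools), "genes\n")
  invisible(x)
}
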