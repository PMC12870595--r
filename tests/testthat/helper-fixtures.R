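# Shared fixtures and independent oracles, all built in code.

toy_graph_path <- function() {
  system.file("extdata", "toy.obo", package = "simpheny")
}

# Two-branch toy ontology with a diamond (D under A1 and A2) plus its
# 4-disease annotation corpus. Frequencies: root 1, A = B = 1/2,
# A1 = A2 = B1 = 1/4, D unannotated (smoothed to 1/5).
toy_graph <- function() {
  g <- read_obo(toy_graph_path())
  corp <- read_annotations(
    system.file("extdata", "toy_annotations.tsv", package = "simpheny")
  )
  compute_information_content(g, corp)
}

# term ids of the toy ontology, by readable alias
TOY <- c(root = "SP:0000001", A = "SP:0000002", B = "SP:0000003",
         A1 = "SP:0000004", A2 = "SP:0000005", B1 = "SP:0000006",
         D = "SP:0000007")

# Random rooted DAG with ids T001..Tn; every non-root node picks 1-2 parents
# among earlier nodes, so the graph is acyclic by construction.
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n))
  parents <- list()
  parents[[ids[1L]]] <- character(0)
  for (i in 2:n) {
    k <- sample(1:min(2L, i - 1L), 1L)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
  }
  simpheny:::new_ontology_graph(ids, stats::setNames(ids, ids), parents)
}

# Brute-force reflexive-transitive closure by repeated expansion; independent
# of the package's topological-order computation.
brute_force_ancestors <- function(parents, term) {
  closed <- term
  repeat {
    grown <- unique(c(closed, unlist(parents[closed], use.names = FALSE)))
    if (length(grown) == length(closed)) return(sort(closed))
    closed <- grown
  }
}

# Exhaustive set-similarity oracle: materializes ancestor sets explicitly and
# recomputes the IC-weighted Jaccard and best-match average by direct loops.
oracle_pair_sim <- function(graph, t1, t2) {
  if (t1 == t2) return(1)
  a1 <- brute_force_ancestors(graph$parents, t1)
  a2 <- brute_force_ancestors(graph$parents, t2)
  uni <- sum(graph$ic[union(a1, a2)])
  if (uni == 0) return(0)
  sum(graph$ic[intersect(a1, a2)]) / uni
}

oracle_fun_sim_avg <- function(graph, A, B) {
  A <- unique(A); B <- unique(B)
  fwd <- mean(vapply(A, function(a) {
    max(vapply(B, function(b) oracle_pair_sim(graph, a, b), 0))
  }, 0))
  rev <- mean(vapply(B, function(b) {
    max(vapply(A, function(a) oracle_pair_sim(graph, a, b), 0))
  }, 0))
  (fwd + rev) / 2
}

# Published per-threshold cumulative TP/FP counts from the reference-cohort
# benchmark (score thresholds 6.0 down to 0.0 in 0.5 steps; totals 271 TP,
# 3171 FP). Used as input data to reconstruct the printed rates.
published_counts <- function() {
  data.frame(
    threshold = seq(6, 0, by = -0.5),
    tp_cum = c(3, 11, 29, 51, 79, 110, 145, 185, 221, 251, 265, 270, 271),
    fp_cum = c(0, 0, 4, 11, 30, 85, 191, 400, 825, 1480, 2266, 2882, 3171)
  )
}

# Expand cumulative counts into one labeled match per count, scored at its
# bin's threshold (inclusive >= comparisons keep the cumulative sums exact).
labeled_from_counts <- function(counts) {
  tp_bin <- diff(c(0, counts$tp_cum))
  fp_bin <- diff(c(0, counts$fp_cum))
  data.frame(
    simpheny_score = c(rep(counts$threshold, tp_bin),
                       rep(counts$threshold, fp_bin)),
    is_tp = rep(c(TRUE, FALSE), c(sum(tp_bin), sum(fp_bin)))
  )
}
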