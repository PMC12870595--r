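#' IC-weighted Jaccard similarity between two ontology terms
#'
#' The score is the summed information content of the shared ancestors of the
#' two terms (self-inclusive) divided by the summed IC over all ancestors of
#' either term. It ranges from 0 to 1, with 1 for identical ancestor-IC
#' content; sharing specific (high-IC) ancestors is rewarded more than
#' sharing generic ones. A term compared with itself scores 1; a zero-IC
#' union between distinct terms scores 0 by convention.
#'
#' @param graph An `ontology_graph` with IC computed.
#' @param t1,t2 Term ids.
#' @return A similarity in \[0, 1\].
#' @seealso [fun_sim_avg()] for term-set similarity.
#' @export
pheno_sim_jaccard <- function(graph, t1, t2) {
  if (is.null(graph$ic)) stop("information content not computed")
  a1 <- graph$ancestors[[t1]]
  a2 <- graph$ancestors[[t2]]
  if (is.null(a1)) stop("unknown term id: ", t1)
  if (is.null(a2)) stop("unknown term id: ", t2)
  if (t1 == t2) return(1)
  inter <- sum(graph$ic[intersect(a1, a2)])
  uni <- sum(graph$ic[union(a1, a2)])
  if (uni == 0) return(0)
  inter / uni
}

# Binary ancestor-closure matrix (terms x terms), cached on the graph.
closure_matrix <- function(graph) {
  if (!is.null(graph$cache$closure)) return(graph$cache$closure)
  n <- length(graph$term_id)
  C <- matrix(0, n, n, dimnames = list(graph$term_id, graph$term_id))
  for (i in seq_len(n)) {
    C[i, graph$ancestors[[graph$term_id[i]]]] <- 1
  }
  graph$cache$closure <- C
  C
}

#' Cross-similarity matrix between two vectors of terms
#'
#' Vectorized IC-weighted Jaccard: entry (i, j) equals
#' `pheno_sim_jaccard(graph, terms_a[i], terms_b[j])`. Used internally by the
#' set-level similarity and by the Monte-Carlo null, where many term pairs are
#' scored at once.
#'
#' @param graph An `ontology_graph` with IC computed.
#' @param terms_a,terms_b Character vectors of term ids.
#' @return Numeric matrix `length(terms_a)` x `length(terms_b)`.
#' @export
term_similarity_matrix <- function(graph, terms_a, terms_b) {
  if (is.null(graph$ic)) stop("information content not computed")
  bad <- setdiff(unique(c(terms_a, terms_b)), graph$term_id)
  if (length(bad)) stop("unknown term id: ", bad[1L])
  C <- closure_matrix(graph)
  ic <- as.numeric(graph$ic)
  Ca <- C[terms_a, , drop = FALSE]
  Cb <- C[terms_b, , drop = FALSE]
  inter <- Ca %*% (t(Cb) * ic)
  sa <- as.vector(Ca %*% ic)
  sb <- as.vector(Cb %*% ic)
  uni <- outer(sa, sb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  out[outer(terms_a, terms_b, "==")] <- 1  # self-pairs score 1 even at zero IC
  dimnames(out) <- list(terms_a, terms_b)
  out
}

#' Best-match-average similarity between two term sets
#'
#' For each term in one set, take the highest pairwise similarity it achieves
#' against the other set; average those maxima within each direction and
#' average the two directional means. Symmetric, in \[0, 1\], and exactly 1
#' for identical sets. Duplicate ids within a set are collapsed before
#' scoring.
#'
#' @param graph An `ontology_graph` with IC computed.
#' @param set_a,set_b Non-empty character vectors of term ids.
#' @return A similarity in \[0, 1\].
#' @export
fun_sim_avg <- function(graph, set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("term sets must be non-empty")
  }
  S <- term_similarity_matrix(graph, set_a, set_b)
  bma_from_matrix(S)
}

# Best-match average from a precomputed cross-similarity matrix (rows = one
# set, columns = the other).
bma_from_matrix <- function(S) {
  fwd <- mean(apply(S, 1L, max))
  rev <- mean(apply(S, 2L, max))
  (fwd + rev) / 2
}

#' Pairwise set-similarity matrix over patient or disease profiles
#'
#' @param graph An `ontology_graph` with IC computed.
#' @param profiles Named list of non-empty term-id vectors; names are profile
#'   ids and must be unique.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = ids.
#' @export
pairwise_matrix <- function(graph, profiles) {
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("profiles must be uniquely named")
  }
  if (any(lengths(profiles) == 0L)) stop("term sets must be non-empty")
  n <- length(profiles)
  M <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- fun_sim_avg(graph, profiles[[i]], profiles[[j]])
        M[i, j] <- s
        M[j, i] <- s
      }
    }
  }
  M
}

#' Write a similarity matrix as TSV
#'
#' @param M Matrix from [pairwise_matrix()].
#' @param path Output path.
#' @param long If `TRUE`, write long format (`id_a`, `id_b`, `score`) instead
#'   of the square matrix with ids in header and first column.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(M, path, long = FALSE) {
  if (long) {
    df <- data.frame(
      id_a = rep(rownames(M), times = ncol(M)),
      id_b = rep(colnames(M), each = nrow(M)),
      score = as.vector(M),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(
      data.frame(id = rownames(M), M, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
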