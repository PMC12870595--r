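#' Read a phenotype ontology from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas (`id:`, `name:`, `is_a:`, `is_obsolete:` lines) into
#' an `ontology_graph`. Obsolete terms are dropped. The graph must be a rooted
#' DAG: exactly one term without parents, no cycles, and every `is_a` target
#' present among the non-obsolete terms.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology_graph`: a list with elements
#'   `term_id` (character vector), `name` (named character), `parents` and
#'   `ancestors` (named lists of term ids; ancestor closures are reflexive),
#'   `root_id`, `top_level_ids` (lexicographically sorted first-level children
#'   of the root), and, after [compute_information_content()], `frequency`,
#'   `ic` and `n_diseases`.
#' @seealso [ancestors()], [compute_information_content()]
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) {
    stop("no [Term] stanzas found in ", path)
  }
  stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
  ids <- character(0)
  names_ <- character(0)
  parents <- list()
  for (k in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[k]:stanza_ends[k]]
    # stop at the next non-Term stanza header, if any
    other <- grep("^\\[(?!Term\\])", block, perl = TRUE)
    if (length(other) > 1L || (length(other) == 1L && other[1L] > 1L)) {
      block <- block[seq_len(min(other[other > 1L]) - 1L)]
    }
    get_field <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), block, value = TRUE)
      trimws(sub(paste0("^", tag, ":\\s*"), "", hits))
    }
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    id <- get_field("id")
    if (length(id) != 1L) stop("OBO stanza without a unique id line")
    nm <- get_field("name")
    isa <- get_field("is_a")
    # "is_a: HP:0000118 ! Phenotypic abnormality" -> keep the id part
    isa <- trimws(sub("\\s*!.*$", "", isa))
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) nm[1L] else id)
    parents[[id]] <- unique(isa)
  }
  names(names_) <- ids
  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown)) {
    stop("is_a references unknown term(s): ", paste(unknown, collapse = ", "))
  }
  new_ontology_graph(ids, names_, parents)
}

#' Construct an ontology graph from parsed components
#'
#' @param ids Character vector of term ids.
#' @param names_ Named character vector of labels.
#' @param parents Named list mapping each term id to its parent ids.
#' @return An `ontology_graph`.
#' @keywords internal
new_ontology_graph <- function(ids, names_, parents) {
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root, found ", length(roots))
  }
  order <- topological_order(ids, parents)
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (t in order) {
    anc <- t
    for (p in parents[[t]]) anc <- c(anc, ancestors[[p]])
    ancestors[[t]] <- unique(anc)
  }
  children <- split(
    rep(ids, vapply(parents, length, 1L)),
    unlist(parents, use.names = FALSE)
  )
  top <- sort(children[[roots]] %||% character(0))
  g <- list(
    term_id = ids,
    name = names_,
    parents = parents,
    ancestors = ancestors,
    root_id = roots,
    top_level_ids = top,
    frequency = NULL,
    ic = NULL,
    n_diseases = NULL,
    cache = new.env(parent = emptyenv())
  )
  class(g) <- "ontology_graph"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn topological sort over parent links; errors on a cycle, naming a member.
topological_order <- function(ids, parents) {
  indeg <- vapply(parents, length, 1L)
  child_of <- split(
    rep(ids, vapply(parents, length, 1L)),
    unlist(parents, use.names = FALSE)
  )
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, t)
    for (ch in child_of[[t]] %||% character(0)) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) {
    cyc <- setdiff(ids, out)
    stop("cycle detected in ontology involving term ", cyc[1L])
  }
  out
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$term_id), "terms, root", x$root_id, "\n")
  cat("  top-level branches:", length(x$top_level_ids), "\n")
  if (!is.null(x$ic)) {
    cat("  information content computed over", x$n_diseases, "diseases\n")
  }
  invisible(x)
}

#' Reflexive-transitive ancestor closure of a term
#'
#' The closure always contains the term itself; the root's closure is the
#' root alone.
#'
#' @param graph An `ontology_graph`.
#' @param term_id A single term id present in the graph.
#' @return Character vector of ancestor term ids (including `term_id`).
#' @export
ancestors <- function(graph, term_id) {
  anc <- graph$ancestors[[term_id]]
  if (is.null(anc)) stop("unknown term id: ", term_id)
  anc
}

#' Read a disease-to-term annotation table
#'
#' Expects a TSV with header `disease_id<TAB>term_id`, one pair per row;
#' lines starting with `#` are ignored.
#'
#' @param path Path to the annotation TSV.
#' @return An `annotation_corpus`: list with `disease_to_terms` (named list of
#'   term-id sets) and `n_diseases`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("disease_id", "term_id") %in% names(df))) {
    stop("annotation table must have columns disease_id and term_id")
  }
  annotation_corpus(split(df$term_id, df$disease_id))
}

#' Construct an annotation corpus from a disease -> terms mapping
#'
#' @param disease_to_terms Named list: disease id -> character vector of
#'   annotated term ids.
#' @return An `annotation_corpus`.
#' @export
annotation_corpus <- function(disease_to_terms) {
  if (length(disease_to_terms) == 0L) {
    stop("annotation corpus is empty")
  }
  disease_to_terms <- lapply(disease_to_terms, unique)
  structure(
    list(
      disease_to_terms = disease_to_terms,
      n_diseases = length(disease_to_terms)
    ),
    class = "annotation_corpus"
  )
}

#' Compute term frequencies and information content
#'
#' A term's frequency is the proportion of annotated diseases carrying the
#' term or any of its descendants (true-path counting: an annotation to a
#' child counts for every ancestor). Information content is `-log(frequency)`;
#' terms with no annotations anywhere below them are smoothed to frequency
#' `1/(n_diseases + 1)` so their IC stays finite.
#'
#' @param graph An `ontology_graph`.
#' @param corpus An `annotation_corpus`; every annotated term must exist in
#'   the graph.
#' @param base Logarithm base for IC; the default natural log. All similarity
#'   ratios built on IC are base-invariant, absolute IC values are not.
#' @return The graph with `frequency`, `ic` and `n_diseases` filled in.
#' @export
compute_information_content <- function(graph, corpus, base = exp(1)) {
  if (!inherits(corpus, "annotation_corpus")) {
    stop("corpus must be an annotation_corpus")
  }
  bad <- setdiff(unique(unlist(corpus$disease_to_terms)), graph$term_id)
  if (length(bad)) {
    stop("annotated term(s) absent from graph: ", paste(bad, collapse = ", "))
  }
  n <- corpus$n_diseases
  counts <- stats::setNames(numeric(length(graph$term_id)), graph$term_id)
  for (terms in corpus$disease_to_terms) {
    hit <- unique(unlist(graph$ancestors[terms], use.names = FALSE))
    counts[hit] <- counts[hit] + 1
  }
  freq <- counts / n
  freq[freq == 0] <- 1 / (n + 1)
  ic <- -log(freq, base = base)
  ic[ic < 0] <- 0  # guard against -0
  graph$frequency <- freq
  graph$ic <- ic
  graph$n_diseases <- n
  graph$ic_base <- base
  rm(list = ls(graph$cache), envir = graph$cache)
  graph
}

#' Read an exclusion list (one term id per line)
#'
#' @param path Path to a plain-text file, one term id per line; blank lines
#'   and `#` comments ignored.
#' @return Character vector of term ids.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Curate a phenotype term set against an exclusion list
#'
#' Removes excluded ids by exact match; optionally also removes all
#' descendants of listed terms. Emits a warning when curation empties the set
#' (the empty result is still returned).
#'
#' @param terms Character vector of term ids.
#' @param exclusion_list Character vector of term ids to remove.
#' @param include_descendants If `TRUE`, descendants of listed terms are
#'   removed as well; requires `graph`.
#' @param graph An `ontology_graph`, needed only with `include_descendants`.
#' @return The curated term set (character vector).
#' @export
curate_phenotypes <- function(terms, exclusion_list,
                              include_descendants = FALSE, graph = NULL) {
  terms <- unique(terms)
  excl <- exclusion_list
  if (include_descendants) {
    if (is.null(graph)) stop("graph required when include_descendants = TRUE")
    is_desc <- vapply(
      graph$term_id,
      function(t) any(excl %in% graph$ancestors[[t]]),
      logical(1)
    )
    excl <- union(excl, graph$term_id[is_desc])
  }
  out <- setdiff(terms, excl)
  if (length(terms) > 0L && length(out) == 0L) {
    warning("curation removed every phenotype term")
  }
  out
}

#' Assign a top-level disease category from a term set
#'
#' Each input term's information content is added once to the score of every
#' first-level branch (child of the root) found in its ancestor closure; the
#' branch with the highest cumulative IC wins. Ties break to the
#' lexicographically smaller branch id. Terms that reach no first-level
#' branch (e.g. the root itself) are skipped with a warning.
#'
#' @param graph An `ontology_graph` with IC computed.
#' @param terms Non-empty character vector of term ids.
#' @return List with `category` (a top-level term id) and `scores` (named
#'   numeric over all top-level ids, in sorted id order).
#' @export
assign_disease_category <- function(graph, terms) {
  if (is.null(graph$ic)) stop("information content not computed")
  terms <- unique(terms)
  if (length(terms) == 0L) stop("term set is empty")
  scores <- stats::setNames(numeric(length(graph$top_level_ids)),
                            graph$top_level_ids)
  skipped <- character(0)
  for (t in terms) {
    anc <- graph$ancestors[[t]]
    if (is.null(anc)) stop("unknown term id: ", t)
    tops <- intersect(anc, graph$top_level_ids)
    if (length(tops) == 0L) {
      skipped <- c(skipped, t)
      next
    }
    scores[tops] <- scores[tops] + graph$ic[[t]]
  }
  if (length(skipped)) {
    warning("term(s) not under any top-level branch skipped: ",
            paste(skipped, collapse = ", "))
  }
  # names(scores) is sorted, so which.max's first hit is the lexicographic tie-break
  list(category = names(scores)[which.max(scores)], scores = scores)
}

#' Serialize an ontology graph to an OBO 1.2 flat file
#'
#' Deterministic: stanzas sorted by term id, `is_a` lines sorted.
#'
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in sort(graph$term_id)) {
    pars <- sort(graph$parents[[id]])
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", graph$name[[id]]),
      if (length(pars)) paste0("is_a: ", pars),
      ""
    ), con)
  }
  invisible(path)
}

#' Write an annotation corpus as a two-column TSV
#'
#' @param corpus An `annotation_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(corpus, path) {
  d2t <- corpus$disease_to_terms
  df <- data.frame(
    disease_id = rep(names(d2t), lengths(d2t)),
    term_id = unlist(d2t, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
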