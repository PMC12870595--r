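#' Construct a query patient profile
#'
#' @param patient_id Identifier string.
#' @param terms Character vector of phenotype term ids (de-duplicated).
#' @param candidate_genes Optional character vector of candidate gene symbols;
#'   upper-cased and whitespace-stripped.
#' @return A `patient_profile`.
#' @export
patient_profile <- function(patient_id, terms, candidate_genes = NULL) {
  structure(
    list(
      patient_id = as.character(patient_id),
      terms = unique(as.character(terms)),
      candidate_genes = normalize_genes(candidate_genes)
    ),
    class = "patient_profile"
  )
}

#' Construct a diagnosed reference patient
#'
#' @param patient_id Identifier string.
#' @param terms Character vector of phenotype term ids.
#' @param diagnostic_genes Non-empty character vector of diagnostic gene
#'   symbols (multigenic diagnoses allowed).
#' @return A `reference_patient`.
#' @export
reference_patient <- function(patient_id, terms, diagnostic_genes) {
  genes <- normalize_genes(diagnostic_genes)
  if (length(genes) == 0L) stop("diagnostic_genes must be non-empty")
  structure(
    list(
      patient_id = as.character(patient_id),
      terms = unique(as.character(terms)),
      diagnostic_genes = genes
    ),
    class = "reference_patient"
  )
}

normalize_genes <- function(genes) {
  if (is.null(genes)) return(NULL)
  g <- toupper(trimws(as.character(genes)))
  unique(g[nzchar(g)])
}

#' Read patient records from TSV or JSON-lines
#'
#' TSV columns: `patient_id`, `hpo_terms` (semicolon-separated term ids) and,
#' depending on `type`, `candidate_genes` or `diagnostic_genes`
#' (semicolon-separated symbols). A `.jsonl`/`.json` file is read as one JSON
#' object per line with the same field names (arrays for the list fields).
#'
#' @param path Input path.
#' @param type `"query"` (yields [patient_profile()] objects) or
#'   `"reference"` (yields [reference_patient()] objects).
#' @return List of profiles, named by patient id.
#' @export
read_patients <- function(path, type = c("query", "reference")) {
  type <- match.arg(type)
  gene_col <- if (type == "query") "candidate_genes" else "diagnostic_genes"
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("patient_id", "hpo_terms")
    if (!all(need %in% names(df))) {
      stop("patient table must have columns: ", paste(need, collapse = ", "))
    }
    recs <- lapply(seq_len(nrow(df)), function(i) {
      list(
        patient_id = df$patient_id[i],
        hpo_terms = split_semis(df$hpo_terms[i]),
        genes = split_semis(df[[gene_col]][i] %||% "")
      )
    })
  }
  out <- lapply(recs, function(r) {
    genes <- r[[gene_col]] %||% r$genes
    if (type == "query") {
      patient_profile(r$patient_id, r$hpo_terms,
                      if (length(genes)) genes else NULL)
    } else {
      reference_patient(r$patient_id, r$hpo_terms, genes)
    }
  })
  stats::setNames(out, vapply(out, `[[`, "", "patient_id"))
}

split_semis <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Write patient records as TSV
#'
#' @param patients List of `patient_profile` or `reference_patient` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  is_ref <- inherits(patients[[1L]], "reference_patient")
  gene_col <- if (is_ref) "diagnostic_genes" else "candidate_genes"
  df <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    hpo_terms = vapply(patients, function(p) paste(p$terms, collapse = ";"), ""),
    genes = vapply(patients, function(p) {
      paste(p[[gene_col]] %||% character(0), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
  names(df)[3L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate gene-overlap matches between a query and a reference cohort
#'
#' A match is one (reference patient, shared gene) pair where the gene sits in
#' both the query's candidate list and that reference's diagnostic genes. A
#' gene diagnosed in k references yields k matches. Output rows are sorted by
#' reference id, then gene, so results are invariant to cohort input order.
#'
#' @param query A `patient_profile` with a non-empty candidate gene list.
#' @param cohort List of `reference_patient` objects.
#' @param exclude_self Drop matches where the reference id equals the query id
#'   (avoids trivial self-rediscovery). Default `TRUE`.
#' @return `data.frame` with columns `query_id`, `reference_id`, `gene`.
#' @export
find_matches <- function(query, cohort, exclude_self = TRUE) {
  if (length(query$candidate_genes %||% character(0)) == 0L) {
    stop("query has no candidate gene list; ",
         "use phenotype-only mode for gene-free queries")
  }
  rows <- lapply(cohort, function(ref) {
    if (exclude_self && identical(ref$patient_id, query$patient_id)) {
      return(NULL)
    }
    shared <- intersect(query$candidate_genes, ref$diagnostic_genes)
    if (length(shared) == 0L) return(NULL)
    data.frame(
      query_id = query$patient_id,
      reference_id = ref$patient_id,
      gene = sort(shared),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make_empty_matches())))
  out[order(out$reference_id, out$gene), , drop = FALSE] |> reset_rownames()
}

make_empty_matches <- function() {
  data.frame(query_id = character(0), reference_id = character(0),
             gene = character(0), stringsAsFactors = FALSE)
}

reset_rownames <- function(df) {
  rownames(df) <- NULL
  df
}
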