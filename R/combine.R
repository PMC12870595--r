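#' Calibrate Empirical Brown's Method parameters from p-value pairs
#'
#' Fisher's statistic X = -2 ln p1 - 2 ln p2 has mean 4 under the null; its
#' variance is 8 + 2 cov(-2 ln p1, -2 ln p2), with the covariance estimated
#' empirically from the supplied pairs. Matching the first two moments of a
#' scaled chi-square c * chisq(f) gives f = 32 / Var and c = Var / 8, so
#' c * f = 4 always. Independent uniform pairs give (c, f) near (1, 4)
#' (Fisher); perfectly dependent pairs give (c, f) near (2, 2). The
#' inverse-normal correlation rho of the pairs is reported alongside.
#'
#' Each reference cohort needs its own calibration: the dependence between
#' the phenotype and gene p-values varies with cohort structure, and reusing
#' parameters across cohorts distorts the null.
#'
#' @param pheno_p,gene_p Numeric vectors of paired p-values in (0, 1\];
#'   at least 10 pairs, neither column constant.
#' @param source_label Name of the reference dataset the pairs came from.
#' @return An `ebm_params` object: list with `rho`, `scale_factor`, `dof`,
#'   `n_pairs`, `source_label`.
#' @export
calibrate_ebm <- function(pheno_p, gene_p, source_label = "unnamed") {
  if (length(pheno_p) != length(gene_p)) {
    stop("pheno_p and gene_p must be paired")
  }
  if (length(pheno_p) < 10L) {
    stop("EBM calibration needs at least 10 p-value pairs")
  }
  check_p(c(pheno_p, gene_p))
  if (stats::sd(pheno_p) == 0 || stats::sd(gene_p) == 0) {
    stop("degenerate calibration input: constant p-value column")
  }
  x1 <- -2 * log(pheno_p)
  x2 <- -2 * log(gene_p)
  cov12 <- stats::cov(x1, x2)
  var_x <- 8 + 2 * cov12
  if (var_x <= 0) stop("estimated variance of the combined statistic is <= 0")
  # clamp away from 1 so the informational z-transform stays finite
  rho <- stats::cor(stats::qnorm(pmin(pheno_p, 1 - 1e-12)),
                    stats::qnorm(pmin(gene_p, 1 - 1e-12)))
  structure(
    list(
      rho = rho,
      scale_factor = var_x / 8,
      dof = 32 / var_x,
      n_pairs = length(pheno_p),
      source_label = source_label
    ),
    class = "ebm_params"
  )
}

#' Construct EBM parameters directly
#'
#' @param scale_factor Scale c > 0.
#' @param dof Degrees of freedom f > 0.
#' @param rho Optional correlation, for the record.
#' @param source_label Dataset label.
#' @param n_pairs Optional calibration size, for the record.
#' @return An `ebm_params` object.
#' @export
ebm_params <- function(scale_factor, dof, rho = NA_real_,
                       source_label = "manual", n_pairs = NA_integer_) {
  stopifnot(scale_factor > 0, dof > 0)
  structure(
    list(rho = rho, scale_factor = scale_factor, dof = dof,
         n_pairs = n_pairs, source_label = source_label),
    class = "ebm_params"
  )
}

#' @export
print.ebm_params <- function(x, ...) {
  cat(sprintf(
    "ebm_params [%s]: c = %.4f, f = %.4f, rho = %.4f (n = %s)\n",
    x$source_label, x$scale_factor, x$dof, x$rho, x$n_pairs
  ))
  invisible(x)
}

#' Write / read EBM parameters as a JSON sidecar
#'
#' Calibrations are per reference dataset and meant to be fixed and reused,
#' so they serialize to a small JSON file.
#'
#' @param params An `ebm_params` object.
#' @param path JSON path.
#' @return `path` invisibly (writer); an `ebm_params` (reader).
#' @export
write_ebm_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ebm_params
#' @export
read_ebm_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  ebm_params(x$scale_factor, x$dof, rho = x$rho %||% NA_real_,
             source_label = x$source_label %||% "unnamed",
             n_pairs = x$n_pairs %||% NA_integer_)
}

check_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  invisible(p)
}

#' Combine a phenotype and a gene p-value with Empirical Brown's Method
#'
#' Computes X = -2 ln(pheno_p) - 2 ln(gene_p) and returns the upper-tail
#' probability of the calibrated scaled chi-square, i.e.
#' `P(chisq(f) >= X / c)`. With (c, f) = (1, 4) this is exactly Fisher's
#' method; with (c, f) = (2, 2) and equal inputs it returns that input
#' unchanged (perfect dependence collapses two tests into one). The result
#' is floored at the smallest positive normal double so that -log10 stays
#' finite.
#'
#' @param pheno_p,gene_p P-values in (0, 1\] (vectorized, recycled).
#' @param params An `ebm_params` object.
#' @return Combined p-value(s) in (0, 1].
#' @export
combine_pvalues <- function(pheno_p, gene_p, params) {
  check_p(pheno_p)
  check_p(gene_p)
  if (!inherits(params, "ebm_params")) stop("params must be ebm_params")
  x <- -2 * log(pheno_p) - 2 * log(gene_p)
  p <- stats::pchisq(x / params$scale_factor, df = params$dof,
                     lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' SimPheny Score: negative log10 of the combined p-value
#'
#' @param combined_p P-value(s) in (0, 1].
#' @return Non-negative score(s); larger means stronger joint evidence of
#'   phenotypic similarity and gene specificity.
#' @export
simpheny_score <- function(combined_p) {
  check_p(combined_p)
  -log10(combined_p)
}

#' Confidence tier for a SimPheny Score
#'
#' Boundaries are inclusive as published: high for score >= 4.5, medium for
#' 2.5 <= score < 4.5, low below 2.5.
#'
#' @param score Non-negative score(s).
#' @param thresholds Numeric `c(low_hi, med_hi)`, default `c(2.5, 4.5)`;
#'   must satisfy `0 < low_hi < med_hi`.
#' @return Character vector in `{"high", "medium", "low"}`.
#' @export
assign_tier <- function(score, thresholds = c(2.5, 4.5)) {
  if (any(score < 0)) stop("scores must be non-negative")
  stopifnot(length(thresholds) == 2L, 0 < thresholds[1L],
            thresholds[1L] < thresholds[2L])
  ifelse(score >= thresholds[2L], "high",
         ifelse(score >= thresholds[1L], "medium", "low"))
}

#' Gene-level score from per-match scores
#'
#' The mean of the two highest match scores for the gene; a single match
#' scores as itself. Keeps multi-match support without letting many weak
#' matches swamp the gene.
#'
#' @param match_scores Non-empty numeric vector of SimPheny Scores.
#' @return The gene score.
#' @export
gene_score <- function(match_scores) {
  if (length(match_scores) == 0L) stop("no match scores supplied")
  if (length(match_scores) == 1L) return(match_scores)
  mean(sort(match_scores, decreasing = TRUE)[1:2])
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with cumulative-minimum monotonicity;
#' output order matches input order. Adjusted values are run-scoped: they
#' depend on how many matches the run produced and do not transfer across
#' cohorts.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  check_p(p_values)
  stats::p.adjust(p_values, method = "BH")
}

#' Rank one query's candidate genes by gene score
#'
#' Matches are grouped by gene, reduced with [gene_score()], and sorted by
#' score descending with alphabetical tie-break; ranks are 1-based and
#' consecutive.
#'
#' @param matches `data.frame` with columns `query_id`, `gene`,
#'   `simpheny_score`, all rows sharing one query id.
#' @return `data.frame` with columns `query_id`, `rank`, `gene`,
#'   `gene_score`, `n_matches`.
#' @export
rank_genes <- function(matches) {
  if (nrow(matches) == 0L) {
    return(data.frame(query_id = character(0), rank = integer(0),
                      gene = character(0), gene_score = numeric(0),
                      n_matches = integer(0), stringsAsFactors = FALSE))
  }
  if (length(unique(matches$query_id)) != 1L) {
    stop("rank_genes expects matches from a single query")
  }
  by_gene <- split(matches$simpheny_score, matches$gene)
  df <- data.frame(
    query_id = matches$query_id[1L],
    gene = names(by_gene),
    gene_score = vapply(by_gene, gene_score, numeric(1)),
    n_matches = vapply(by_gene, length, integer(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$gene_score, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  reset_rownames(df[, c("query_id", "rank", "gene", "gene_score", "n_matches")])
}
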