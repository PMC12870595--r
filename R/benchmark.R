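#' Label matches against known diagnoses
#'
#' A match is a true positive when its gene belongs to the query's known
#' diagnostic gene set, a false positive otherwise.
#'
#' @param matches `data.frame` with at least `query_id` and `gene` columns.
#' @param truth Named list: query id -> character vector of diagnostic genes.
#' @return `matches` with a logical `is_tp` column appended.
#' @export
label_matches <- function(matches, truth) {
  missing_q <- setdiff(unique(matches$query_id), names(truth))
  if (length(missing_q)) {
    stop("query id(s) missing from truth: ", paste(missing_q, collapse = ", "))
  }
  matches$is_tp <- vapply(seq_len(nrow(matches)), function(i) {
    matches$gene[i] %in% toupper(truth[[matches$query_id[i]]])
  }, logical(1))
  matches
}

#' Confusion counts and rates at one score threshold
#'
#' Matches with score >= threshold are the called positives (inclusive
#' comparison). TPR = TP/(TP+FN), FPR = FP/(FP+TN), FDR = FP/(FP+TP) with
#' FDR defined as 0 when nothing is called.
#'
#' @param labeled `data.frame` with `simpheny_score` and logical `is_tp`.
#' @param threshold Score cutoff.
#' @return One-row `data.frame`: `threshold, tp, fp, fn, tn, tpr, fpr, fdr`.
#' @export
threshold_metrics <- function(labeled, threshold) {
  if (nrow(labeled) == 0L) stop("no labeled matches")
  called <- labeled$simpheny_score >= threshold
  tp <- sum(called & labeled$is_tp)
  fp <- sum(called & !labeled$is_tp)
  fn <- sum(!called & labeled$is_tp)
  tn <- sum(!called & !labeled$is_tp)
  data.frame(
    threshold = threshold,
    tp = tp, fp = fp, fn = fn, tn = tn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    fdr = if (fp + tp > 0) fp / (fp + tp) else 0
  )
}

#' ROC curve and auROC over match scores
#'
#' Sweeps every distinct score as an inclusive threshold, adding the (0,0)
#' and (1,1) sentinels, and integrates by the trapezoid rule. The area
#' equals the Mann-Whitney probability that a random true-positive match
#' outscores a random false positive (ties counted half).
#'
#' @param labeled `data.frame` with `simpheny_score` and logical `is_tp`;
#'   both classes must be present.
#' @return List with `points` (`data.frame` of `fpr`, `tpr`) and `auroc`.
#' @export
roc_curve <- function(labeled) {
  n_tp <- sum(labeled$is_tp)
  n_fp <- sum(!labeled$is_tp)
  if (n_tp == 0L || n_fp == 0L) {
    stop("ROC needs both true and false positive matches")
  }
  thr <- sort(unique(labeled$simpheny_score), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    called <- labeled$simpheny_score >= t
    c(fpr = sum(called & !labeled$is_tp) / n_fp,
      tpr = sum(called & labeled$is_tp) / n_tp)
  }, numeric(2))
  points <- data.frame(fpr = c(0, pts["fpr", ], 1),
                       tpr = c(0, pts["tpr", ], 1))
  auroc <- sum(diff(points$fpr) *
                 (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  list(points = points, auroc = auroc)
}

#' Sensitivity / false-discovery surface over a threshold grid
#'
#' The FDR-TPR view is preferred over ROC under heavy class imbalance,
#' where abundant true negatives deflate the FPR.
#'
#' @param labeled `data.frame` with `simpheny_score` and `is_tp`.
#' @param thresholds Ascending numeric grid; default 1.0 to 6.0 in 0.5 steps.
#' @return `data.frame`, one [threshold_metrics()] row per threshold.
#' @export
fdr_tpr_curve <- function(labeled, thresholds = seq(1, 6, by = 0.5)) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  do.call(rbind, lapply(thresholds, function(t) threshold_metrics(labeled, t)))
}

#' Fraction of queries whose diagnostic gene ranks within the top k
#'
#' A query with several diagnostic genes counts as a hit at k when any of
#' them ranks <= k; a diagnostic gene absent from the ranking is a miss at
#' every k. The denominator is the number of rankings supplied.
#'
#' @param rankings List of [rank_genes()] tables (one per query).
#' @param truth Named list: query id -> diagnostic gene set.
#' @param ks Integer vector of cutoffs, default `c(1, 5, 10)`.
#' @return Named numeric vector of fractions, names `"k"` values.
#' @export
topk_summary <- function(rankings, truth, ks = c(1L, 5L, 10L)) {
  rankings <- Filter(function(r) nrow(r) > 0L, rankings)
  if (length(rankings) == 0L) stop("no non-empty rankings supplied")
  best_rank <- vapply(rankings, function(r) {
    qid <- r$query_id[1L]
    if (!qid %in% names(truth)) stop("query id missing from truth: ", qid)
    hits <- r$rank[r$gene %in% toupper(truth[[qid]])]
    if (length(hits)) min(hits) else Inf
  }, numeric(1))
  stats::setNames(
    vapply(ks, function(k) mean(best_rank <= k), numeric(1)),
    as.character(ks)
  )
}

#' Write labeled matches or threshold metrics as TSV
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table (`patient_id`, semicolon-separated `diagnostic_genes`)
#'
#' @param path TSV path.
#' @return Named list: patient id -> character vector of gene symbols.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("patient_id", "diagnostic_genes") %in% names(df))) {
    stop("truth table must have columns patient_id and diagnostic_genes")
  }
  stats::setNames(
    lapply(df$diagnostic_genes, function(x) toupper(split_semis(x))),
    df$patient_id
  )
}
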