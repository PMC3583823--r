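#' Confusion counts for a top-k returned list
#'
#' A database domain is relevant when its label (at the chosen hierarchy
#' level) equals the query's. Among the top `k` of the ranked list, relevant
#' domains are true positives and irrelevant ones false positives; relevant
#' domains not returned are false negatives and irrelevant ones not
#' returned are true negatives.
#'
#' @param ranked a `ranked_list` over the full database.
#' @param labels named character vector of database labels (names are
#'   domain ids), e.g. from [labels_at_level()].
#' @param query_label the query's label at the same level; must have at
#'   least one relevant domain in the database.
#' @param k list length, `0 <= k <= length(ranked ids)`.
#' @return list of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`, `k`, `n`.
#' @export
confusion_at_k <- function(ranked, labels, query_label, k) {
  n <- length(labels)
  if (k < 0 || k > nrow(ranked))
    mg_stop_input("k = ", k, " must lie in [0, ", nrow(ranked), "]")
  if (is.null(names(labels)))
    mg_stop_input("labels must be named by domain id")
  missing_ids <- setdiff(ranked$id, names(labels))
  if (length(missing_ids))
    mg_stop_input("ranked ids not in labels: ",
                  paste(utils::head(missing_ids, 3L), collapse = ", "))
  n_rel <- sum(labels == query_label)
  if (n_rel == 0)
    mg_stop_input("no database domain is relevant to label '", query_label,
                  "'; a query must have at least one relevant domain")
  top <- ranked$id[seq_len(k)]
  tp <- sum(labels[top] == query_label)
  structure(list(tp = tp, fp = k - tp, fn = n_rel - tp,
                 tn = n - k - (n_rel - tp), k = k, n = n),
            class = "confusion_counts")
}

#' Rates from confusion counts
#'
#' `TPR = TP/(TP+FN)` (= recall), `FPR = FP/(FP+TN)`,
#' `precision = TP/(TP+FP)` (`NA` at `k = 0`, where it is undefined).
#'
#' @param counts a `confusion_counts` object.
#' @return list with `tpr`, `fpr`, `recall`, `precision`.
#' @export
confusion_rates <- function(counts) {
  tpr <- counts$tp / (counts$tp + counts$fn)
  fpr <- if (counts$fp + counts$tn > 0) counts$fp / (counts$fp + counts$tn) else 0
  precision <- if (counts$k > 0) counts$tp / counts$k else NA_real_
  list(tpr = tpr, fpr = fpr, recall = tpr, precision = precision)
}

#' ROC curve and AUC of a ranked list
#'
#' Sweeps every list length `k = 0..N` (exact, no threshold grid), plots
#' the true positive rate against the false positive rate, and integrates
#' by the trapezoid rule. A ranking with all relevant domains first gives
#' AUC 1; all relevant last gives 0.
#'
#' @inheritParams confusion_at_k
#' @return object of class `eval_curve`: `points` (data frame `x`, `y`),
#'   `kind = "roc"`, `auc`.
#' @export
roc_curve <- function(ranked, labels, query_label) {
  sw <- sweep_counts(ranked, labels, query_label)
  tpr <- sw$tp / sw$n_rel
  fpr <- sw$fp / sw$n_irr
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(points = data.frame(x = fpr, y = tpr), kind = "roc",
                 auc = auc),
            class = "eval_curve")
}

#' Recall-precision curve of a ranked list
#'
#' Points `(recall, precision)` for every `k = 1..N`.
#'
#' @inheritParams confusion_at_k
#' @return object of class `eval_curve` (`kind = "recall_precision"`, no
#'   `auc`).
#' @export
recall_precision_curve <- function(ranked, labels, query_label) {
  sw <- sweep_counts(ranked, labels, query_label)
  ks <- seq_len(nrow(ranked))
  tp <- sw$tp[-1L]  # drop k = 0
  structure(list(points = data.frame(x = tp / sw$n_rel, y = tp / ks),
                 kind = "recall_precision", auc = NA_real_),
            class = "eval_curve")
}

# Cumulative TP/FP over the full sweep k = 0..n_list.
sweep_counts <- function(ranked, labels, query_label) {
  if (is.null(names(labels)))
    mg_stop_input("labels must be named by domain id")
  n_rel <- sum(labels == query_label)
  n_irr <- length(labels) - n_rel
  if (n_rel == 0)
    mg_stop_input("no database domain is relevant to label '", query_label, "'")
  if (n_irr == 0)
    mg_stop_input("every database domain is relevant to label '", query_label,
                  "'; the false positive rate is undefined")
  rel <- unname(labels[ranked$id] == query_label)
  list(tp = c(0, cumsum(rel)), fp = c(0, cumsum(!rel)),
       n_rel = n_rel, n_irr = n_irr)
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("eval_curve (%s): %d points%s\n", x$kind, nrow(x$points),
              if (!is.na(x$auc)) sprintf(", AUC = %.4f", x$auc) else ""))
  invisible(x)
}

#' Write curve points as CSV
#' @param curve an `eval_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(curve$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen relevant domain scores above a
#' randomly chosen irrelevant one, with the tie-corrected midrank form. On
#' tie-free scores this equals the trapezoidal ROC AUC of the full sweep.
#'
#' @param scores numeric ranking scores.
#' @param relevant logical vector, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, relevant) {
  relevant <- as.logical(relevant)
  n1 <- sum(relevant); n0 <- sum(!relevant)
  if (n1 == 0 || n0 == 0)
    mg_stop_input("need at least one relevant and one irrelevant score")
  r <- rank(scores)  # midranks on ties
  (sum(r[relevant]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean AUC over a query set
#'
#' Runs a ranker for each query, computes the per-query ROC AUC at the
#' chosen relevance level, and averages -- the standard single-figure
#' retrieval summary.
#'
#' @param queries list of `domain_query` objects (each must have at least
#'   one relevant database domain at `level`).
#' @param db a `domain_database`.
#' @param ranker function `(db, query) -> ranked_list`.
#' @param level relevance level (`"fold"`, `"superfamily"`, `"family"`).
#' @return list with `mean` and `per_query` (data frame `id`, `auc`).
#' @export
mean_auc <- function(queries, db, ranker, level = "fold") {
  labels <- labels_at_level(db, level)
  auc <- vapply(queries, function(q) {
    ranked <- ranker(db, q)
    roc_curve(ranked, labels, query_label_at_level(q, level))$auc
  }, 0)
  ids <- vapply(queries, `[[`, "", "id")
  list(mean = mean(auc),
       per_query = data.frame(id = ids, auc = auc, stringsAsFactors = FALSE))
}
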