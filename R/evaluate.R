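# Propagation-based precision/recall with top-n and threshold selection,
# pairwise GO similarity, averaged similarity curves, and PR-curve area.

#' Propagate a GO term set to the root
#'
#' Union of ancestor closures over the set: each term is replaced by itself
#' plus every term on any path up to its namespace root.
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of term ids (possibly empty).
#' @return Sorted character vector (empty input gives empty output).
#' @export
propagate <- function(dag, terms) {
  if (length(terms) == 0L) return(character(0))
  assert_in_dag(dag, terms)
  sort(unique(unlist(lapply(unique(terms), go_ancestors, dag = dag))))
}

select_predictions <- function(df, n = NULL, threshold = NULL) {
  if (is.null(df) || nrow(df) == 0L) return(character(0))
  if (!is.null(n)) {
    head(df$go_id, n)
  } else {
    df$go_id[df$score >= threshold]
  }
}

#' Propagation-based precision and recall at one operating point
#'
#' Per protein, the top `n` predictions by score (or all predictions with
#' score at or above `threshold`) are selected; both the selection and the
#' true term set are propagated to the root, and a propagated predicted term
#' counts as correct iff it lies in the propagated truth. Protein-level
#' precision (correct / propagated predictions) and recall (correct /
#' propagated truth) are macro-averaged over proteins: a protein with no
#' selected predictions contributes recall 0 but is skipped in the precision
#' mean. Proteins present in `preds` but absent from `truth` are skipped
#' with a warning.
#'
#' @param preds A `prediction_set`.
#' @param truth Named list, protein id -> character vector of true term ids
#'   (nonempty for every evaluated protein).
#' @param dag A `go_dag`.
#' @param n Top-n cutoff (give exactly one of `n`, `threshold`).
#' @param threshold Score cutoff.
#' @return One-row data frame: `parameter`, `precision`, `recall`,
#'   `proteins_scored` (the count entering the precision mean).
#' @export
precision_recall <- function(preds, truth, dag, n = NULL, threshold = NULL) {
  stopifnot(xor(is.null(n), is.null(threshold)))
  extra <- setdiff(names(preds), names(truth))
  if (length(extra) > 0L) {
    warning("prediction(s) for protein(s) without truth skipped: ",
            paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  prots <- names(truth)
  if (any(vapply(truth, length, integer(1)) == 0L)) {
    stop2("every evaluated protein needs a nonempty truth set")
  }
  precisions <- numeric(0)
  recalls <- numeric(0)
  for (pid in prots) {
    true_prop <- propagate(dag, truth[[pid]])
    sel <- select_predictions(preds[[pid]], n = n, threshold = threshold)
    if (length(sel) == 0L) {
      recalls <- c(recalls, 0)
      next
    }
    pred_prop <- propagate(dag, sel)
    correct <- length(intersect(pred_prop, true_prop))
    precisions <- c(precisions, correct / length(pred_prop))
    recalls <- c(recalls, correct / length(true_prop))
  }
  data.frame(parameter = if (is.null(n)) threshold else n,
             precision = if (length(precisions)) mean(precisions) else NA_real_,
             recall = mean(recalls),
             proteins_scored = length(precisions))
}

#' Precision-recall curve over top-n operating points
#'
#' @inheritParams precision_recall
#' @param n Integer vector of top-n values (default 1:10).
#' @return Data frame with one [precision_recall()] row per `n`.
#' @export
pr_curve <- function(preds, truth, dag, n = 1:10) {
  do.call(rbind, lapply(n, function(k) {
    suppressWarnings(precision_recall(preds, truth, dag, n = k))
  }))
}

#' Pairwise GO-term similarity by shared propagated nodes
#'
#' The number of nodes shared by the two terms' root-propagated closures,
#' divided by the larger closure size. Equals 1 iff the closures are
#' identical and 0 for terms in different namespaces (disjoint closures).
#'
#' @param dag A `go_dag`.
#' @param predicted_term,true_term Single term ids.
#' @return A number in \[0, 1\].
#' @export
go_pair_similarity <- function(dag, predicted_term, true_term) {
  a <- go_ancestors(dag, predicted_term)
  b <- go_ancestors(dag, true_term)
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Mean predicted-vs-true GO similarity across operating points
#'
#' For each protein and each parameter value, the selected predictions (top-n
#' mode: the n best by score; threshold mode: score >= parameter) are paired
#' with every true term and [go_pair_similarity()] is averaged over all
#' pairs; the curve point is the mean over proteins with at least one
#' selected prediction.
#'
#' @inheritParams precision_recall
#' @param mode `"top_n"` or `"threshold"`.
#' @param parameters Increasing vector of n values or thresholds.
#' @return Data frame `parameter`, `mean_similarity`, `proteins_scored`
#'   (class `similarity_curve`).
#' @export
average_similarity <- function(preds, truth, dag,
                               mode = c("top_n", "threshold"), parameters) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(parameters, strictly = TRUE))
  prots <- intersect(names(truth), names(preds))
  rows <- lapply(parameters, function(par) {
    sims <- numeric(0)
    for (pid in prots) {
      sel <- if (mode == "top_n") {
        select_predictions(preds[[pid]], n = par)
      } else {
        select_predictions(preds[[pid]], threshold = par)
      }
      if (length(sel) == 0L || length(truth[[pid]]) == 0L) next
      pair_sims <- outer(sel, truth[[pid]],
                         Vectorize(function(p, t) go_pair_similarity(dag, p, t)))
      sims <- c(sims, mean(pair_sims))
    }
    data.frame(parameter = par,
               mean_similarity = if (length(sims)) mean(sims) else NA_real_,
               proteins_scored = length(sims))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_curve", class(out))
  out
}

#' Trapezoidal area under a precision-recall curve
#'
#' Points are sorted by recall and the area under precision as a function of
#' recall is integrated by the trapezoid rule over the observed recall range
#' (no extrapolation).
#'
#' @param points Data frame with columns `recall` and `precision` (at least
#'   two points).
#' @return A single number.
#' @export
pr_auc <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) < 2L) stop2("need at least 2 points for an area")
  o <- order(points$recall)
  r <- points$recall[o]
  p <- points$precision[o]
  sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
}

#' Tab-separated evaluation report
#'
#' One row per operating point with precision, recall, mean similarity and
#' the number of proteins scored, for both the top-n and threshold metrics.
#'
#' @inheritParams precision_recall
#' @param n_values Top-n points (default 1:10).
#' @param thresholds Threshold points (default `seq(0.1, 0.9, 0.2)`).
#' @param path Optional output path; when given the report is written as TSV.
#' @return The report data frame (invisibly when written).
#' @export
evaluation_report <- function(preds, truth, dag, n_values = 1:10,
                              thresholds = seq(0.1, 0.9, 0.2), path = NULL) {
  top <- do.call(rbind, lapply(n_values, function(k) {
    pr <- suppressWarnings(precision_recall(preds, truth, dag, n = k))
    cbind(mode = "top_n", pr)
  }))
  thr <- do.call(rbind, lapply(thresholds, function(tau) {
    pr <- suppressWarnings(precision_recall(preds, truth, dag, threshold = tau))
    cbind(mode = "threshold", pr)
  }))
  sim_top <- average_similarity(preds, truth, dag, "top_n", n_values)
  sim_thr <- average_similarity(preds, truth, dag, "threshold", thresholds)
  rep <- rbind(top, thr)
  rep$mean_similarity <- c(sim_top$mean_similarity, sim_thr$mean_similarity)
  if (!is.null(path)) {
    write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
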