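# CAFA-style evaluation: tie-ranked top-n selection, precision/recall with
# DAG propagation, threshold sweeps, break-even points, semantic-similarity
# summaries and the average-depth diagnostic.

#' Average (fractional) ranks of confidence scores
#'
#' Ranks scores in descending order; tied scores all receive the mean of the
#' ranks they occupy, e.g. scores (0.9, 0.8, 0.8) rank (1, 2.5, 2.5). Ranks
#' always sum to n(n+1)/2.
#'
#' @param scores numeric vector of confidences.
#' @return numeric vector of average ranks.
#' @export
tied_average_ranks <- function(scores) {
  if (length(scores) == 0) return(numeric())
  rank(-scores, ties.method = "average")
}

#' Select the top n tie groups of a target's predictions
#'
#' Predictions are grouped by identical confidence score; all GO terms in
#' the n highest-scoring groups are returned, so the selection may contain
#' more than n terms when scores tie.
#'
#' @param predictions a prediction frame for one target.
#' @param n number of score groups to keep (>= 1).
#' @return character vector of GO terms.
#' @export
top_n_select <- function(predictions, n) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(predictions) == 0) return(character())
  levels_desc <- sort(unique(predictions$confidence), decreasing = TRUE)
  keep <- utils::head(levels_desc, n)
  predictions$term[predictions$confidence %in% keep]
}

#' Precision and recall of one target after DAG propagation
#'
#' Both the predicted and the true GO term sets are propagated to the root
#' of the ontology; every node on a path from a predicted (true) term to the
#' root counts as predicted (true). Precision is the fraction of propagated
#' predicted nodes that are also true; recall the fraction of propagated
#' true nodes that are predicted. An empty prediction set scores (0, 0).
#'
#' @param predicted_terms character vector of predicted GO terms.
#' @param true_terms character vector of true GO terms (non-empty).
#' @param dag a [go_dag].
#' @return named numeric vector `c(precision=, recall=)`.
#' @export
pr_single_target <- function(predicted_terms, true_terms, dag) {
  if (length(true_terms) == 0)
    stop("target has no true GO terms; exclude it from evaluation")
  if (length(predicted_terms) == 0)
    return(c(precision = 0, recall = 0))
  pred <- propagate(dag, predicted_terms)
  truth <- propagate(dag, true_terms)
  correct <- length(intersect(pred, truth))
  c(precision = correct / length(pred), recall = correct / length(truth))
}

# shared averaging loop: `select` maps a target's prediction frame to the
# evaluated term set for one grid value
pr_curve <- function(predictions, truth, dag, grid, select) {
  targets <- names(truth)[lengths(truth) > 0]
  dropped <- setdiff(names(truth), targets)
  if (length(dropped) > 0)
    message("excluding ", length(dropped), " target(s) with empty truth")
  if (length(targets) == 0) stop("no targets with non-empty truth")
  by_target <- split(as.data.frame(predictions), predictions$target)
  out <- data.frame(selector = grid, precision = NA_real_, recall = NA_real_,
                    n_targets = length(targets))
  for (i in seq_along(grid)) {
    pr <- vapply(targets, function(tg) {
      entry <- by_target[[tg]]
      terms <- if (is.null(entry)) character() else select(entry, grid[[i]])
      pr_single_target(terms, truth[[tg]], dag)
    }, c(precision = 0, recall = 0))
    out$precision[i] <- mean(pr["precision", ])
    out$recall[i] <- mean(pr["recall", ])
  }
  out
}

#' Top-n precision-recall curve
#'
#' For each n in `n_range`, every target's top n tie groups are selected
#' (see [top_n_select()]), scored with [pr_single_target()], and the
#' precision and recall are averaged over all evaluated targets. Targets
#' with no selected predictions contribute (0, 0); targets with empty truth
#' are excluded.
#'
#' @param predictions a prediction frame over all targets.
#' @param truth an `annotation_map` of true GO terms per target.
#' @param dag a [go_dag].
#' @param n_range integer grid of n values (default 1:20).
#' @return data frame with columns selector, precision, recall, n_targets.
#' @export
pr_curve_topn <- function(predictions, truth, dag, n_range = 1:20) {
  if (length(truth) == 0) stop("empty truth table")
  pr_curve(predictions, truth, dag, as.integer(n_range),
           function(entry, n) top_n_select(entry, n))
}

#' Sliding-threshold precision-recall curve
#'
#' For each threshold t on the grid, the predictions with confidence >= t
#' are selected (use `strict = TRUE` for > t), scored with
#' [pr_single_target()], and averaged over targets as in [pr_curve_topn()].
#'
#' @param predictions a prediction frame over all targets.
#' @param truth an `annotation_map` of true GO terms per target.
#' @param dag a [go_dag].
#' @param t_grid numeric threshold grid (default 0 to 1 in steps of 0.01).
#' @param strict if TRUE select confidence strictly greater than t.
#' @return data frame with columns selector, precision, recall, n_targets.
#' @export
pr_curve_threshold <- function(predictions, truth, dag,
                               t_grid = seq(0, 1, by = 0.01),
                               strict = FALSE) {
  if (length(truth) == 0) stop("empty truth table")
  sel <- if (strict) function(entry, t) entry$term[entry$confidence > t]
         else function(entry, t) entry$term[entry$confidence >= t]
  pr_curve(predictions, truth, dag, as.numeric(t_grid), sel)
}

#' Break-even point of a threshold curve
#'
#' The grid point where averaged precision and recall are closest (ties go
#' to the larger threshold); no interpolation between grid points is
#' performed.
#'
#' @param curve a threshold-mode curve from [pr_curve_threshold()].
#' @return list with `t`, `precision`, `recall` and `average` ((P+R)/2).
#' @export
break_even <- function(curve) {
  if (nrow(curve) == 0) stop("empty curve")
  gap <- abs(curve$precision - curve$recall)
  best <- which(gap == min(gap))
  i <- best[which.max(curve$selector[best])]
  list(t = curve$selector[[i]], precision = curve$precision[[i]],
       recall = curve$recall[[i]],
       average = (curve$precision[[i]] + curve$recall[[i]]) / 2)
}

#' Semantic-similarity curves over top-k selections
#'
#' For each k, each target's top k tie groups are selected. Every selected
#' (predicted) term is compared against each true term with
#' [semantic_similarity()]; the maximum over true terms is that prediction's
#' similarity. The *average* curve reports the mean over predicted terms,
#' then over targets; the *best* curve reports the mean over targets of each
#' target's single best prediction similarity. Targets with no selected
#' predictions contribute 0 to both curves.
#'
#' @param predictions a prediction frame over all targets.
#' @param truth an `annotation_map` of true GO terms per target.
#' @param dag a [go_dag].
#' @param k_range integer grid of k values (default 1:20).
#' @return list of two data frames, `average` and `best`, each with columns
#'   selector, similarity, n_targets.
#' @export
similarity_scores <- function(predictions, truth, dag, k_range = 1:20) {
  targets <- names(truth)[lengths(truth) > 0]
  if (length(targets) == 0) stop("no targets with non-empty truth")
  by_target <- split(as.data.frame(predictions), predictions$target)
  k_range <- as.integer(k_range)
  avg <- best <- data.frame(selector = k_range, similarity = NA_real_,
                            n_targets = length(targets))
  for (i in seq_along(k_range)) {
    per_target <- vapply(targets, function(tg) {
      entry <- by_target[[tg]]
      terms <- if (is.null(entry)) character()
               else top_n_select(entry, k_range[[i]])
      if (length(terms) == 0) return(c(avg = 0, best = 0))
      sims <- vapply(terms, function(g) {
        max(vapply(truth[[tg]], function(tt)
          suppressWarnings(semantic_similarity(dag, g, tt)), 0))
      }, 0)
      c(avg = mean(sims), best = max(sims))
    }, c(avg = 0, best = 0))
    avg$similarity[i] <- mean(per_target["avg", ])
    best$similarity[i] <- mean(per_target["best", ])
  }
  list(average = avg, best = best)
}

#' Average depth of a set of GO terms
#'
#' Mean of [term_depth()] over the set under the chosen path convention. A
#' diagnostic of how specific a predictor's terms are: deeper terms are more
#' specific.
#'
#' @param terms non-empty character vector of GO terms.
#' @param dag a [go_dag].
#' @param convention `"shortest"` or `"longest"`, see [term_depth()].
#' @return numeric scalar.
#' @export
average_depth <- function(terms, dag, convention = c("shortest", "longest")) {
  if (length(terms) == 0) stop("empty term set")
  mean(term_depth(dag, terms, match.arg(convention)))
}

#' Write a precision-recall (or similarity) curve as TSV
#'
#' @param curve a data frame from one of the curve functions.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
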