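#' Gate candidate models by ROC score
#'
#' Models with ROC strictly above `threshold` become ensemble members; if
#' none qualifies the gate falls back to `fallback`.  If no model clears
#' the fallback either, no ensemble can be built for the species.
#'
#' @param roc numeric vector of candidate-model ROC scores.
#' @param threshold primary ROC gate (default 0.9).
#' @param fallback fallback gate (default 0.8).
#' @return list with `members` (indices into `roc`) and `threshold_used`.
#' @export
select_members <- function(roc, threshold = 0.9, fallback = 0.8) {
  stopifnot(length(roc) >= 1)
  members <- which(roc > threshold)
  used <- threshold
  if (length(members) == 0) {
    members <- which(roc > fallback)
    used <- fallback
  }
  if (length(members) == 0)
    stop("no-ensemble error: no model exceeds the fallback ROC gate of ",
         fallback)
  list(members = members, threshold_used = used)
}

#' Weighted-mean ensemble prediction
#'
#' Pointwise weighted mean of member predictions, with weights proportional
#' to member ROC scores (normalized to sum 1).  Members whose prediction is
#' entirely `NA` are dropped and the weights renormalized, with a warning.
#'
#' @param preds numeric matrix, one column per member.
#' @param weights unnormalized member weights (e.g. ROC scores).
#' @return numeric vector of ensemble suitabilities in \[0, 1\].
#' @export
weighted_mean_predict <- function(preds, weights) {
  preds <- as.matrix(preds)
  stopifnot(ncol(preds) == length(weights))
  bad <- apply(preds, 2, function(p) all(is.na(p)))
  if (any(bad)) {
    warning(sum(bad), " member(s) failed to predict; dropped and ",
            "weights renormalized")
    preds <- preds[, !bad, drop = FALSE]
    weights <- weights[!bad]
  }
  if (length(weights) == 0) stop("no members left to predict")
  w <- weights / sum(weights)
  drop(preds %*% w)
}

#' Weighted-mean ensemble variable importance
#'
#' Aggregates the per-model permutation importances of the full candidate
#' set into ensemble percentages: per method, importances are averaged over
#' its calibration runs and multiplied by the method's total ensemble
#' weight (methods contributing no member get weight 0); per variable, the
#' weighted method scores are summed and divided by the number of modelling
#' methods; the scores are finally rescaled to percentages summing to 100.
#'
#' @param importance data.frame with columns `method`, `run`, `variable`,
#'   `importance` covering the candidate model set.
#' @param member_weights named numeric vector of normalized ensemble
#'   weights per member, named `"<method>.<run>"`.
#' @param n_methods denominator for the method sum (default 10).
#' @return named numeric vector of percentages summing to 100.
#' @export
emwm_variable_importance <- function(importance, member_weights,
                                     n_methods = 10) {
  stopifnot(all(c("method", "run", "variable", "importance") %in%
                names(importance)))
  # total ensemble weight carried by each method
  meth_of_member <- sub("\\.[0-9]+$", "", names(member_weights))
  w_m <- tapply(member_weights, meth_of_member, sum)
  vars <- unique(importance$variable)
  score <- stats::setNames(numeric(length(vars)), vars)
  for (m in unique(importance$method)) {
    wm <- if (m %in% names(w_m)) w_m[[m]] else 0
    if (wm == 0) next
    sub <- importance[importance$method == m, ]
    a_mv <- tapply(sub$importance, sub$variable, mean)
    score[names(a_mv)] <- score[names(a_mv)] + wm * a_mv
  }
  score <- score / n_methods
  tot <- sum(score)
  if (tot <= 0) {
    warning("all-zero importance scores; returning uniform percentages")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * score / tot
}
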