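# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Stratified calibration/evaluation split
#'
#' Splits record indices into a calibration (training) and an evaluation
#' (test) part, stratified by class so that each class appears in both
#' parts whenever it has at least two members.  The per-class test count is
#' `round((1 - fraction) * n_class)`, clamped to leave at least one member
#' on each side.  Deterministic given `seed`.
#'
#' @param y 0/1 response vector (both classes present, length >= 10).
#' @param fraction calibration fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_calibration <- function(y, fraction = 0.8, seed = 1) {
  stopifnot(length(y) >= 10, fraction > 0, fraction < 1)
  if (length(unique(y)) < 2) stop("both classes must be present")
  test <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      if (length(idx) < 2) {
        warning("class ", cls, " has < 2 members; forced into calibration set")
        next
      }
      n_test <- round((1 - fraction) * length(idx))
      n_test <- min(max(n_test, 1L), length(idx) - 1L)
      test <- c(test, sample(idx, n_test))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Prevalence-balancing case weights
#'
#' Weights each class so that total presence weight equals total absence
#' weight (`prevalence = 0.5`), with the overall sum kept at `n`.  More
#' generally the presence share of the total weight equals `prevalence`.
#'
#' @param y 0/1 response vector with both classes present.
#' @param prevalence target presence share of total weight (default 0.5).
#' @return numeric weight per record.
#' @export
class_weights <- function(y, prevalence = 0.5) {
  y <- as.integer(y)
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  if (n1 == 0 || n0 == 0) stop("weighting error: single-class input")
  w <- ifelse(y == 1, prevalence * n / n1, (1 - prevalence) * n / n0)
  w
}

#' Evaluate suitability predictions against presence/absence labels
#'
#' ROC is the area under the receiver-operating-characteristic curve,
#' computed as the Mann-Whitney probability that a random presence outranks
#' a random absence (ties counted 1/2).  The true skill statistic (TSS) is
#' maximized by scanning all midpoints between distinct predicted values as
#' cutoffs; a record is predicted present when its suitability is strictly
#' greater than the cutoff.  Sensitivity and specificity at the selected
#' cutoff are reported in percent.
#'
#' @param pred numeric suitabilities.
#' @param y 0/1 labels (both classes present).
#' @return list with `roc`, `tss`, `cutoff`, `sensitivity`, `specificity`.
#' @export
evaluate_predictions <- function(pred, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("evaluation error: single-class labels")
  r <- rank(pred)
  roc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  v <- sort(unique(pred))
  if (length(v) == 1) {
    # constant predictions: no informative cutoff exists
    return(list(roc = roc, tss = 0, cutoff = v,
                sensitivity = 0, specificity = 100))
  }
  # midpoints between distinct values, plus the two degenerate cutoffs
  # (everything predicted present / absent), so TSS is never below 0
  cuts <- c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)])
  sens <- vapply(cuts, function(ct) mean(pred[y == 1] > ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(pred[y == 0] <= ct), numeric(1))
  tss <- sens + spec - 1
  best <- which.max(tss)  # ties: smallest cutoff
  list(roc = roc, tss = tss[best], cutoff = cuts[best],
       sensitivity = 100 * sens[best], specificity = 100 * spec[best])
}

#' Permutation variable importance
#'
#' For each variable, predictions on the intact data are correlated with
#' predictions after shuffling that variable's column; importance is the
#' mean over permutations of `1 - max(0, r)` (Pearson), hence in \[0, 1\].
#' A variable the model ignores scores 0.  If the model's predictions have
#' zero variance, all importances are defined as 0.
#'
#' @param object an `sdm_fit` (or anything with a compatible `predict`).
#' @param X covariate data.frame used for the assessment.
#' @param n_perm number of permutations (default 3).
#' @param seed integer seed.
#' @return named numeric importance per variable.
#' @export
permutation_importance <- function(object, X, n_perm = 3, seed = 1) {
  p0 <- predict(object, X)
  vars <- names(X)
  out <- stats::setNames(numeric(length(vars)), vars)
  if (stats::sd(p0) == 0) return(out)
  with_seed(seed, {
    for (v in vars) {
      rs <- numeric(n_perm)
      for (k in seq_len(n_perm)) {
        Xs <- X
        Xs[[v]] <- X[[v]][sample.int(nrow(X))]
        ps <- predict(object, Xs)
        r <- if (stats::sd(ps) == 0) 0 else stats::cor(p0, ps)
        rs[k] <- max(0, r)
      }
      out[v] <- mean(1 - rs)
    }
  })
  pmin(pmax(out, 0), 1)
}
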