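#' Fit an ensemble ecological niche model
#'
#' The main fitting function.  For one species it fits every requested
#' learner over `n_runs` stratified 80/20 calibration splits (one split per
#' run, shared by all methods), weights presences and absences to equal
#' prevalence, evaluates each candidate on its held-out split (ROC, TSS,
#' TSS-maximizing cutoff, sensitivity, specificity), estimates permutation
#' variable importance, gates candidates by ROC (0.9, falling back to 0.8),
#' and combines the members into a ROC-weighted mean ensemble with
#' aggregated variable-importance percentages.
#'
#' @param occurrences occurrence data.frame (species, lon, lat, presence,
#'   source).  If `species` is given, the table may contain several species
#'   and absences for the target are derived from the other species'
#'   records via [derive_absences()].
#' @param stack an [env_stack()] of environmental layers.
#' @param species optional target species label.
#' @param methods learner ids (default all ten, see [enm_methods()]).
#' @param n_runs calibration repetitions per method (default 3).
#' @param calib_fraction calibration fraction (default 0.8).
#' @param prevalence presence share of total case weight (default 0.5).
#' @param n_perm permutations for variable importance (default 3).
#' @param roc_gate,roc_fallback ensemble ROC gates (defaults 0.9 / 0.8).
#' @param vif_threshold if non-`NA`, continuous covariates are first
#'   screened with [vif_filter()] at this pairwise-correlation threshold
#'   (default `NA`: no screening inside `enm`; see [vif_filter()]).
#' @param sre_quantile SRE envelope quantile (default 0.025).
#' @param seed integer master seed; all splits, stochastic learners and
#'   permutations derive from it.
#' @param min_presences presence count below which a warning is issued
#'   (default 30).
#' @return an object of class `enm` with components `models` (per-candidate
#'   list: method, run, fit, evaluation, importance, error), `scores`
#'   (data.frame of candidate evaluations), `ensemble` (members, weights,
#'   threshold used, evaluation, importance percentages), `data`,
#'   `call`.
#' @seealso [predict.enm()], [summary.enm()], [variable_importance()]
#' @export
enm <- function(occurrences, stack, species = NULL,
                methods = enm_methods(), n_runs = 3,
                calib_fraction = 0.8, prevalence = 0.5, n_perm = 3,
                roc_gate = 0.9, roc_fallback = 0.8, vif_threshold = NA,
                sre_quantile = 0.025, seed = 1, min_presences = 30) {
  cl <- match.call()
  if (!is.null(species))
    occurrences <- derive_absences(occurrences, species, stack)
  ex <- extract_covariates(stack, occurrences)
  X <- ex$X; y <- ex$y
  if (sum(y == 1) < min_presences)
    warning("only ", sum(y == 1), " presences; a minimum of ",
            min_presences, " is recommended")
  vif_report <- NULL
  if (!is.na(vif_threshold)) {
    cont <- names(X)[vapply(X, is.numeric, logical(1))]
    if (length(cont) >= 2) {
      vif_report <- vif_filter(as.matrix(X[cont]), vif_threshold)
      X <- X[c(vif_report$retained, setdiff(names(X), cont))]
    }
  }
  # sub-seeds: one per run for the split, one per candidate for the fit
  sub <- with_seed(seed, sample.int(2^30, n_runs * (1 + length(methods))))
  split_seeds <- sub[seq_len(n_runs)]
  fit_seeds <- matrix(sub[-seq_len(n_runs)], nrow = length(methods))

  models <- list()
  for (run in seq_len(n_runs)) {
    sp <- split_calibration(y, calib_fraction, seed = split_seeds[run])
    w_train <- class_weights(y[sp$train], prevalence)
    for (mi in seq_along(methods)) {
      method <- methods[mi]
      rec <- list(method = method, run = run, fit = NULL, eval = NULL,
                  importance = NULL, error = NULL)
      rec$fit <- tryCatch(
        with_seed(fit_seeds[mi, run],
                  fit_sdm(method, X[sp$train, , drop = FALSE], y[sp$train],
                          weights = w_train, sre_quantile = sre_quantile)),
        error = function(e) {
          rec$error <<- paste("fit failure:", conditionMessage(e)); NULL
        })
      if (!is.null(rec$fit)) {
        rec$eval <- tryCatch({
          pred <- predict(rec$fit, X[sp$test, , drop = FALSE])
          evaluate_predictions(pred, y[sp$test])
        }, error = function(e) {
          rec$error <<- paste("evaluation failure:", conditionMessage(e))
          NULL
        })
      }
      if (!is.null(rec$eval)) {
        rec$importance <- permutation_importance(
          rec$fit, X[sp$train, , drop = FALSE], n_perm = n_perm,
          seed = fit_seeds[mi, run] + 1L)
      }
      models[[paste0(method, ".", run)]] <- rec
    }
  }

  ok <- !vapply(models, function(m) is.null(m$eval), logical(1))
  scores <- do.call(rbind, lapply(models[ok], function(m)
    data.frame(method = m$method, run = m$run, roc = m$eval$roc,
               tss = m$eval$tss, cutoff = m$eval$cutoff,
               sensitivity = m$eval$sensitivity,
               specificity = m$eval$specificity,
               stringsAsFactors = FALSE)))
  rownames(scores) <- NULL

  ensemble <- tryCatch({
    sel <- select_members(scores$roc, roc_gate, roc_fallback)
    member_ids <- paste0(scores$method, ".", scores$run)[sel$members]
    w <- scores$roc[sel$members]
    w <- stats::setNames(w / sum(w), member_ids)
    # ensemble evaluated on the full dataset (members were tested on
    # held-out splits; the combined map needs one common reference)
    preds <- vapply(member_ids, function(id) predict(models[[id]]$fit, X),
                    numeric(nrow(X)))
    ens_pred <- weighted_mean_predict(preds, w)
    ev <- evaluate_predictions(ens_pred, y)
    imp_df <- do.call(rbind, lapply(models[ok], function(m)
      data.frame(method = m$method, run = m$run,
                 variable = names(m$importance),
                 importance = as.numeric(m$importance),
                 stringsAsFactors = FALSE)))
    pct <- emwm_variable_importance(imp_df, w, n_methods = length(methods))
    list(member_ids = member_ids, weights = w,
         threshold_used = sel$threshold_used, eval = ev, importance = pct)
  }, error = function(e) {
    warning("ensemble not built: ", conditionMessage(e))
    NULL
  })

  structure(list(models = models, scores = scores, ensemble = ensemble,
                 data = list(X = X, y = y, cells = ex$cells),
                 species = species, vif_report = vif_report,
                 settings = list(methods = methods, n_runs = n_runs,
                                 calib_fraction = calib_fraction,
                                 prevalence = prevalence, n_perm = n_perm,
                                 roc_gate = roc_gate,
                                 roc_fallback = roc_fallback,
                                 sre_quantile = sre_quantile, seed = seed),
                 call = cl),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  n_ok <- nrow(x$scores)
  n_all <- length(x$models)
  cat("Ensemble niche model",
      if (!is.null(x$species)) paste0("for '", x$species, "'"), "\n")
  cat("  candidates: ", n_ok, " evaluated of ", n_all, " attempted (",
      length(x$settings$methods), " methods x ", x$settings$n_runs,
      " runs)\n", sep = "")
  if (!is.null(x$ensemble)) {
    cat("  ensemble: ", length(x$ensemble$member_ids),
        " member(s), ROC gate ", x$ensemble$threshold_used,
        sprintf(", ROC %.3f, TSS %.3f\n", x$ensemble$eval$roc,
                x$ensemble$eval$tss), sep = "")
    top <- sort(x$ensemble$importance, decreasing = TRUE)[1]
    cat(sprintf("  top predictor: %s (%.1f%%)\n", names(top), top))
  } else cat("  ensemble: none (no model cleared the ROC gates)\n")
  invisible(x)
}

#' Summarize an ensemble niche model
#'
#' @param object an `enm`.
#' @param ... unused.
#' @return data.frame of per-candidate evaluation scores with the ensemble
#'   row appended (method `"EMwm"`).
#' @export
summary.enm <- function(object, ...) {
  out <- object$scores
  if (!is.null(object$ensemble)) {
    e <- object$ensemble$eval
    out <- rbind(out, data.frame(method = "EMwm", run = NA_integer_,
                                 roc = e$roc, tss = e$tss,
                                 cutoff = e$cutoff,
                                 sensitivity = e$sensitivity,
                                 specificity = e$specificity,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Predict from an ensemble niche model
#'
#' @param object an `enm`.
#' @param newdata an [env_stack()] (prediction over all masked-in cells,
#'   returned as a grid) or a covariate data.frame (returned as a vector).
#' @param type `"ensemble"` for the weighted-mean suitability,
#'   `"members"` for per-member predictions, `"all"` for every evaluated
#'   candidate, or `"consensus"` for the majority-vote binary map over all
#'   candidates at their TSS-maximizing cutoffs (see
#'   [binarize_consensus()]).
#' @param consensus consensus fraction for `type = "consensus"`
#'   (default 0.5).
#' @param ... unused.
#' @return a numeric grid (matrix with `NA` off-mask) or vector; for
#'   `"members"`/`"all"`, a named list of them.
#' @export
predict.enm <- function(object, newdata,
                        type = c("ensemble", "members", "all", "consensus"),
                        consensus = 0.5, ...) {
  type <- match.arg(type)
  is_stack <- inherits(newdata, "env_stack")
  if (is_stack) {
    stk <- newdata
    lin <- which(stk$mask)
    Xn <- as.data.frame(lapply(stk$layers, function(m) m[lin]))
    for (nm in names(stk$layers))
      if (stk$kind[nm] == "categorical") Xn[[nm]] <- factor(Xn[[nm]])
  } else Xn <- newdata

  as_grid <- function(v) {
    if (!is_stack) return(v)
    g <- matrix(NA_real_, nrow(stk$mask), ncol(stk$mask))
    g[lin] <- v
    g
  }
  ids <- if (type %in% c("ensemble", "members")) {
    if (is.null(object$ensemble)) stop("object has no ensemble")
    object$ensemble$member_ids
  } else {
    ok <- !vapply(object$models, function(m) is.null(m$eval), logical(1))
    names(object$models)[ok]
  }
  preds <- vapply(ids, function(id) predict(object$models[[id]]$fit, Xn),
                  numeric(nrow(Xn)))
  if (type == "ensemble")
    return(as_grid(weighted_mean_predict(preds, object$ensemble$weights)))
  if (type %in% c("members", "all"))
    return(lapply(stats::setNames(seq_along(ids), ids),
                  function(j) as_grid(preds[, j])))
  cutoffs <- vapply(ids, function(id) object$models[[id]]$eval$cutoff,
                    numeric(1))
  as_grid(as.numeric(binarize_consensus(preds, cutoffs, consensus)))
}

#' Ensemble variable-importance percentages
#'
#' @param object a fitted model object.
#' @param ... passed on to methods.
#' @return named numeric vector of percentages summing to 100.
#' @export
variable_importance <- function(object, ...) UseMethod("variable_importance")

#' @rdname variable_importance
#' @export
variable_importance.enm <- function(object, ...) {
  if (is.null(object$ensemble)) stop("object has no ensemble")
  object$ensemble$importance
}

#' Plot the ensemble suitability surface
#'
#' @param x an `enm`.
#' @param stack an [env_stack()] to project onto.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.enm <- function(x, stack, main = "ensemble suitability", ...) {
  g <- predict(x, stack, type = "ensemble")
  plot_grid(g, stack, main = main, ...)
}

# shared grid plotting helper (row 1 = north)
plot_grid <- function(g, stack, main = "", ...) {
  nr <- nrow(g); nc <- ncol(g)
  xs <- stack$extent[1] + (seq_len(nc) - 0.5) * stack$res
  ys <- stack$extent[4] - (seq_len(nr) - 0.5) * stack$res
  graphics::image(xs, rev(ys), t(g[nr:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "lon", ylab = "lat", main = main, useRaster = TRUE,
                  ...)
  invisible(NULL)
}
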