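#' Available modelling methods
#'
#' The ten presence/absence learners known to the registry: generalized
#' linear model (GLM), gradient boosting (GBM), generalized additive model
#' (GAM), classification tree analysis (CTA), artificial neural network
#' (ANN), surface range envelope (SRE), flexible discriminant analysis
#' (FDA), adaptive regression splines (MARS), random forest (RF), and
#' maximum entropy (MAXENT).
#'
#' @return character vector of method ids.
#' @export
enm_methods <- function() {
  c("GLM", "GBM", "GAM", "CTA", "ANN", "SRE", "FDA", "MARS", "RF", "MAXENT")
}

# ---- design-matrix helpers ------------------------------------------------

# remember factor levels so prediction frames align with training
design_info <- function(X) {
  is_fac <- vapply(X, is.factor, logical(1))
  list(vars = names(X), factors = names(X)[is_fac],
       levels = lapply(X[is_fac], levels))
}

align_frame <- function(X, info) {
  miss <- setdiff(info$vars, names(X))
  if (length(miss) > 0)
    stop("schema error: missing variable(s) ", paste(miss, collapse = ", "))
  X <- X[info$vars]
  for (nm in info$factors) {
    f <- factor(as.character(X[[nm]]), levels = info$levels[[nm]])
    if (anyNA(f)) f[is.na(f)] <- info$levels[[nm]][1]  # unseen level fallback
    X[[nm]] <- f
  }
  X
}

# numeric model matrix without intercept column
build_matrix <- function(X, info) {
  X <- align_frame(X, info)
  stats::model.matrix(~ ., data = X)[, -1, drop = FALSE]
}

# ---- individual learner adapters ------------------------------------------

fit_glm_learner <- function(X, y, w) {
  dat <- cbind(.y = y, X)
  suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               weights = w))
}

fit_gam_learner <- function(X, y, w) {
  terms <- vapply(names(X), function(nm) {
    if (is.factor(X[[nm]])) return(nm)
    nu <- length(unique(X[[nm]]))
    if (nu < 4) nm else sprintf("s(%s, k = %d)", nm, min(9L, nu - 1L))
  }, character(1))
  f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  dat <- cbind(.y = y, X)
  suppressWarnings(
    mgcv::gam(f, data = dat, family = stats::binomial(), weights = w,
              method = "REML"))
}

fit_cta_learner <- function(X, y, w) {
  dat <- cbind(.y = factor(y, levels = c(0, 1)), X)
  rpart::rpart(.y ~ ., data = dat, weights = w, method = "class")
}

fit_ann_learner <- function(X, y, w, info) {
  m <- build_matrix(X, info)
  ctr <- list(center = colMeans(m), scale = pmax(apply(m, 2, stats::sd), 1e-8))
  ms <- scale(m, ctr$center, ctr$scale)
  net <- nnet::nnet(ms, y, weights = w, size = 8, decay = 0.01,
                    maxit = 500, entropy = TRUE, trace = FALSE)
  list(net = net, ctr = ctr)
}

fit_fda_learner <- function(X, y, w, info) {
  # discriminant analysis with equal priors mirrors the 0.5 prevalence
  m <- build_matrix(X, info)
  MASS::lda(m, grouping = factor(y, levels = c(0, 1)), prior = c(0.5, 0.5))
}

fit_rf_learner <- function(X, y, w) {
  randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                             ntree = 500)
}

fit_gbm_learner <- function(X, y, w, info) {
  m <- build_matrix(X, info)
  dtrain <- xgboost::xgb.DMatrix(m, label = y, weight = w)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 2, eta = 0.1,
                  nthread = 1),
    data = dtrain, nrounds = 100, verbose = 0)
}

maxent_features <- function(m) {
  quad <- m^2
  colnames(quad) <- paste0(colnames(m), "_sq")
  cbind(m, quad)
}

fit_maxent_learner <- function(X, y, w, info) {
  m <- maxent_features(build_matrix(X, info))
  foldid <- rep_len(1:5, nrow(m))  # deterministic folds
  cv <- glmnet::cv.glmnet(m, y, family = "binomial", weights = w,
                          alpha = 1, foldid = foldid, nfolds = 5)
  cv
}

# ---- surface range envelope (native) ---------------------------------------

fit_sre_learner <- function(X, y, q = 0.025) {
  pres <- X[y == 1, , drop = FALSE]
  if (nrow(pres) == 0) stop("SRE needs at least one presence")
  env <- list()
  for (nm in names(X)) {
    if (is.factor(X[[nm]])) {
      env[[nm]] <- list(type = "cat",
                        levels = unique(as.character(pres[[nm]])))
    } else {
      b <- stats::quantile(pres[[nm]], c(q, 1 - q), names = FALSE, type = 7)
      env[[nm]] <- list(type = "num", lower = b[1], upper = b[2])
    }
  }
  env
}

predict_sre <- function(env, X) {
  ok <- rep(TRUE, nrow(X))
  for (nm in names(env)) {
    e <- env[[nm]]
    v <- X[[nm]]
    ok <- ok & if (e$type == "cat") as.character(v) %in% e$levels
               else !is.na(v) & v >= e$lower & v <= e$upper
  }
  as.numeric(ok)
}

# ---- adaptive regression splines (native hinge-basis logistic) -------------

mars_basis <- function(m, knots) {
  cols <- list()
  for (nm in names(knots)) {
    x <- m[, nm]
    for (k in knots[[nm]]) {
      cols[[sprintf("h(%s-%.6g)", nm, k)]] <- pmax(x - k, 0)
      cols[[sprintf("h(%.6g-%s)", k, nm)]] <- pmax(k - x, 0)
    }
  }
  if (length(cols) == 0) return(matrix(numeric(0), nrow(m), 0))
  do.call(cbind, cols)
}

fit_mars_learner <- function(X, y, w, info, knots_per_var = 5,
                             max_pairs = 10, min_gain = 1e-3) {
  m <- build_matrix(X, info)
  num_cols <- colnames(m)[apply(m, 2, function(v) length(unique(v)) > 3)]
  knots <- lapply(stats::setNames(num_cols, num_cols), function(nm)
    unique(stats::quantile(m[, nm], probs = seq(0.1, 0.9,
                                                length.out = knots_per_var),
                           names = FALSE, type = 7)))
  B <- mars_basis(m, knots)
  fac_cols <- setdiff(colnames(m), num_cols)
  base <- m[, fac_cols, drop = FALSE]
  dev0 <- suppressWarnings(
    stats::glm.fit(cbind(1, base), y, weights = w,
                   family = stats::binomial())$deviance)
  chosen <- integer(0)
  # forward selection of reflected hinge pairs by weighted deviance
  pair_idx <- matrix(seq_len(ncol(B)), nrow = 2)
  dev_cur <- dev0
  for (step in seq_len(min(max_pairs, ncol(pair_idx)))) {
    best <- NULL; best_dev <- dev_cur
    for (p in seq_len(ncol(pair_idx))) {
      if (p %in% chosen) next
      cand <- cbind(1, base, B[, c(chosen_cols(chosen, pair_idx),
                                   pair_idx[, p]), drop = FALSE])
      d <- suppressWarnings(tryCatch(
        stats::glm.fit(cand, y, weights = w,
                       family = stats::binomial())$deviance,
        error = function(e) Inf))
      if (d < best_dev - 1e-12) { best_dev <- d; best <- p }
    }
    if (is.null(best) || (dev_cur - best_dev) < min_gain * max(dev0, 1))
      break
    chosen <- c(chosen, best)
    dev_cur <- best_dev
  }
  D <- cbind(1, base, B[, chosen_cols(chosen, pair_idx), drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(D, y, weights = w, family = stats::binomial()))
  list(coef = fit$coefficients, knots = knots, chosen = chosen,
       pair_idx = pair_idx, fac_cols = fac_cols)
}

chosen_cols <- function(chosen, pair_idx) {
  if (length(chosen) == 0) integer(0) else as.vector(pair_idx[, chosen])
}

predict_mars <- function(fit, m) {
  B <- mars_basis(m, fit$knots)
  D <- cbind(1, m[, fit$fac_cols, drop = FALSE],
             B[, chosen_cols(fit$chosen, fit$pair_idx), drop = FALSE])
  co <- fit$coef
  co[is.na(co)] <- 0
  stats::plogis(drop(D %*% co))
}

# ---- registry --------------------------------------------------------------

#' Fit a single species distribution learner
#'
#' Uniform adapter over the ten registry methods.  Every adapter accepts a
#' covariate data.frame (factors for categorical layers), a 0/1 response
#' and case weights, and returns an object whose [predict.sdm_fit()] method
#' emits habitat-suitability probabilities in \[0, 1\].  Case weights are
#' honoured where the backing implementation supports them (GLM, GAM, CTA,
#' ANN, GBM, MARS, MAXENT); FDA uses equal class priors and RF its default
#' resampling; SRE is presence-only by construction.
#'
#' @param method one of [enm_methods()].
#' @param X covariate data.frame.
#' @param y 0/1 response vector.
#' @param weights case weights (default all 1).
#' @param sre_quantile envelope quantile for SRE (default 0.025).
#' @return an object of class `sdm_fit`.
#' @export
fit_sdm <- function(method, X, y, weights = NULL, sre_quantile = 0.025) {
  method <- match.arg(method, enm_methods())
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  if (is.null(weights)) weights <- rep(1, length(y))
  info <- design_info(X)
  fit <- switch(method,
    GLM = fit_glm_learner(X, y, weights),
    GAM = fit_gam_learner(X, y, weights),
    CTA = fit_cta_learner(X, y, weights),
    ANN = fit_ann_learner(X, y, weights, info),
    SRE = fit_sre_learner(X, y, q = sre_quantile),
    FDA = fit_fda_learner(X, y, weights, info),
    MARS = fit_mars_learner(X, y, weights, info),
    RF = fit_rf_learner(X, y, weights),
    GBM = fit_gbm_learner(X, y, weights, info),
    MAXENT = fit_maxent_learner(X, y, weights, info))
  structure(list(method = method, fit = fit, info = info),
            class = "sdm_fit")
}

#' Predict habitat suitability from a fitted learner
#'
#' @param object an `sdm_fit`.
#' @param newdata covariate data.frame with the training variables.
#' @param ... unused.
#' @return numeric vector of suitabilities in \[0, 1\].
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  X <- align_frame(newdata, object$info)
  p <- switch(object$method,
    GLM = stats::predict(object$fit, newdata = X, type = "response"),
    GAM = as.numeric(stats::predict(object$fit, newdata = X,
                                    type = "response")),
    CTA = stats::predict(object$fit, newdata = X, type = "prob")[, "1"],
    ANN = {
      ms <- scale(build_matrix(X, object$info),
                  object$fit$ctr$center, object$fit$ctr$scale)
      as.numeric(stats::predict(object$fit$net, ms))
    },
    SRE = predict_sre(object$fit, X),
    FDA = stats::predict(object$fit,
                         build_matrix(X, object$info))$posterior[, "1"],
    MARS = predict_mars(object$fit, build_matrix(X, object$info)),
    RF = stats::predict(object$fit, newdata = X, type = "prob")[, "1"],
    GBM = stats::predict(object$fit,
                         xgboost::xgb.DMatrix(build_matrix(X, object$info))),
    MAXENT = as.numeric(stats::predict(
      object$fit, newx = maxent_features(build_matrix(X, object$info)),
      s = "lambda.min", type = "response")))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat("sdm_fit:", x$method, "learner on", length(x$info$vars),
      "variable(s)\n")
  invisible(x)
}
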