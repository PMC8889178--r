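#' Variance inflation factors
#'
#' VIF of variable j is `1 / (1 - R^2_j)`, with `R^2_j` from the ordinary
#' least-squares regression (with intercept) of variable j on all other
#' variables.  Exact collinearity is reported as `Inf`.
#'
#' @param X numeric matrix or data.frame of continuous variables
#'   (>= 2 columns, >= 3 rows).
#' @return named numeric vector of VIF values (all >= 1).
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  if (ncol(X) < 2 || nrow(X) < 3)
    stop("need at least 2 variables and 3 rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: zero-variance column(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  vif
}

#' Iterative collinearity filter by pairwise correlation and VIF
#'
#' Repeatedly finds the variable pair with the largest absolute Pearson
#' correlation; while that exceeds `threshold` (strictly), the pair member
#' with the larger VIF is removed (ties broken by removing the later
#' variable in input order) and correlations are recomputed.  Stops when
#' every remaining pair has `|r| <= threshold`.
#'
#' @param X numeric matrix or data.frame of continuous variables.
#' @param threshold correlation threshold (default 0.85).
#' @return a `vif_report`: list with `retained` (names), `vif` (VIFs of the
#'   retained set), and `steps` (data.frame of removals: variable, the
#'   triggering `|r|`, and its VIF at removal).
#' @export
vif_filter <- function(X, threshold = 0.85) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  order0 <- colnames(X)
  steps <- data.frame(variable = character(), abs_r = numeric(),
                      vif = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(X) < 2) break
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= threshold) break
    hit <- which(cm == mx, arr.ind = TRUE)[1, ]
    pair <- colnames(X)[hit]
    vif <- compute_vif(X)
    v <- vif[pair]
    drop_nm <- if (v[1] > v[2]) pair[1]
      else if (v[2] > v[1]) pair[2]
      else pair[which.max(match(pair, order0))]  # tie: later in input order
    steps <- rbind(steps, data.frame(variable = drop_nm, abs_r = mx,
                                     vif = unname(vif[drop_nm]),
                                     stringsAsFactors = FALSE))
    X <- X[, setdiff(colnames(X), drop_nm), drop = FALSE]
  }
  out <- list(retained = colnames(X),
              vif = if (ncol(X) >= 2) compute_vif(X)
                    else stats::setNames(1, colnames(X)),
              steps = steps, threshold = threshold)
  class(out) <- "vif_report"
  out
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF collinearity filter (|r| threshold ", x$threshold, ")\n", sep = "")
  if (nrow(x$steps) == 0) cat("  no variables removed\n")
  else {
    cat("  removed, in order:\n")
    for (i in seq_len(nrow(x$steps)))
      cat(sprintf("    %d. %s  (|r| = %.3f, VIF = %.2f)\n", i,
                  x$steps$variable[i], x$steps$abs_r[i], x$steps$vif[i]))
  }
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Design matrix of continuous layer values for VIF screening
#'
#' @param stack an `env_stack`.
#' @param table optional occurrence table; if given, values are sampled at
#'   the occurrence cells (the default screening scope), otherwise over all
#'   masked-in raster cells.
#' @return numeric matrix, one column per continuous layer.
#' @export
vif_design <- function(stack, table = NULL) {
  cont <- names(stack$kind)[stack$kind == "continuous"]
  if (length(cont) < 2) stop("need at least 2 continuous layers")
  if (is.null(table)) {
    m <- vapply(cont, function(nm) stack$layers[[nm]][stack$mask],
                numeric(sum(stack$mask)))
  } else {
    ex <- extract_covariates(stack, table)
    m <- as.matrix(ex$X[cont])
  }
  m
}
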