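#' Pearson correlation coefficient
#'
#' Linear correlation between two vectors.  Constant input is an error (the
#' correlation is undefined), never silently zero.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have the same length")
  if (length(a) < 2) stop("need at least 2 observations")
  if (anyNA(a) || anyNA(b)) stop("missing values in correlation input")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(a, b)
}

#' Mean absolute error
#'
#' @param pred,actual Numeric vectors of equal length.
#' @return Mean of `|pred - actual|` (kcal/mol for affinity predictions).
#' @export
mae <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("vectors must have the same length")
  if (!length(pred)) stop("empty input")
  mean(abs(pred - actual))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((actual - pred)^2) / sum((actual - mean(actual))^2)`.
#'
#' @param pred,actual Numeric vectors of equal length `>= 2`; `actual` must
#'   not be constant.
#' @return R-squared (`<= 1`, can be negative for poor predictions).
#' @export
r2 <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("vectors must have the same length")
  if (length(pred) < 2) stop("need at least 2 observations")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant actual values")
  1 - sum((actual - pred)^2) / ss_tot
}

#' Leave-one-out cross-validation with an arbitrary trainer
#'
#' For each sample `i`, trains on all other samples and predicts sample `i`.
#' The trainer is any function `trainer(X, y)` returning an object with a
#' `predict(object, newdata)` method.
#'
#' @param X Feature matrix/data.frame.
#' @param y Targets (length `>= 3`).
#' @param trainer Training function; defaults to a GBRT trainer built from
#'   `config`.
#' @param config A [gbrt_config()] used when `trainer` is `NULL` (this path
#'   runs all folds in compiled code).
#' @return Numeric vector of held-out predictions, in input order.
#' @export
loocv <- function(X, y, trainer = NULL, config = gbrt_config()) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(y) < 3) stop("LOOCV needs at least 3 samples")
  if (is.null(trainer)) {
    return(cpp_gbrt_loocv(X, y, config$n_trees, config$shrinkage,
                          config$max_depth, config$min_samples_leaf))
  }
  n <- length(y)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(trainer(X[-i, , drop = FALSE], y[-i]),
                    error = function(e) stop("trainer failed on fold ", i, ": ",
                                             conditionMessage(e)))
    preds[i] <- as.numeric(predict(fit, X[i, , drop = FALSE]))
  }
  preds
}

#' Rank features by single-feature cross-validated correlation
#'
#' Scores every feature by the Pearson correlation between LOOCV predictions
#' of a model trained on that feature alone and the observed targets, sorts
#' in descending order (stable; ties keep registry/column order) and retains
#' the top `top_n`.  A feature whose correlation is undefined (e.g. constant
#' held-out predictions) scores `-Inf`.
#'
#' @param X Feature matrix/data.frame with named columns.
#' @param y Targets.
#' @param config GBRT configuration used for the single-feature models.
#' @param top_n How many features to retain (all when fewer exist).
#' @param method `"loocv"` (default) scores on held-out predictions;
#'   `"train"` scores on in-sample fitted values.
#' @return A data.frame `feature`, `r`, sorted descending, at most `top_n`
#'   rows.
#' @export
rank_features <- function(X, y, config = gbrt_config(), top_n = 10,
                          method = c("loocv", "train")) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  scores <- vapply(seq_len(ncol(X)), function(j) {
    Xj <- X[, j, drop = FALSE]
    preds <- if (method == "loocv") {
      loocv(Xj, y, config = config)
    } else {
      fit_gbrt(Xj, y, config)$fitted
    }
    tryCatch(pearson_r(preds, y), error = function(e) -Inf)
  }, numeric(1))
  ord <- order(-scores)  # stable: ties keep column order
  out <- data.frame(feature = colnames(X)[ord], r = scores[ord],
                    stringsAsFactors = FALSE)
  head(out, top_n)
}

#' Greedy forward feature selection
#'
#' Starting from the best-ranked single feature, repeatedly adds the
#' candidate feature (from the ranked pool) that maximises the LOOCV Pearson
#' correlation of the refit model, stopping when the best improvement is at
#' most `tol`.
#'
#' @param X Feature matrix/data.frame with named columns.
#' @param y Targets.
#' @param ranked Ranked pool from [rank_features()] (data.frame or character
#'   vector of feature names, best first).
#' @param config GBRT configuration used throughout.
#' @param tol Minimum strict improvement in correlation to keep adding.
#' @return A list with `selected` (ordered character vector), `r` (final
#'   LOOCV correlation), `predictions` (LOOCV predictions of the final set)
#'   and `trajectory` (data.frame `step`, `feature`, `r`).
#' @export
greedy_select <- function(X, y, ranked, config = gbrt_config(), tol = 1e-4) {
  pool <- if (is.data.frame(ranked)) ranked$feature else as.character(ranked)
  if (!length(pool)) stop("ranked feature pool is empty")
  X <- as_feature_matrix(X)
  score <- function(feats) {
    preds <- loocv(X[, feats, drop = FALSE], y, config = config)
    r <- tryCatch(pearson_r(preds, y), error = function(e) -Inf)
    list(r = r, preds = preds)
  }
  selected <- pool[1]
  cur <- score(selected)
  traj <- data.frame(step = 1L, feature = pool[1], r = cur$r,
                     stringsAsFactors = FALSE)
  remaining <- setdiff(pool, selected)
  while (length(remaining)) {
    cand <- lapply(remaining, function(f) score(c(selected, f)))
    rs <- vapply(cand, `[[`, numeric(1), "r")
    best <- which.max(rs)
    if (rs[best] <= cur$r + tol) break
    selected <- c(selected, remaining[best])
    cur <- cand[[best]]
    traj <- rbind(traj, data.frame(step = nrow(traj) + 1L,
                                   feature = remaining[best], r = cur$r,
                                   stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, remaining[best])
  }
  list(selected = selected, r = cur$r, predictions = cur$preds, trajectory = traj)
}

#' Evaluate held-out predictions
#'
#' @param predictions Held-out (e.g. LOOCV) predictions.
#' @param actual Observed values.
#' @return A list with `pearson_r`, `mae`, `r2`, `n`.
#' @export
evaluation_metrics <- function(predictions, actual) {
  list(pearson_r = pearson_r(predictions, actual),
       mae = mae(predictions, actual),
       r2 = r2(predictions, actual),
       n = length(actual))
}
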