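#' Configuration for the gradient boosted regression tree learner
#'
#' @param n_trees Number of boosting stages `M` (`>= 0`).
#' @param shrinkage Learning rate `nu` in `(0, 1]`; each stage's contribution
#'   is scaled by this factor.
#' @param max_depth Depth of each regression tree (a depth-`d` tree has at
#'   most `2^d` leaves).
#' @param min_samples_leaf Minimum samples per leaf.
#' @param loss Loss function; only half squared error is supported
#'   (`Psi(y, F) = (y - F)^2 / 2`), for which the pseudo-residual is the
#'   ordinary residual and the line search is closed-form.
#' @param seed Recorded in the config for provenance.  The learner itself is
#'   deterministic: split thresholds are midpoints between consecutive
#'   distinct sorted feature values and SSE ties break to the lowest feature
#'   index, then lowest threshold.
#' @return A `gbrt_config` list.
#' @export
gbrt_config <- function(n_trees = 500, shrinkage = 0.1, max_depth = 3,
                        min_samples_leaf = 1, loss = "half_squared_error",
                        seed = 1L) {
  if (n_trees < 0) stop("n_trees must be >= 0")
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]")
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (min_samples_leaf < 1) stop("min_samples_leaf must be >= 1")
  loss <- match.arg(loss, "half_squared_error")
  structure(list(n_trees = as.integer(n_trees), shrinkage = shrinkage,
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 loss = loss, seed = as.integer(seed)),
            class = "gbrt_config")
}

#' Pseudo-residuals (negative loss gradient)
#'
#' For half-squared-error loss the negative gradient of `Psi(y, F)` with
#' respect to `F`, evaluated at the current predictions, is simply `y - f`.
#'
#' @param y Observed targets.
#' @param f Current model predictions, same length as `y`.
#' @param loss Loss name (only `half_squared_error`).
#' @return Numeric vector of per-sample gradients.
#' @export
pseudo_residuals <- function(y, f, loss = "half_squared_error") {
  match.arg(loss, "half_squared_error")
  if (length(y) != length(f)) stop("y and f must have the same length")
  if (!length(y)) stop("empty target vector")
  y - f
}

#' Fit a single least-squares regression tree
#'
#' Greedy top-down CART: each node takes the (feature, threshold) split
#' minimising the summed within-child squared deviation, until the depth
#' limit is reached or no admissible split strictly improves the node SSE.
#' Leaf values are the mean target in the leaf.  Constant targets give a
#' single-leaf tree.
#'
#' @param X Numeric feature matrix (n x p), no missing values.
#' @param targets Numeric response (typically pseudo-residuals).
#' @param max_depth,min_samples_leaf Tree-shape limits.
#' @return A `gbrt_tree`: parallel node vectors `feature` (1-based, `NA` at
#'   leaves), `threshold`, `value`, `left`, `right`, plus `n_leaves` and the
#'   in-sample `fitted` values.
#' @export
fit_tree <- function(X, targets, max_depth = 3, min_samples_leaf = 1) {
  X <- as_feature_matrix(X)
  targets <- as.numeric(targets)
  if (nrow(X) != length(targets)) stop("X rows and targets length differ")
  if (anyNA(X) || anyNA(targets)) stop("missing values are not allowed")
  if (nrow(X) < 2 * min_samples_leaf) {
    stop("need at least 2 * min_samples_leaf = ", 2 * min_samples_leaf, " samples")
  }
  tree <- cpp_fit_tree(X, targets, as.integer(max_depth), as.integer(min_samples_leaf))
  structure(tree, class = "gbrt_tree")
}

#' @export
predict.gbrt_tree <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  cpp_predict_tree(object$feature, object$threshold, object$value,
                   object$left, object$right, X)
}

#' Closed-form line search for the stage weight
#'
#' The stage weight `beta_m` minimises
#' `sum_i Psi(y_i, f_prev_i + beta * h_i)`; for half-squared-error loss the
#' minimiser is `sum(h * (y - f_prev)) / sum(h^2)`, with the convention
#' `beta_m = 0` when the tree predictions are all zero.  When leaf values are
#' the mean pseudo-residuals (as here), this evaluates to 1; it is computed
#' and stored anyway so alternative leaf-value rules keep working.
#'
#' @param y Targets.
#' @param f_prev Predictions before this stage.
#' @param tree_predictions Stage tree predictions `h`.
#' @param loss Loss name.
#' @return Scalar weight `beta_m`.
#' @export
line_search_weight <- function(y, f_prev, tree_predictions,
                               loss = "half_squared_error") {
  match.arg(loss, "half_squared_error")
  if (length(y) != length(f_prev) || length(y) != length(tree_predictions)) {
    stop("inputs must have the same length")
  }
  den <- sum(tree_predictions^2)
  if (den == 0) return(0)
  sum(tree_predictions * (y - f_prev)) / den
}

#' Fit a gradient boosted regression tree model
#'
#' Stagewise boosting with half-squared-error loss: the initial constant
#' `beta0` is the target mean; each of `M` stages fits a fixed-size
#' regression tree to the current pseudo-residuals, computes the line-search
#' weight `beta_m`, and updates the model by `nu * beta_m` times the tree.
#' With `n_trees = 0` the model predicts `beta0` everywhere.
#'
#' @param X Numeric feature matrix or data.frame (no missing values).
#' @param y Numeric targets.
#' @param config A [gbrt_config()].
#' @return A `gbrt_model` with `beta0`, `trees`, `beta` (stage weights),
#'   `train_loss` (half-SSE after each stage), `fitted`, `feature_names` and
#'   `config`.
#' @export
fit_gbrt <- function(X, y, config = gbrt_config()) {
  stopifnot(inherits(config, "gbrt_config"))
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (length(y) < 2) stop("need at least 2 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed at fit time")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- cpp_fit_gbrt(X, y, config$n_trees, config$shrinkage,
                      config$max_depth, config$min_samples_leaf)
  fit$trees <- lapply(fit$trees, function(t) structure(t, class = "gbrt_tree"))
  structure(list(beta0 = fit$beta0, trees = fit$trees, beta = fit$beta,
                 train_loss = fit$train_loss, fitted = fit$fitted,
                 feature_names = colnames(X), config = config),
            class = "gbrt_model")
}

#' Predict binding affinity with a fitted GBRT model
#'
#' `F(x) = beta0 + sum_m nu * beta_m * h_m(x)`.
#'
#' @param object A `gbrt_model`.
#' @param newdata Feature matrix/data.frame with the model's features (by
#'   name when named, else by position with matching arity).
#' @param n_trees Use only the first `n_trees` stages (default: all).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gbrt_model <- function(object, newdata, n_trees = NULL, ...) {
  X <- as_feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    missing <- setdiff(object$feature_names, colnames(X))
    if (length(missing)) {
      stop("newdata lacks model features: ", paste(missing, collapse = ", "))
    }
    X <- X[, object$feature_names, drop = FALSE]
  } else if (ncol(X) != length(object$feature_names)) {
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object$feature_names))
  }
  if (anyNA(X)) stop("missing values in newdata")
  m <- if (is.null(n_trees)) length(object$trees) else min(n_trees, length(object$trees))
  out <- rep(object$beta0, nrow(X))
  nu <- object$config$shrinkage
  for (k in seq_len(m)) {
    out <- out + nu * object$beta[k] * predict(object$trees[[k]], X)
  }
  out
}

#' Serialize a GBRT model to JSON
#'
#' Writes a versioned, self-contained JSON document (initial constant,
#' shrinkage, stage weights, per-tree node records, feature names, config).
#' Serialization is deterministic: the same model yields byte-identical
#' output.
#'
#' @param model A `gbrt_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
gbrt_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "gbrt_model"))
  doc <- list(
    format = "prbind-gbrt", format_version = 1L,
    beta0 = model$beta0,
    shrinkage = model$config$shrinkage,
    beta = as.numeric(model$beta),
    feature_names = as.character(model$feature_names),
    config = unclass(model$config),
    trees = lapply(model$trees, function(t) {
      list(feature = as.integer(t$feature), threshold = as.numeric(t$threshold),
           value = as.numeric(t$value), left = as.integer(t$left),
           right = as.integer(t$right))
    })
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Deserialize a GBRT model from JSON
#'
#' @param json JSON string or path to a file written by [gbrt_to_json()].
#' @return A `gbrt_model`.
#' @export
gbrt_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(doc$format, "prbind-gbrt")) stop("not a prbind GBRT model document")
  cfg <- do.call(gbrt_config, doc$config[c("n_trees", "shrinkage", "max_depth",
                                           "min_samples_leaf", "loss", "seed")])
  trees <- lapply(doc$trees, function(t) {
    structure(list(
      feature = vapply(t$feature, function(v) if (is.null(v)) NA_integer_ else as.integer(v), 1L),
      threshold = vapply(t$threshold, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 1.0),
      value = as.numeric(unlist(t$value)),
      left = vapply(t$left, function(v) if (is.null(v)) NA_integer_ else as.integer(v), 1L),
      right = vapply(t$right, function(v) if (is.null(v)) NA_integer_ else as.integer(v), 1L)
    ), class = "gbrt_tree")
  })
  structure(list(beta0 = doc$beta0, trees = trees, beta = as.numeric(unlist(doc$beta)),
                 train_loss = NULL, fitted = NULL,
                 feature_names = as.character(unlist(doc$feature_names)),
                 config = cfg),
            class = "gbrt_model")
}

#' @export
print.gbrt_model <- function(x, ...) {
  cat("gbrt_model:", length(x$trees), "trees, shrinkage", x$config$shrinkage,
      ", depth", x$config$max_depth, "\n")
  cat("  beta0 =", signif(x$beta0, 6), "; features:",
      paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1)
  if (!is.matrix(X) || !is.numeric(X)) stop("features must be a numeric matrix")
  storage.mode(X) <- "double"
  X
}
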