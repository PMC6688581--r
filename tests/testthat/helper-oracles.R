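# Independent oracles used by the learner tests: a naive recursive CART in
# plain R (exhaustive split enumeration at every node) and its predictor.
# Kept deliberately simple and separate from the package implementation.

naive_cart <- function(X, y, depth, min_leaf = 1) {
  grow <- function(idx, d) {
    node <- list(value = mean(y[idx]))
    if (d <= 0 || length(idx) < 2 * min_leaf) return(node)
    if (sum((y[idx] - mean(y[idx]))^2) < 1e-14) return(node)
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[idx, j]))
      if (length(xs) < 2) next
      for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
        li <- idx[X[idx, j] <= thr]
        ri <- idx[X[idx, j] > thr]
        if (length(li) < min_leaf || length(ri) < min_leaf) next
        sse <- sum((y[li] - mean(y[li]))^2) + sum((y[ri] - mean(y[ri]))^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(sse = sse, j = j, thr = thr, li = li, ri = ri)
        }
      }
    }
    if (is.null(best)) return(node)
    if (!(best$sse < sum((y[idx] - mean(y[idx]))^2))) return(node)
    node$j <- best$j
    node$thr <- best$thr
    node$l <- grow(best$li, d - 1)
    node$r <- grow(best$ri, d - 1)
    node
  }
  grow(seq_along(y), depth)
}

predict_naive_cart <- function(node, X) {
  apply(X, 1, function(x) {
    cur <- node
    while (!is.null(cur$j)) cur <- if (x[cur$j] <= cur$thr) cur$l else cur$r
    cur$value
  })
}

# trainer returning a constant (mean) predictor, for LOOCV protocol tests
constant_trainer <- function(X, y) structure(list(mu = mean(y)), class = "const_model")
predict.const_model <- function(object, newdata, ...) rep(object$mu, nrow(newdata))
registerS3method("predict", "const_model", predict.const_model)

# trainer that memorises its training rows exactly
memorizing_trainer <- function(X, y) {
  structure(list(X = X, y = y), class = "memo_model")
}
predict.memo_model <- function(object, newdata, ...) {
  apply(newdata, 1, function(x) {
    hit <- which(apply(object$X, 1, function(r) all(r == x)))
    if (length(hit)) object$y[hit[1]] else mean(object$y)
  })
}
registerS3method("predict", "memo_model", predict.memo_model)
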