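# Minimal linear SVM (L2-regularized squared hinge, one-vs-one multiclass).
# Inputs here are tiny (3-D second-layer coordinates), so the smooth primal
# is solved directly with BFGS; no external SVM library is required.

svm_binary_fit <- function(X, y, C = 1) {
  # y in {-1, +1}; returns c(w, b)
  d <- ncol(X)
  obj <- function(th) {
    w <- th[1:d]; b <- th[d + 1]
    m <- 1 - y * (X %*% w + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[1:d]; b <- th[d + 1]
    m <- as.vector(1 - y * (X %*% w + b))
    act <- m > 0
    gw <- w - 2 * C * colSums((y * m * act) * X)
    gb <- -2 * C * sum(y * m * act)
    c(gw, gb)
  }
  stats::optim(rep(0, d + 1), obj, grad, method = "BFGS",
               control = list(maxit = 200))$par
}

#' Fit a linear one-vs-one support vector machine
#'
#' Linear maximum-margin classifier (squared-hinge primal, solved by BFGS)
#' with one-vs-one voting for multiclass problems.
#'
#' @param X numeric matrix (observations x features).
#' @param y class labels (factor or coercible).
#' @param C misclassification cost (default 1).
#' @return object of class \code{linear_svm}.
#' @export
linear_svm <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  lv <- levels(y)
  if (length(lv) < 2) stop("need at least 2 classes")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    sel <- y %in% p
    yy <- ifelse(y[sel] == p[1], 1, -1)
    svm_binary_fit(X[sel, , drop = FALSE], yy, C)
  })
  structure(list(models = models, pairs = pairs, levels = lv, C = C,
                 d = ncol(X)), class = "linear_svm")
}

#' @rdname linear_svm
#' @param object a \code{linear_svm}.
#' @param newdata matrix of observations to classify.
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0, nrow(newdata), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (k in seq_along(object$models)) {
    th <- object$models[[k]]
    sc <- as.vector(newdata %*% th[1:object$d] + th[object$d + 1])
    p <- object$pairs[[k]]
    votes[, p[1]] <- votes[, p[1]] + (sc >= 0)
    votes[, p[2]] <- votes[, p[2]] + (sc < 0)
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}
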