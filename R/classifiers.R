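#' Sparse inverse-covariance (precision) estimation
#'
#' Solves the l1-penalised Gaussian maximum-likelihood problem
#' \deqn{\max_{C \succ 0} \; \log\det C - \mathrm{tr}(SC) - \lambda \|C\|_1}
#' where the penalty is the elementwise (vector) l1 norm over *all* entries
#' of `C` (set `penalize_diag = FALSE` for the off-diagonal-only variant).
#' The Laplace-prior interpretation of the penalty makes `lambda` the
#' inverse scale of an elementwise prior on the precision entries.
#'
#' Optimisation is proximal gradient (ISTA) on the equivalent minimisation
#' with backtracking line search that maintains positive definiteness; the
#' soft-threshold step yields exact zeros. Convergence is certified by the
#' duality gap: the primal objective minus the dual value
#' `log det W + p` at the entrywise box projection of `C^-1` onto the dual
#' feasible set `{W : |W - S|_inf <= lambda}`; iteration stops once the gap
#' is at most `tol`.
#'
#' @param S symmetric positive semidefinite covariance matrix.
#' @param lambda penalty weight, >= 0 (> 0 required when `S` is singular).
#' @param tol duality-gap tolerance (default 1e-5).
#' @param penalize_diag penalise the diagonal as well (default TRUE).
#' @param max_iter iteration cap.
#' @return the estimated precision matrix, with attributes `gap`,
#'   `iterations`, `lambda`.
#' @export
fit_sparse_precision <- function(S, lambda, tol = 1e-5, penalize_diag = TRUE,
                                 max_iter = 5000L) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (ncol(S) != p || max(abs(S - t(S))) > 1e-8) {
    stop("S must be a symmetric matrix")
  }
  S <- (S + t(S)) / 2
  if (lambda < 0) stop("lambda must be nonnegative")
  if (lambda == 0) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < p * 1e-12 * max(ev)) {
      stop("lambda > 0 is required when S is singular")
    }
  }

  soft <- function(M, thr) {
    out <- sign(M) * pmax(abs(M) - thr, 0)
    if (!penalize_diag) diag(out) <- diag(M)
    out
  }
  penalty <- function(C) {
    if (penalize_diag) lambda * sum(abs(C)) else lambda * (sum(abs(C)) - sum(abs(diag(C))))
  }
  # smooth part g(C) = -logdet C + tr(SC); returns Inf outside the PD cone
  smooth_val <- function(C) {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    list(val = -2 * sum(log(diag(ch))) + sum(S * C), chol = ch)
  }
  # dual value at the box projection of C^-1 onto the feasible set
  # {W : |W - S|_inf <= lambda} (diagonal fixed at S when unpenalised);
  # -Inf when the projection leaves the PD cone.
  dual_val <- function(Cinv) {
    U <- pmin(pmax(Cinv - S, -lambda), lambda)
    if (!penalize_diag) diag(U) <- 0
    W <- S + U
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    2 * sum(log(diag(ch))) + p
  }

  C <- diag(1 / (diag(S) + lambda), p)
  sv <- smooth_val(C)
  step <- 1 / max(diag(S) + lambda)^2
  gap <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Cinv <- chol2inv(sv$chol)
    grad <- S - Cinv

    gap <- (sv$val + penalty(C)) - dual_val(Cinv)
    if (gap <= tol) break

    # backtracking proximal step
    repeat {
      Cn <- soft(C - step * grad, step * lambda)
      Cn <- (Cn + t(Cn)) / 2
      svn <- smooth_val(Cn)
      if (is.finite(svn$val)) {
        dC <- Cn - C
        if (svn$val <= sv$val + sum(grad * dC) + sum(dC^2) / (2 * step)) break
      }
      step <- step / 2
      if (step < 1e-18) stop("line search failed; gap = ", format(gap))
    }
    C <- Cn
    sv <- svn
    step <- step * 1.2
  }
  if (gap > tol) {
    stop(sprintf(
      "sparse precision solver did not reach tol %.1e in %d iterations (gap %.3e)",
      tol, max_iter, gap
    ))
  }
  attr(C, "gap") <- gap
  attr(C, "iterations") <- it
  attr(C, "lambda") <- lambda
  C
}

variance_floor <- function(x) {
  # per-feature floor keyed to the overall feature variance; keeps constant
  # in-fold features from producing zero-variance Gaussians
  v <- apply(x, 2L, stats::var)
  pmax(1e-9 * max(v, 1e-12), 1e-12)
}

#' Gaussian naive Bayes
#'
#' Per-class, per-feature means and variances (with a small variance floor)
#' and equal class priors.
#'
#' @param x `samples x features` matrix.
#' @param labels class label per sample (two classes).
#' @return a `gnb_model`.
#' @export
fit_gnb <- function(x, labels) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("training data contain a single class")
  floor_v <- variance_floor(x)
  per_class <- lapply(classes, function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    list(mean = colMeans(xi), var = pmax(apply(xi, 2L, stats::var), floor_v))
  })
  names(per_class) <- classes
  structure(
    list(classes = classes, per_class = per_class,
         prior = stats::setNames(rep(1 / length(classes), length(classes)), classes)),
    class = "gnb_model"
  )
}

#' @export
predict.gnb_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- vapply(object$classes, function(cl) {
    pc <- object$per_class[[cl]]
    dev <- sweep(newdata, 2L, pc$mean)
    ll <- sweep(dev^2, 2L, 2 * pc$var, "/") +
      matrix(0.5 * log(2 * pi * pc$var), nrow(newdata), ncol(newdata),
             byrow = TRUE)
    -rowSums(ll) + log(object$prior[[cl]])
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  # ties resolve to the lexicographically first class
  object$classes[apply(scores, 1L, which.max)]
}

#' Linear max-margin classifier
#'
#' An l2-regularised hinge-loss linear separator: libsvm (via e1071) with a
#' linear kernel at the default cost constant, no input scaling.
#'
#' @param x `samples x features` matrix.
#' @param labels class label per sample (two classes).
#' @param cost regularisation constant (libsvm default 1).
#' @return a `linear_margin_model` wrapping the fitted svm.
#' @export
fit_linear_margin <- function(x, labels, cost = 1) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("training data contain a single class")
  fit <- e1071::svm(as.matrix(x), labels, kernel = "linear", cost = cost,
                    scale = FALSE)
  structure(list(svm = fit, classes = levels(labels)),
            class = "linear_margin_model")
}

#' @export
predict.linear_margin_model <- function(object, newdata, ...) {
  as.character(predict(object$svm, as.matrix(newdata)))
}

#' Sparse Gaussian MRF classifier
#'
#' For each class, centres the training features, forms the
#' maximum-likelihood (1/n) empirical covariance, and estimates a sparse
#' precision matrix via [fit_sparse_precision()] with a shared penalty
#' `lambda`. Prediction assigns the class with the larger Gaussian
#' log-likelihood (equal priors).
#'
#' @param x `samples x features` matrix (features should be pre-reduced;
#'   covariance is estimated from few samples).
#' @param labels class label per sample (two classes).
#' @param lambda l1 penalty shared across classes.
#' @param tol duality-gap tolerance passed to the solver.
#' @param penalize_diag see [fit_sparse_precision()].
#' @return a `gmrf_model` with per-class `mean`, `precision`, `covariance`,
#'   and solver diagnostics.
#' @export
fit_gmrf <- function(x, labels, lambda = 0.1, tol = 1e-5,
                     penalize_diag = TRUE) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("training data contain a single class")
  per_class <- lapply(classes, function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    xc <- sweep(xi, 2L, mu)
    S <- crossprod(xc) / nrow(xc)
    C <- fit_sparse_precision(S, lambda, tol = tol,
                              penalize_diag = penalize_diag)
    list(mean = mu, precision = C, covariance = S,
         gap = attr(C, "gap"), iterations = attr(C, "iterations"))
  })
  names(per_class) <- classes
  structure(
    list(classes = classes, per_class = per_class, lambda = lambda,
         prior = stats::setNames(rep(1 / length(classes), length(classes)), classes)),
    class = "gmrf_model"
  )
}

#' @export
predict.gmrf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$per_class[[1]]$mean)) {
    stop("feature count does not match the model")
  }
  scores <- vapply(object$classes, function(cl) {
    pc <- object$per_class[[cl]]
    ld <- determinant(pc$precision, logarithm = TRUE)$modulus
    xc <- sweep(newdata, 2L, pc$mean)
    quad <- rowSums((xc %*% pc$precision) * xc)
    drop(0.5 * ld - 0.5 * quad + log(object$prior[[cl]]))
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  object$classes[apply(scores, 1L, which.max)]
}

#' Fit one of the study's classifiers
#'
#' Dispatcher over the three classifier families compared in the pipeline.
#'
#' @param train a [feature_table()] (or a plain matrix, with `labels`).
#' @param kind `"gnb"`, `"linear_margin"`, or `"gmrf"`.
#' @param labels required when `train` is a matrix.
#' @param ... passed to the specific fitter (e.g. `lambda` for gmrf, `cost`
#'   for the linear margin).
#' @return a fitted model with a `predict()` method returning labels.
#' @export
fit_classifier <- function(train, kind = c("gnb", "linear_margin", "gmrf"),
                           labels = NULL, ...) {
  kind <- match.arg(kind)
  if (inherits(train, "feature_table")) {
    x <- train$values
    labels <- train$labels
  } else {
    x <- as.matrix(train)
    if (is.null(labels)) stop("labels required when train is a matrix")
  }
  switch(kind,
    gnb = fit_gnb(x, labels),
    linear_margin = fit_linear_margin(x, labels, ...),
    gmrf = fit_gmrf(x, labels, ...)
  )
}
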