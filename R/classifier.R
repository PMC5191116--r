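## Import vector machine: sparse kernel logistic regression with greedy
## forward selection of import points.

.sigmoid <- function(f) 1 / (1 + exp(-f))

# regularized negative log-likelihood; f = b + K %*% alpha
.ivmNll <- function(f, y, alpha, Kss, lambda) {
  # numerically safe -log p(y | f)
  nll <- sum(log1p(exp(-abs(f))) + pmax(f, 0) - y * f)
  nll + 0.5 * lambda * drop(crossprod(alpha, Kss %*% alpha))
}

.rbfKernel <- function(A, B, gamma) {
  # exp(-gamma ||a - b||^2) via the inner-product expansion (BLAS-bound)
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# joint Newton refit of (alpha, bias) for a fixed import set
.ivmRefit <- function(Kts, Kss, y, lambda, alpha, bias, maxIter = 25, tol = 1e-9) {
  s <- length(alpha)
  f <- drop(bias + Kts %*% alpha)
  obj <- .ivmNll(f, y, alpha, Kss, lambda)
  for (it in seq_len(maxIter)) {
    p <- .sigmoid(f)
    w <- pmax(p * (1 - p), 1e-10)
    g <- c(crossprod(Kts, p - y) + lambda * Kss %*% alpha, sum(p - y))
    H <- matrix(0, s + 1, s + 1)
    KtW <- Kts * w
    H[1:s, 1:s] <- crossprod(Kts, KtW) + lambda * Kss
    H[1:s, s + 1] <- colSums(KtW)
    H[s + 1, 1:s] <- H[1:s, s + 1]
    H[s + 1, s + 1] <- sum(w)
    diag(H) <- diag(H) + 1e-10
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking line search on the objective
    t <- 1
    repeat {
      aNew <- alpha - t * step[1:s]
      bNew <- bias - t * step[s + 1]
      fNew <- drop(bNew + Kts %*% aNew)
      objNew <- .ivmNll(fNew, y, aNew, Kss, lambda)
      if (objNew <= obj + 1e-12 || t < 1e-4) break
      t <- t / 2
    }
    improved <- obj - objNew
    alpha <- aNew; bias <- bNew; f <- fNew; obj <- objNew
    if (improved < tol * (abs(obj) + 1)) break
  }
  list(alpha = alpha, bias = bias, f = f, obj = obj)
}

#' Train an import vector machine
#'
#' Fits sparse kernel logistic regression by greedy forward selection of
#' import points: starting from the intercept-only model, candidate
#' training points (a seeded random subsample per step) are scored by the
#' second-order decrease in the regularized negative log-likelihood that a
#' single Newton step on their kernel weight would achieve; the best
#' candidate is added and all weights are refit jointly by Newton's method.
#' Selection stops when the relative objective improvement falls below
#' \code{tol} or the import budget is reached. Features are standardized
#' internally; the RBF kernel operates on standardized features.
#'
#' @param features T x p feature matrix (e.g. from [computeFeatures()]).
#' @param labels integer vector in \{0, 1\} (0 = canopy, 1 = grape bunch);
#'   both classes must be present with at least 10 points each.
#' @param gamma RBF bandwidth; \code{NULL} (default) sets
#'   1 / (p * median per-feature variance of standardized columns).
#' @param lambda ridge penalty on the kernel weights (default 1e-3).
#' @param maxImport import point budget (default 200).
#' @param tol relative-improvement stopping tolerance (default 1e-4).
#' @param nCandidates candidate points scored per selection step
#'   (default 100).
#' @param seed RNG seed for candidate subsampling.
#' @return An [IvmModel-class].
#' @seealso [predictIVM()], [assignLabels()]
#' @export
trainIVM <- function(features, labels, gamma = NULL, lambda = 1e-3,
                     maxImport = 200, tol = 1e-4, nCandidates = 100,
                     seed = 1) {
  X <- unclass(as.matrix(features))
  attr(X, "valid") <- NULL
  y <- as.integer(labels)
  if (!all(y %in% 0:1)) stop("labels must be 0 or 1")
  if (min(table(factor(y, 0:1))) < 10) stop("need at least 10 points per class")
  if (any(!is.finite(X))) stop("features must be finite")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be > 0")
  if (lambda <= 0) stop("lambda must be > 0")

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (is.null(gamma)) {
    v <- apply(Xs, 2, stats::var)
    mv <- stats::median(v[v > 1e-12])
    if (!is.finite(mv) || mv <= 0) mv <- 1
    gamma <- 1 / (ncol(Xs) * mv)
  }

  Tn <- nrow(Xs)
  if (!is.null(seed)) set.seed(seed)
  imp <- integer(0)
  alpha <- numeric(0)
  bias <- stats::qlogis(mean(y))
  Kts <- matrix(0, Tn, 0)
  Kss <- matrix(0, 0, 0)
  f <- rep(bias, Tn)
  obj <- .ivmNll(f, y, alpha, Kss, lambda)

  for (step in seq_len(maxImport)) {
    pool <- setdiff(seq_len(Tn), imp)
    if (!length(pool)) break
    cand <- if (length(pool) > nCandidates) sample(pool, nCandidates) else pool
    Kcand <- .rbfKernel(Xs, Xs[cand, , drop = FALSE], gamma)  # T x C
    p <- .sigmoid(f)
    w <- pmax(p * (1 - p), 1e-10)
    # one-coordinate Newton decrease for each candidate's new weight
    g <- drop(crossprod(Kcand, p - y))              # gradient wrt new weight
    h <- drop(crossprod(Kcand^2, w)) + lambda * 1   # K(q,q) = 1 for RBF
    score <- g^2 / (2 * h)
    best <- which.max(score)
    q <- cand[best]

    impNew <- c(imp, q)
    KtsNew <- cbind(Kts, Kcand[, best])
    kq <- .rbfKernel(Xs[impNew, , drop = FALSE], Xs[q, , drop = FALSE], gamma)
    KssNew <- rbind(cbind(Kss, kq[-length(kq)]), t(kq))

    fit <- .ivmRefit(KtsNew, KssNew, y, lambda, c(alpha, 0), bias)
    rel <- (obj - fit$obj) / (abs(obj) + 1e-12)
    if (fit$obj >= obj || rel < tol) {
      if (length(imp) > 0) break
      # always accept the first import point so the model is kernelized
    }
    imp <- impNew; Kts <- KtsNew; Kss <- KssNew
    alpha <- fit$alpha; bias <- fit$bias; f <- fit$f
    obj <- fit$obj
  }

  new("IvmModel",
    importPoints = Xs[imp, , drop = FALSE],
    alpha = as.numeric(alpha), bias = as.numeric(bias),
    gamma = gamma, lambda = lambda,
    center = as.numeric(ctr), scale = as.numeric(scl),
    prior = mean(y), nll = obj
  )
}

#' Predict class posterior probabilities
#'
#' Evaluates the fitted kernel expansion for each feature row and returns
#' calibrated posteriors for (canopy, grape bunch). Rows flagged invalid in
#' the feature matrix (undefined normals / too few neighbors) receive the
#' training prior instead, and are marked in the \code{"fallback"}
#' attribute of the result.
#'
#' @param model an [IvmModel-class].
#' @param features N x p matrix, same layout as in training (the
#'   \code{"valid"} attribute of [computeFeatures()] output is honored).
#' @return N x 2 matrix of posteriors with columns \code{canopy},
#'   \code{bunch}; rows sum to 1.
#' @export
predictIVM <- function(model, features) {
  stopifnot(is(model, "IvmModel"))
  X <- unclass(as.matrix(features))
  valid <- attr(features, "valid")
  attr(X, "valid") <- NULL
  if (ncol(X) != length(model@center)) {
    stop("feature width does not match the model")
  }
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, `/`)
  K <- .rbfKernel(Xs, model@importPoints, model@gamma)
  p1 <- .sigmoid(drop(model@bias + K %*% model@alpha))
  if (!is.null(valid) && any(!valid)) {
    p1[!valid] <- model@prior
  }
  out <- cbind(canopy = 1 - p1, bunch = p1)
  attr(out, "fallback") <- if (is.null(valid)) rep(FALSE, nrow(out)) else !valid
  out
}

#' Assign hard labels from posteriors
#'
#' Each point takes the class of highest posterior probability; exact ties
#' go to class 0 (canopy), which is conservative for grape bunch precision.
#'
#' @param posteriors N x 2 matrix of class posteriors.
#' @return integer vector in \{0, 1\}.
#' @export
assignLabels <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (ncol(posteriors) != 2) stop("posteriors must be N x 2")
  as.integer(posteriors[, 2] > posteriors[, 1])
}
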