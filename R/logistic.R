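# Ridge-penalized logistic fitting by Newton / iteratively reweighted least
# squares. This is the numerical core of the sex classifiers: a small ridge
# penalty (default 1e-6 on standardized covariates) keeps the optimum finite
# under the perfect separation that all-female vs male-bearing pregnancies
# inevitably produce at high fetal fraction.

#' Fit a binary ridge-logistic regression
#'
#' Maximizes the binomial log-likelihood minus `lambda/2 * sum(beta_j^2)`
#' over the non-intercept coefficients, by Newton's method (IRLS).
#' Convergence is declared when the penalized-gradient max-norm drops below
#' `1e-8`; after 100 iterations the current iterate is returned with a
#' warning (with `lambda = 0` and separable data this is the expected,
#' still perfectly usable, capped solution). Deterministic given the data.
#'
#' @param x numeric design matrix (no intercept column; one row per sample).
#' @param y 0/1 response (or logical).
#' @param lambda ridge penalty on non-intercept coefficients.
#' @return named coefficient vector, `(Intercept)` first.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), ncol = 1)
#' y <- rbinom(40, 1, plogis(2 * x))
#' fitLogistic(x, y)
#' @export
fitLogistic <- function(x, y, lambda = 1e-6) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (min(sum(y), sum(1 - y)) < 2)
    stop("need at least 2 samples on each side of the partition")
  X <- cbind("(Intercept)" = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(1, p - 1L))
  # penalized negative log-likelihood, numerically safe at saturated eta
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      lambda / 2 * sum(pen * beta^2)
  }
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - lambda * pen * beta
    if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(lambda * pen + 1e-12, p)
    dir <- solve(H, grad)
    # damped Newton: halve the step until the penalized objective improves
    f0 <- nll(beta)
    t <- 1
    for (h in seq_len(40)) {
      if (nll(beta + t * dir) <= f0) break
      t <- t / 2
    }
    beta <- beta + t * dir
  }
  if (!converged && max(abs(grad)) >= 1e-6)
    warning("fitLogistic: gradient ", format(max(abs(grad)), digits = 3),
            " after 100 iterations (likely perfect separation); ",
            "returning capped-iteration solution")
  setNames(drop(beta), colnames(X))
}

#' Fit a 3-class multinomial ridge-logistic regression
#'
#' Full-Newton maximization of the multinomial log-likelihood with a ridge
#' penalty on non-intercept coefficients; softmax over `K - 1` linear
#' predictors against a reference class. Same convergence and capping rules
#' as [fitLogistic()].
#'
#' @param x numeric design matrix (no intercept column).
#' @param y factor or character response.
#' @param reference reference class (zero coefficient vector).
#' @param lambda ridge penalty.
#' @return named list of coefficient vectors, one per non-reference class.
#' @export
fitMultinomial <- function(x, y, reference = "FF", lambda = 1e-6) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- c(reference, sort(setdiff(unique(y), reference)))
  if (!reference %in% y) stop("reference class absent from training labels")
  K <- length(classes)
  if (K < 2) stop("need at least two classes")
  X <- cbind("(Intercept)" = 1, x)
  p <- ncol(X)
  m <- K - 1L
  penDiag <- rep(c(0, rep(1, p - 1L)), m)
  Y <- outer(y, classes[-1], "==") * 1          # n x m indicator
  B <- matrix(0, p, m)                          # coefficients, ref = 0
  probsOf <- function(B) {
    eta <- X %*% B
    mx <- pmax(0, apply(eta, 1, max))
    ee <- exp(eta - mx)
    list(P = ee / (exp(-mx) + rowSums(ee)), eta = eta, mx = mx)
  }
  nll <- function(B) {
    pr <- probsOf(B)
    lin <- rowSums(Y * pr$eta)
    sum(pr$mx + log(exp(-pr$mx) + rowSums(exp(pr$eta - pr$mx))) - lin) +
      lambda / 2 * sum(penDiag * as.vector(B)^2)
  }
  converged <- FALSE
  for (it in seq_len(100)) {
    P <- probsOf(B)$P                           # n x m, P(ref) implicit
    grad <- as.vector(crossprod(X, Y - P)) - lambda * penDiag * as.vector(B)
    if (max(abs(grad)) < 1e-8) { converged <- TRUE; break }
    H <- matrix(0, p * m, p * m)
    for (j in seq_len(m)) for (k in seq_len(m)) {
      w <- if (j == k) pmax(P[, j] * (1 - P[, j]), 1e-10) else -P[, j] * P[, k]
      H[((j - 1) * p + 1):(j * p), ((k - 1) * p + 1):(k * p)] <-
        crossprod(X * w, X)
    }
    H <- H + diag(lambda * penDiag + 1e-12, p * m)
    dir <- matrix(solve(H, grad), p, m)
    f0 <- nll(B)
    t <- 1
    for (h in seq_len(40)) {
      if (nll(B + t * dir) <= f0) break
      t <- t / 2
    }
    B <- B + t * dir
  }
  if (!converged && max(abs(grad)) >= 1e-6)
    warning("fitMultinomial: gradient ", format(max(abs(grad)), digits = 3),
            " after 100 iterations (likely perfect separation); ",
            "returning capped-iteration solution")
  out <- lapply(seq_len(m), function(j) setNames(B[, j], colnames(X)))
  names(out) <- classes[-1]
  out
}

# Softmax probabilities of a multinomial coefficient list over classes
# (reference first); newX is the raw design matrix without intercept.
.multinomProbs <- function(components, reference, newX) {
  X <- cbind(1, as.matrix(newX))
  eta <- vapply(components, function(b) drop(X %*% b),
                numeric(nrow(X)))
  eta <- matrix(eta, nrow = nrow(X))
  mx <- pmax(0, apply(eta, 1, max))
  e0 <- exp(0 - mx)
  ee <- exp(eta - mx)
  denom <- e0 + rowSums(ee)
  probs <- cbind(e0, ee) / denom
  colnames(probs) <- c(reference, names(components))
  probs
}
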