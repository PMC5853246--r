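#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric enumeration: with both margins fixed, the
#' two-sided p-value is the sum of the probabilities of all tables whose
#' hypergeometric probability is at most that of the observed table
#' (within relative tolerance 1e-7), the convention of the classical
#' "probability at most observed" rule.
#'
#' @param m 2x2 matrix (or vector of length 4, column-major) of
#'   nonnegative integer counts.
#' @return Two-sided p-value.  A table with a zero margin carries no
#'   information: p = 1 with a warning.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))   # 1
#' fisher_exact(matrix(c(10, 0, 0, 10), 2)) # 2 / choose(20, 10)
#' @export
fisher_exact <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 4L && any(dim(m) != c(2L, 2L))) m <- matrix(m, 2L, 2L)
  stopifnot(all(dim(m) == c(2L, 2L)))
  if (any(m < 0) || any(m != round(m))) stop("cells must be nonnegative integers")
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  if (r1 == 0 || r2 == 0 || c1 == 0 || (m[1, 2] + m[2, 2]) == 0) {
    warning("zero margin: table carries no information, p = 1")
    return(1)
  }
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values, returned in the input order.  The
#' default is plain Benjamini-Hochberg; \code{method = "storey"} rescales
#' by a Storey-type estimate of the null proportion
#' pi0 = min(1, mean(p > lambda) / (1 - lambda)).
#'
#' @param p vector of p-values in [0, 1].
#' @param method \code{"bh"} (default) or \code{"storey"}.
#' @param lambda tuning parameter of the Storey pi0 estimate.
#' @return Vector of q-values, same length and order as \code{p}.
#' @export
bh_qvalues <- function(p, method = c("bh", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Plain maximum-likelihood binomial logistic fit, Newton-Raphson /
#' Fisher-scoring form, used for the dose-response and carrier-indicator
#' fits of the diagnostic screen.
#'
#' @param x numeric covariate vector (an intercept is always included).
#' @param y binary response (0/1).
#' @param tol convergence tolerance on the coefficient step (default 1e-8).
#' @param maxit maximum iterations (default 100).
#' @return List with \code{coef} (intercept, slope), \code{converged},
#'   \code{separation} (TRUE when the fit diverges towards infinite
#'   coefficients, i.e. complete or quasi-complete separation),
#'   \code{fitted}, \code{iterations}.
#' @export
logistic_irls <- function(x, y, tol = 1e-8, maxit = 100L) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - p)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  separation <- !converged || max(abs(beta)) > 15
  list(coef = c(intercept = unname(beta[1]), slope = unname(beta[2])),
       converged = converged, separation = separation,
       fitted = stats::plogis(eta), iterations = iter)
}

#' Firth bias-reduced logistic regression
#'
#' Penalized-likelihood logistic fit (Jeffreys-prior penalty) used as the
#' fallback when the plain maximum-likelihood fit meets complete or
#' quasi-complete separation, where ML coefficients diverge.  The modified
#' score adds h_i (1/2 - p_i) with h_i the hat-matrix diagonal.
#'
#' @inheritParams logistic_irls
#' @return List with \code{coef}, \code{converged}, \code{iterations}.
#' @export
logistic_firth <- function(x, y, tol = 1e-6, maxit = 200L) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X, X * w)
    XtWXinv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWXinv)) break
    # hat diagonal of W^1/2 X (X'WX)^-1 X' W^1/2
    h <- rowSums((X %*% XtWXinv) * X) * w
    score <- crossprod(X, (y - p) + h * (0.5 - p))
    step <- drop(XtWXinv %*% score)
    # dampen large steps for stability on separated data
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  list(coef = c(intercept = unname(beta[1]), slope = unname(beta[2])),
       converged = converged, iterations = iter)
}
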