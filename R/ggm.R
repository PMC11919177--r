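#' Pearson correlation matrix of a score table
#'
#' @param scores Numeric matrix or data frame of construct scores
#'   (respondents in rows); non-numeric bookkeeping columns (`code`,
#'   `wave`) are dropped.
#' @return Correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(scores) {
  x <- score_matrix(scores)
  if (nrow(x) < ncol(x) + 1)
    stop("need at least p + 1 complete rows to estimate correlations")
  if (anyNA(x)) stop("scores contain missing values")
  cor(x)
}

# coerce score table / matrix to a plain numeric matrix
score_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  keep <- vapply(scores, is.numeric, logical(1))
  keep[names(scores) %in% c("rt_s", "age", "grade")] <- FALSE
  as.matrix(scores[, keep, drop = FALSE])
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Maximizes `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|` (the
#' diagonal is unpenalized) by block coordinate descent.
#'
#' @param S Symmetric positive semi-definite input matrix with unit
#'   diagonal (a correlation matrix).
#' @param lambda Non-negative L1 penalty.
#' @param thr Outer-loop convergence threshold (relative to the mean
#'   absolute off-diagonal of `S`).
#' @param maxit Maximum outer sweeps.
#' @return The estimated precision matrix (symmetric positive definite;
#'   off-diagonal entries below `1e-8` in magnitude are exact zeros).
#' @export
glasso_fit <- function(S, lambda, thr = 1e-8, maxit = 1000) {
  stopifnot(lambda >= 0, isSymmetric(unname(S)))
  fit <- glasso_path_cpp(S, lambda, n = 2, gamma = 0, thr = thr,
                         maxit = maxit)
  if (fit$iters[1] > maxit)
    stop("graphical lasso did not converge in ", maxit,
         " sweeps (lambda = ", lambda, ")")
  K <- fit$K[, , 1]
  dimnames(K) <- dimnames(S)
  K
}

#' Convert a precision matrix to partial correlations
#'
#' `rho_ij = -K_ij / sqrt(K_ii K_jj)`, with the diagonal set to zero.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @return Partial correlation matrix (zero diagonal).
#' @export
precision_to_partial <- function(K) {
  d <- sqrt(diag(K))
  P <- -K / outer(d, d)
  diag(P) <- 0
  P
}

#' Gaussian log-likelihood of a precision matrix
#'
#' `(n/2) (log det K - tr(SK))`; the additive constant
#' `-(np/2) log(2 pi)` is omitted (it does not affect model selection
#' at fixed `p`).
#'
#' @param K Precision matrix.
#' @param S Sample correlation/covariance matrix.
#' @param n Sample size.
#' @return Scalar log-likelihood (up to the stated constant).
#' @export
gaussian_loglik <- function(K, S, n) {
  n / 2 * (determinant(K, logarithm = TRUE)$modulus[[1]] - sum(S * K))
}

#' Extended Bayesian information criterion
#'
#' `EBIC = -2 loglik + E log(n) + 4 gamma E log(p)`, where `E` is the
#' number of nonzero off-diagonal pairs (edges). `gamma = 0` reduces to
#' the BIC; `gamma = 0.5` is the conventional choice balancing
#' sensitivity and specificity.
#'
#' @param loglik Gaussian log-likelihood of the fitted model.
#' @param E Edge count.
#' @param n Sample size.
#' @param p Number of nodes.
#' @param gamma EBIC hyperparameter.
#' @return Scalar EBIC (lower is better).
#' @export
ebic <- function(loglik, E, n, p, gamma = 0.5) {
  -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
}

#' Penalty path for the graphical lasso
#'
#' Logarithmically spaced from `lambda_max` (the largest absolute
#' off-diagonal correlation, at which the estimated graph is empty)
#' down to `ratio * lambda_max`.
#'
#' @param S Correlation matrix.
#' @param path_size Number of penalty values.
#' @param ratio `lambda_min / lambda_max` (default 0.01).
#' @return Decreasing numeric vector of length `path_size`.
#' @export
lambda_path <- function(S, path_size = 100, ratio = 0.01) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (!is.finite(lmax) || lmax <= 0)
    stop("degenerate correlation matrix: no off-diagonal signal")
  exp(seq(log(lmax), log(lmax * ratio), length.out = path_size))
}

# minimal estimator used in resampling loops: scores -> partial cor matrix
estimate_pcor <- function(x, gamma = 0.5, path_size = 100, ratio = 0.01) {
  S <- cor(x)
  lams <- lambda_path(S, path_size, ratio)
  fit <- glasso_path_cpp(S, lams, n = nrow(x), gamma = gamma)
  best <- which.min(fit$ebic)
  W <- precision_to_partial(fit$K[, , best])
  W[abs(W) < 1e-8] <- 0
  dimnames(W) <- dimnames(S)
  list(W = W, best = best, fit = fit, lambdas = lams)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a logarithmic penalty path
#' (`path_size` models, warm-started) on the score correlation matrix
#' and selects the model minimizing the extended BIC with hyperparameter
#' `gamma`. Edge weights are the regularized partial correlations of
#' the selected precision matrix.
#'
#' @param scores Score table or numeric matrix (respondents in rows).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param path_size Number of penalty values on the path (default 100).
#' @param ratio `lambda_min / lambda_max` for the path.
#' @return A `weighted_network` object: `labels`, symmetric weight
#'   matrix `W` (zero diagonal), and `meta` (selected penalty, EBIC
#'   value, sample size, path size, edge count, density).
#' @export
estimate_network <- function(scores, gamma = 0.5, path_size = 100,
                             ratio = 0.01) {
  x <- score_matrix(scores)
  S <- correlation_matrix(x)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("degenerate correlation matrix (not positive definite)")
  est <- estimate_pcor(x, gamma = gamma, path_size = path_size,
                       ratio = ratio)
  weighted_network(est$W, meta = list(
    lambda_selected = est$lambdas[est$best],
    lambda_index = est$best,
    gamma = gamma,
    ebic_value = est$fit$ebic[est$best],
    n = nrow(x),
    path_size = path_size))
}

#' Construct a weighted network object
#'
#' @param W Symmetric weight matrix with zero diagonal and labelled
#'   dimnames; entries are (partial) correlations, `|w| < 1`.
#' @param meta Optional list of estimation metadata.
#' @return A `weighted_network` object.
#' @export
weighted_network <- function(W, meta = list()) {
  stopifnot(isSymmetric(unname(W)), all(abs(diag(W)) < 1e-12),
            all(abs(W) < 1))
  if (is.null(rownames(W)))
    dimnames(W) <- list(paste0("V", seq_len(nrow(W))),
                        paste0("V", seq_len(nrow(W))))
  p <- nrow(W)
  meta$edges <- sum(W[upper.tri(W)] != 0)
  meta$density <- meta$edges / (p * (p - 1) / 2)
  structure(list(labels = rownames(W), W = W, meta = meta),
            class = "weighted_network")
}

#' Edge density of a network
#'
#' Proportion of node pairs with a nonzero estimated weight. (Some
#' psychometric reports label this quantity "sparsity"; it is a
#' density: 19 of 21 edges gives 0.90.)
#'
#' @param net A `weighted_network`.
#' @return Scalar in `[0, 1]`.
#' @export
network_density <- function(net) {
  net$meta$density
}

#' Edge list of a network
#' @param net A `weighted_network`.
#' @return Data frame `node_a`, `node_b`, `weight` for nonzero edges,
#'   pairs in upper-triangle order.
#' @export
edge_list <- function(net) {
  W <- net$W
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(node_a = rownames(W)[ut[, 1]],
             node_b = colnames(W)[ut[, 2]],
             weight = W[ut],
             stringsAsFactors = FALSE)
}

#' @export
print.weighted_network <- function(x, ...) {
  p <- length(x$labels)
  cat("Regularized partial-correlation network: ", p, " nodes, ",
      x$meta$edges, "/", p * (p - 1) / 2, " edges (density ",
      round(x$meta$density, 3), ")\n", sep = "")
  if (!is.null(x$meta$lambda_selected))
    cat("  lambda =", signif(x$meta$lambda_selected, 4),
        "selected by EBIC (gamma =", x$meta$gamma,
        ") at n =", x$meta$n, "\n")
  invisible(x)
}
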