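# Cross-lagged panel network: each wave-2 construct regressed on all
# wave-1 constructs with a lasso penalty, penalty chosen per target by
# k-fold cross-validation (glmnet). Inputs are standardized, so the
# coefficients are standardized cross-lagged effects; the lasso's exact
# zeros are the "small coefficient elimination".

#' Fit a cross-lagged panel network
#'
#' For each wave-2 construct `j`, minimizes
#' `(1/2n) ||X2_j - X1 beta||^2 + lambda ||beta||_1` over all wave-1
#' constructs, with all columns standardized to mean 0 / sd 1 before
#' fitting. The penalty is selected per target by `folds`-fold
#' cross-validation (CV-minimum by default, one-standard-error rule
#' available); fold assignment is drawn deterministically from `seed`.
#' Autoregressive (self) paths are estimated like any other predictor
#' but are flagged downstream and excluded from expected-influence
#' centralities.
#'
#' @param x1,x2 Wave-1 and wave-2 score tables or matrices for the same
#'   respondents in the same row order, identical column labels.
#'   Alternatively `x1` may be a [match_waves()] result, in which case
#'   `x2` is taken from it.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param lambda_rule `"min"` (CV-minimum, default) or `"1se"`.
#' @param lambda Optional fixed penalty (bypasses cross-validation);
#'   `lambda = 0` gives the unpenalized least-squares limit.
#' @param extra_threshold Optional magnitude below which selected
#'   coefficients are additionally zeroed (default 0: the lasso's own
#'   zeros are the only elimination).
#' @return A `directed_network` object: `labels`, coefficient matrix
#'   `B_hat` (entry (i, j) = standardized effect of wave-1 node i on
#'   wave-2 node j), per-target `lambdas`, and `cv` settings.
#' @export
fit_clpn <- function(x1, x2 = NULL, folds = 10, seed = 1L,
                     lambda_rule = c("min", "1se"), lambda = NULL,
                     extra_threshold = 0) {
  lambda_rule <- match.arg(lambda_rule)
  if (inherits(x1, "matched_waves")) {
    x2 <- score_matrix(x1$t2)
    x1 <- score_matrix(x1$t1)
  } else {
    x1 <- score_matrix(x1)
    x2 <- score_matrix(x2)
  }
  stopifnot(nrow(x1) == nrow(x2),
            identical(colnames(x1), colnames(x2)))
  n <- nrow(x1)
  if (is.null(lambda) && n <= folds)
    stop("need more respondents than cross-validation folds")
  labels <- colnames(x1)
  p <- length(labels)
  for (nm in labels) {
    if (sd(x1[, nm]) == 0 || sd(x2[, nm]) == 0)
      stop("zero-variance construct: ", nm)
  }
  z1 <- scale(x1)
  z2 <- scale(x2)
  B_hat <- matrix(0, p, p, dimnames = list(labels, labels))
  lambdas <- setNames(numeric(p), labels)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  for (j in seq_len(p)) {
    y <- z2[, j]
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(z1, y, alpha = 1, foldid = foldid,
                              intercept = FALSE, standardize = FALSE)
      lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
      beta <- as.numeric(stats::coef(cv, s = lam))[-1]
    } else {
      # descending path ending at the requested penalty keeps glmnet's
      # warm starts well-behaved, including the lambda = 0 limit
      lam <- lambda
      lmax <- max(abs(crossprod(z1, y)) / n)
      if (lam >= lmax) {
        path <- c(lam * 1.5, lam)
      } else {
        path <- exp(seq(log(lmax), log(max(lam, lmax * 1e-5)),
                        length.out = 50))
        if (lam < min(path)) path <- c(path, lam)
      }
      fit <- glmnet::glmnet(z1, y, alpha = 1, lambda = path,
                            intercept = FALSE, standardize = FALSE,
                            thresh = 1e-12)
      beta <- as.numeric(stats::coef(fit, s = lam, exact = TRUE, x = z1,
                                     y = y, alpha = 1, intercept = FALSE,
                                     standardize = FALSE,
                                     thresh = 1e-12))[-1]
    }
    beta[abs(beta) <= extra_threshold] <- 0
    B_hat[, j] <- beta
    lambdas[j] <- lam
  }
  structure(list(labels = labels, B_hat = B_hat, lambdas = lambdas,
                 cv = list(folds = folds, rule = lambda_rule,
                           seed = seed, fixed_lambda = lambda),
                 n = n),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  M <- x$B_hat
  diag_n <- sum(diag(M) != 0)
  diag(M) <- 0
  cat("Cross-lagged panel network: ", length(x$labels), " nodes, ",
      sum(M != 0), " cross-lagged edges, ", diag_n,
      " autoregressive paths (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Incoming and outgoing expected influence of a cross-lagged network
#'
#' IEI(j) is the signed sum of cross-lagged effects into wave-2 node j;
#' OEI(i) is the signed sum of effects out of wave-1 node i.
#' Autoregressive paths are excluded.
#'
#' @param net A `directed_network` from [fit_clpn()].
#' @return Data frame with `node`, `iei`, `oei`.
#' @export
clpn_centralities <- function(net) {
  data.frame(node = net$labels,
             iei = expected_influence(net, "in", exclude_self = TRUE),
             oei = expected_influence(net, "out", exclude_self = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Directed prediction table of a cross-lagged network
#'
#' Nonzero directed edges, autoregressive paths flagged, sorted by
#' target label and then by decreasing absolute weight (ties broken by
#' source label), so the ordering does not depend on the input label
#' order.
#'
#' @param net A `directed_network`.
#' @return Data frame with `from`, `to`, `weight`, `autoregressive`.
#' @export
prediction_table <- function(net) {
  B <- net$B_hat
  nz <- which(B != 0, arr.ind = TRUE)
  out <- data.frame(from = net$labels[nz[, 1]],
                    to = net$labels[nz[, 2]],
                    weight = B[nz],
                    stringsAsFactors = FALSE)
  out$autoregressive <- out$from == out$to
  out <- out[order(out$to, -abs(out$weight), out$from), , drop = FALSE]
  rownames(out) <- NULL
  out
}
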