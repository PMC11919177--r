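# Independent oracles used across the suite. These deliberately share no
# code with the package: the graphical-lasso oracle is an ADMM solver of
# the same penalized objective, and the centrality oracles enumerate all
# simple paths exhaustively.

# penalized Gaussian log-likelihood objective (maximized by the
# graphical lasso); diagonal unpenalized
glasso_objective <- function(K, S, lambda) {
  determinant(K, logarithm = TRUE)$modulus[[1]] - sum(S * K) -
    lambda * sum(abs(K[row(K) != col(K)]))
}

# ADMM solver for the same objective: eigenvalue prox for the smooth
# part, soft-thresholding for the penalty
admm_glasso <- function(S, lambda, rho = 1, maxit = 20000, tol = 1e-11) {
  p <- nrow(S)
  Theta <- diag(p); Z <- diag(p); U <- matrix(0, p, p)
  st <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (i in seq_len(maxit)) {
    e <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    th <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Theta <- e$vectors %*% (th * t(e$vectors))
    Z_old <- Z
    A <- Theta + U
    Z <- st(A, lambda / rho)
    diag(Z) <- diag(A)
    U <- U + Theta - Z
    if (max(abs(Theta - Z)) < tol && max(abs(Z - Z_old)) < tol) break
  }
  Theta
}

# random correlation-like PD matrix with unit diagonal
random_pd_corr <- function(p) {
  A <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(A) + diag(p) * 0.5)
}

# exhaustive simple-path enumeration for small weighted graphs;
# returns list(dist, closeness, betweenness) under the 1/|w| metric
enumerate_centrality <- function(W, tol = 1e-9) {
  p <- nrow(W)
  L <- 1 / abs(W)
  L[W == 0] <- Inf
  diag(L) <- Inf
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path, len) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (w in which(is.finite(L[v, ])))
        if (!(w %in% path)) rec(c(path, w), len + L[v, w])
    }
    rec(s, 0)
    res
  }
  dist <- matrix(Inf, p, p)
  diag(dist) <- 0
  btw <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    d <- min(lens)
    dist[s, t] <- dist[t, s] <- d
    short <- ps[lens <= d * (1 + tol) + tol]
    for (v in seq_len(p)) {
      if (v == s || v == t) next
      through <- vapply(short, function(q) v %in% q$path, logical(1))
      btw[v] <- btw[v] + mean(through)
    }
  }
  tot <- rowSums(dist)
  cl <- ifelse(is.finite(tot) & p > 1, 1 / tot, 0)
  list(dist = dist, closeness = cl, betweenness = btw)
}

# random sparse symmetric weight matrix on p nodes (signed weights)
random_weight_matrix <- function(p, edge_prob = 0.6) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < edge_prob) {
      w <- runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
      W[i, j] <- W[j, i] <- w
    }
  }
  dimnames(W) <- list(paste0("V", 1:p), paste0("V", 1:p))
  W
}

# ordinary least-squares cross-lagged coefficients on standardized data
ols_clpn <- function(x1, x2) {
  z1 <- scale(x1); z2 <- scale(x2)
  solve(crossprod(z1), crossprod(z1, z2))
}
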