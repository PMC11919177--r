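test_that("correlation matrix matches hand-computed values", {
  x <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                1, 1, 2, 2), ncol = 3)
  S <- correlation_matrix(x)
  expect_equal(diag(S), rep(1, 3), ignore_attr = TRUE)
  # manual Pearson: deviations (-1.5,-.5,.5,1.5) vs (-.5,-1.5,1.5,.5)
  # give cross-product 3 over sqrt(5 * 5) = 0.6
  expect_equal(S[1, 2], 0.6)
  expect_equal(S[1, 3], cov(x[, 1], x[, 3]) / (sd(x[, 1]) * sd(x[, 3])))
  # identical columns give off-diagonal 1
  expect_equal(correlation_matrix(cbind(x[, 1], x[, 1], x[, 2]))[1, 2], 1)
  # independent columns at n = 10000 have |r| < 0.05
  set.seed(44)
  z <- matrix(rnorm(10000 * 3), ncol = 3)
  Sz <- correlation_matrix(z)
  expect_lt(max(abs(Sz[upper.tri(Sz)])), 0.05)
  expect_error(correlation_matrix(z[1:3, ]), "p \\+ 1")
})

test_that("glasso reduces to the matrix inverse at lambda 0", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  K <- glasso_fit(S, 0)
  expect_equal(K, matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2),
               tolerance = 1e-7)
})

test_that("glasso shrinks to the empty graph at large lambda", {
  set.seed(3)
  S <- random_pd_corr(5)
  lam <- max(abs(S[upper.tri(S)]))
  K <- glasso_fit(S, lam)
  expect_true(all(K[upper.tri(K)] == 0))
  expect_equal(diag(K), 1 / diag(S), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("glasso objective matches the ADMM oracle on small problems", {
  set.seed(17)
  for (p in 2:3) for (lam in c(0, 0.1)) {
    S <- random_pd_corr(p)
    Kg <- glasso_fit(S, lam)
    Ka <- admm_glasso(S, lam)
    expect_lt(abs(glasso_objective(Kg, S, lam) -
                  glasso_objective(Ka, S, lam)), 1e-6)
  }
})

test_that("partial correlations follow the precision-matrix identity", {
  K <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(precision_to_partial(K)[1, 2], 0.5)
  # diagonal K -> all zeros
  expect_true(all(precision_to_partial(diag(c(2, 3, 4))) == 0))
  # any PD K gives |rho| < 1
  set.seed(8)
  for (i in 1:10) {
    A <- matrix(rnorm(16), 4)
    K4 <- crossprod(A) + diag(4) * 0.1
    P <- precision_to_partial(K4)
    expect_lt(max(abs(P)), 1)
    expect_true(isSymmetric(P))
  }
})

test_that("EBIC follows its definition", {
  # loglik = -100, E = 5, n = 100, p = 7, gamma = 0.5:
  # 200 + 5 ln(100) + 10 ln(7) = 242.485
  expect_equal(ebic(-100, 5, 100, 7, 0.5),
               200 + 5 * log(100) + 10 * log(7))
  expect_equal(ebic(-100, 5, 100, 7, 0.5), 242.485, tolerance = 1e-4)
  # gamma = 0 reduces to BIC; E = 0 reduces to -2 loglik
  expect_equal(ebic(-50, 3, 200, 7, 0), 100 + 3 * log(200))
  expect_equal(ebic(-50, 0, 200, 7, 0.5), 100)
})

test_that("EBIC values from the path agree with the R-side formula", {
  set.seed(2)
  x <- sample_two_wave(make_default_truth(), 300, seed = 2)$x1
  S <- cor(x)
  lams <- lambda_path(S, 20)
  fit <- cognet:::glasso_path_cpp(S, lams, n = 300, gamma = 0.5)
  for (m in c(1, 10, 20)) {
    K <- fit$K[, , m]
    E <- sum(K[upper.tri(K)] != 0)
    expect_equal(fit$ebic[m],
                 ebic(gaussian_loglik(K, S, 300), E, 300, 7, 0.5),
                 tolerance = 1e-8)
  }
})

test_that("edge count is non-increasing in lambda along the path", {
  set.seed(13)
  x <- sample_two_wave(make_default_truth(), 400, seed = 13)$x1
  S <- cor(x)
  lams <- lambda_path(S, 50)
  fit <- cognet:::glasso_path_cpp(S, lams, n = 400, gamma = 0.5)
  expect_true(all(diff(fit$edges) >= 0))   # lambdas decrease along path
  # the path starts empty at lambda_max
  expect_equal(fit$edges[1], 0)
})

test_that("network estimation is deterministic and recovers the truth", {
  tr <- make_default_truth()
  x <- sample_two_wave(tr, 5000, seed = 77)$x1
  net1 <- estimate_network(x)
  net2 <- estimate_network(x)
  expect_identical(net1$W, net2$W)
  P <- truth_partial_cor(tr)
  ut <- upper.tri(P)
  # planted edges found, planted zeros (near) absent
  expect_true(all(net1$W[ut][P[ut] != 0] != 0))
  expect_lt(max(abs(net1$W[ut][P[ut] == 0])), 0.05)
  # density bookkeeping is consistent
  expect_equal(net1$meta$density,
               sum(net1$W[ut] != 0) / 21)
  expect_equal(network_density(net1), net1$meta$density)
})

test_that("independent data yields an (almost) empty network", {
  set.seed(99)
  x <- matrix(rnorm(4000 * 7), ncol = 7)
  colnames(x) <- construct_labels()
  net <- estimate_network(x)
  expect_equal(net$meta$edges, 0)
})

test_that("support-recovery F1 improves with sample size", {
  tr <- make_default_truth()
  P <- truth_partial_cor(tr)
  ut <- upper.tri(P)
  truth_e <- P[ut] != 0
  f1 <- function(est_e) {
    tp <- sum(est_e & truth_e)
    if (tp == 0) return(0)
    prec <- tp / sum(est_e); rec <- tp / sum(truth_e)
    2 * prec * rec / (prec + rec)
  }
  med_f1 <- vapply(c(200, 1000, 5000), function(n) {
    scores <- vapply(1:20, function(s) {
      x <- sample_two_wave(tr, n, seed = 1000 + s)$x1
      f1(estimate_network(x)$W[ut] != 0)
    }, numeric(1))
    median(scores)
  }, numeric(1))
  expect_true(all(diff(med_f1) >= 0))
  expect_gte(med_f1[3], 0.8)
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- sample_two_wave(make_default_truth(), 50, seed = 1)$x1
  xx <- cbind(x, dup = x[, 1])
  expect_error(estimate_network(xx), "degenerate")
  expect_error(lambda_path(diag(3)), "degenerate")
})
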