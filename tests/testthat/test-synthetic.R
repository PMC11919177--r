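test_that("default ground truth is valid and deterministic", {
  tr <- make_default_truth()
  expect_s3_class(tr, "network_truth")
  expect_true(isSymmetric(tr$K1))
  ev <- eigen(tr$K1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # planted zeros have exactly zero partial correlation
  P <- truth_partial_cor(tr)
  expect_equal(P["PHQ", "BD"], 0)
  expect_equal(P["NAB", "GAD"], 0)
  # planted edges carry their design values with the design signs
  expect_equal(P["SR", "BD"], 0.40)
  expect_equal(P["PHQ", "GAD"], 0.35)
  expect_identical(make_default_truth(7), make_default_truth(7))
  # all planted contemporaneous edges are at least 0.2 in magnitude
  expect_true(min(abs(P[P != 0])) >= 0.2)
})

test_that("latent sampling matches the implied covariances", {
  tr <- make_default_truth()
  s <- sample_two_wave(tr, 50000, seed = 5)
  expect_lt(max(abs(cov(s$x1) - solve(tr$K1))), 0.03)
  # wave-2 covariance follows B' Sigma1 B + Sigma_e
  S2 <- t(tr$B) %*% solve(tr$K1) %*% tr$B + tr$Sigma_e
  expect_lt(max(abs(cov(s$x2) - S2)), 0.03)
})

test_that("identity transition with vanishing noise reproduces wave 1", {
  tr <- make_default_truth()
  tr$B <- diag(7); dimnames(tr$B) <- dimnames(tr$K1)
  tr$Sigma_e <- diag(1e-12, 7); dimnames(tr$Sigma_e) <- dimnames(tr$K1)
  s <- sample_two_wave(tr, 100, seed = 3)
  expect_lt(max(abs(s$x2 - s$x1)), 1e-4)
  # single row does not error
  s1 <- sample_two_wave(make_default_truth(), 1, seed = 3)
  expect_equal(nrow(s1$x1), 1)
})

test_that("sampling is deterministic under a fixed seed", {
  tr <- make_default_truth()
  expect_identical(sample_two_wave(tr, 20, seed = 9),
                   sample_two_wave(tr, 20, seed = 9))
  r1 <- discretize_to_items(sample_two_wave(tr, 20, seed = 9)$x1, seed = 2)
  r2 <- discretize_to_items(sample_two_wave(tr, 20, seed = 9)$x1, seed = 2)
  expect_identical(r1, r2)
})

test_that("discretization clips, centers, and tracks the latent scores", {
  tr <- make_default_truth()
  im0 <- tr$item_model; im0$noise_sd <- 0
  # latent at the standardized midpoint -> every item at the rounded
  # center of its range, constant across items
  z0 <- matrix(0, 4, 7, dimnames = list(NULL, tr$labels))
  r0 <- discretize_to_items(z0, item_model = im0, seed = 1)
  expect_true(all(r0$anis_1 == 3))
  expect_true(all(r0$atq_5 == 3))
  expect_equal(r0$phq_1, r0$phq_9)
  # extreme negative latent -> clipped at the response minimum
  zneg <- matrix(-50, 3, 7, dimnames = list(NULL, tr$labels))
  rneg <- discretize_to_items(zneg, item_model = im0, seed = 1)
  expect_true(all(rneg$phq_5 == 0))
  expect_true(all(rneg$rrs_10 == 1))
  # rescored totals correlate with the latent scores at default noise
  s <- sample_two_wave(tr, 2000, seed = 12)
  rec <- discretize_to_items(s$x1, item_model = tr$item_model, seed = 13)
  sc <- score_records(rec)
  for (lab in tr$labels)
    expect_gt(cor(sc[[lab]], s$x1[, lab]), 0.8)
})

test_that("violation injection matches its stated rates and ledger", {
  tr <- make_default_truth()
  rec <- discretize_to_items(sample_two_wave(tr, 400, seed = 1)$x1,
                             seed = 2)
  # zero rates: unchanged
  r0 <- inject_qc_violations(rec, c(lie = 0, missing = 0, fast = 0),
                             seed = 3)
  expect_equal(r0, rec, ignore_attr = TRUE)
  expect_equal(nrow(attr(r0, "qc_injections")), 0)
  # missing rate 1: every record has at least one blank item
  r1 <- inject_qc_violations(rec, c(missing = 1), seed = 3)
  items <- grep("^(phq|gad|rrs|anis|atq)_", names(r1), value = TRUE)
  expect_true(all(rowSums(is.na(r1[, items])) >= 1))
  # lie rate 0.1 at n = 5000: injected count within binomial 99% CI
  big <- discretize_to_items(sample_two_wave(tr, 5000, seed = 4)$x1,
                             seed = 5)
  r2 <- inject_qc_violations(big, c(lie = 0.1), seed = 6)
  n_lie <- sum(!r2$lie_ok)
  ci <- qbinom(c(0.005, 0.995), 5000, 0.1)
  expect_gte(n_lie, ci[1])
  expect_lte(n_lie, ci[2])
  expect_equal(n_lie, sum(attr(r2, "qc_injections")$reason == "lie"))
})

test_that("the validity filter removes at least the injected records", {
  tr <- make_default_truth()
  for (seed in 1:3) {
    rec <- discretize_to_items(
      sample_two_wave(tr, 300, seed = seed)$x1, seed = seed + 100)
    bad <- inject_qc_violations(rec, c(lie = 0.05, missing = 0.05,
                                       fast = 0.05), seed = seed + 200)
    out <- apply_qc(bad)
    injected <- unique(attr(bad, "qc_injections")$code)
    # every injected record is gone (chance outliers may add more)
    expect_length(intersect(out$retained$code, injected), 0)
  }
})

test_that("the full study simulation is reproducible end to end", {
  a <- simulate_two_wave_study(n_t1 = 120, n_t2 = 60, seed = 42)
  b <- simulate_two_wave_study(n_t1 = 120, n_t2 = 60, seed = 42)
  expect_identical(a$records_t1, b$records_t1)
  expect_identical(a$records_t2, b$records_t2)
  expect_equal(nrow(a$records_t2), 60)
  expect_true(all(a$records_t2$code %in% a$records_t1$code))
})
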