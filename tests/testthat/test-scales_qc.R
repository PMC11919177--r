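test_that("scale definitions enforce their invariants", {
  expect_error(scale_definition("x", 5, 3, 1), "response_min")
  expect_error(scale_definition("x", 5, 1, 4,
                                subscales = list(a = 1:3, b = 3:5)),
               "disjoint")
  expect_error(scale_definition("x", 5, 1, 4,
                                subscales = list(a = 1:3, b = c(4, 6))),
               "disjoint|n_items")
  sc <- default_scales()
  expect_equal(vapply(sc, `[[`, numeric(1), "n_items"),
               c(phq = 9, gad = 7, rrs = 22, anis = 10, atq = 8))
  expect_equal(sort(unlist(sc$rrs$subscales, use.names = FALSE)), 1:22)
})

test_that("scoring sums items and subscales correctly", {
  r0 <- make_record(levels = c(phq = 0, gad = 0, rrs = 1, anis = 1,
                               atq = 1))
  s0 <- score_records(r0)
  expect_equal(s0$PHQ, 0)                      # all-minimum PHQ
  r4 <- make_record(levels = c(phq = 1, gad = 1, rrs = 4, anis = 1,
                               atq = 1))
  s4 <- score_records(r4)
  expect_equal(s4$SR + s4$BD + s4$RP, 88)      # 22 items x 4
  r1 <- make_record(levels = c(phq = 1, gad = 2, rrs = 2, anis = 3,
                               atq = 3))
  s1 <- score_records(r1)
  expect_equal(s1$PHQ, 9)
  expect_equal(s1$GAD, 14)
  # scores bounded by item count x response bounds
  expect_true(s1$SR >= 12 && s1$SR <= 48)
})

test_that("scoring names the scale and item of a missing response", {
  r <- make_record()
  r$gad_4 <- NA
  expect_error(score_records(r), "gad.*item 4")
})

test_that("scoring is invariant to item order within a subscale map", {
  set.seed(11)
  r <- make_record()
  items <- paste0("rrs_", 1:12)               # SR items
  r[items] <- sample(1:4, 12, replace = TRUE)
  s <- score_records(r)
  perm <- sample(items)
  r2 <- r
  r2[items] <- r[perm]                        # shuffle responses among items
  expect_equal(score_records(r2)$SR, s$SR)
})

test_that("validity filter handles the hand-built five-record fixture", {
  fx <- qc_fixture()
  out <- apply_qc(fx$records, fx$config)
  expect_equal(out$report$n_retained, 1)
  expect_equal(out$retained$code, "E")
  exp_counts <- c(unparseable = 0, lie = 1, missing = 1, fast = 1,
                  age_grade = 0, outlier = 1, demographic = 0)
  expect_equal(out$report$exclusions, exp_counts)
})

test_that("validity filter attributes each record to the first rule hit", {
  fx <- qc_fixture()
  recs <- fx$records
  recs$lie_ok[recs$code == "C"] <- FALSE      # C now fails lie AND speed
  out <- apply_qc(recs, fx$config)
  expect_equal(out$report$exclusions[["lie"]], 2)
  expect_equal(out$report$exclusions[["fast"]], 0)
})

test_that("validity filter conserves counts and passes clean/empty input", {
  clean <- make_records(8)
  out <- apply_qc(clean)
  expect_equal(out$report$n_retained, 8)
  empty <- apply_qc(clean[0, , drop = FALSE])
  expect_equal(empty$report$n_input, 0)
  expect_equal(empty$report$n_retained, 0)
  # conservation on randomly corrupted fixtures
  for (seed in 1:5) {
    recs <- discretize_to_items(
      sample_two_wave(make_default_truth(), 60, seed = seed)$x1,
      seed = seed)
    recs <- inject_qc_violations(recs, c(lie = 0.2, missing = 0.2,
                                         fast = 0.2), seed = seed)
    rep <- apply_qc(recs)$report
    expect_equal(rep$n_input, rep$n_retained + sum(rep$exclusions))
  }
})

test_that("out-of-range responses are excluded as unparseable", {
  r <- make_record()
  r$phq_1 <- 7
  out <- apply_qc(rbind(r, make_record("ok")))
  expect_equal(out$report$exclusions[["unparseable"]], 1)
  expect_equal(out$retained$code, "ok")
})

test_that("wave matching is an inner join with role counts", {
  s1 <- score_records(make_records(3, codes = c("a", "b", "c")))
  s2 <- score_records(make_records(3, codes = c("b", "c", "d")))
  m <- match_waves(s1, s2)
  expect_equal(m$codes, c("b", "c"))
  expect_equal(m$counts, c(t1_only = 1, t2_only = 1, matched = 2))
  # disjoint codes
  s3 <- score_records(make_records(2, codes = c("x", "y")))
  expect_equal(match_waves(s1, s3)$counts[["matched"]], 0)
  # full overlap
  expect_equal(match_waves(s1, s1)$counts[["matched"]], 3)
  # duplicate codes error
  sd <- score_records(make_records(2, codes = c("a", "a")))
  expect_error(match_waves(sd, s2), "duplicate")
})

test_that("prevalence is the fraction at or above the cutoff", {
  sc <- data.frame(PHQ = c(4, 5, 6))
  expect_equal(prevalence(sc, "PHQ", 5), 2 / 3)
  expect_equal(prevalence(sc, "PHQ", 100), 0)
  expect_equal(prevalence(sc, "PHQ", 0), 1)
  expect_error(prevalence(sc, "XYZ", 5), "unknown construct")
})

test_that("paired t statistics match direct computation", {
  s1 <- score_records(make_records(5))
  s2 <- s1
  diffs <- c(1, -1, 2, 0, 3)
  s2$PHQ <- s1$PHQ + diffs
  m <- match_waves(s1, s2)
  ct <- compare_waves(m)
  # d-bar / (s_d / sqrt(n)) = 1 / (1.5811 / 2.2361) = 1.4142
  expect_equal(ct$t[ct$construct == "PHQ"], 1.41421356, tolerance = 1e-6)
  expect_equal(ct$df[ct$construct == "PHQ"], 4)
  # identical columns and constant shifts are degenerate, reported as 0
  expect_true(all(ct$degenerate[ct$construct != "PHQ"]))
  expect_true(all(ct$t[ct$construct != "PHQ"] == 0))
})

test_that("paired t on jittered constant shift matches one-sample t", {
  set.seed(21)
  n <- 30
  x <- rnorm(n, 10, 2)
  shift <- 0.8 + rnorm(n, sd = 0.1)
  s1 <- score_records(make_records(n))
  s1$PHQ <- x
  s2 <- s1
  s2$PHQ <- x + shift
  ct <- compare_waves(match_waves(s1, s2))
  expect_equal(ct$t[ct$construct == "PHQ"],
               unname(t.test(shift)$statistic), tolerance = 1e-10)
})

test_that("independent comparison uses Welch t", {
  set.seed(31)
  a <- score_records(make_records(20, codes = sprintf("a%02d", 1:20)))
  b <- score_records(make_records(25, codes = sprintf("b%02d", 1:25)))
  a$GAD <- rnorm(20, 8, 2)
  b$GAD <- rnorm(25, 9, 3)
  ct <- compare_samples(a, b)
  tt <- t.test(a$GAD, b$GAD)
  row <- ct[ct$construct == "GAD", ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$df, unname(tt$parameter), tolerance = 1e-10)
  # constant-in-both-groups constructs flagged, not errored
  expect_true(all(ct$degenerate[ct$construct != "GAD"]))
  expect_error(compare_samples(a[1, ], b), "at least 2")
})
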