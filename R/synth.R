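#' Ground truth for the synthetic two-wave generator
#'
#' Builds the fixed data-generating model used throughout the package's
#' validation: a sparse symmetric positive-definite precision matrix
#' `K1` for the seven constructs at wave 1 (dense positive partial
#' correlations among the three rumination subscales, a strong
#' depression-anxiety edge, a handful of cognition-symptom edges, and
#' planted zeros elsewhere), a cross-lagged transition matrix `B` with
#' autoregressive diagonal 0.4 and planted cross-lags of known sign
#' (SR to PHQ, NAT to GAD, PHQ to GAD, GAD to SR), diagonal residual
#' covariance `Sigma_e = 0.5 I`, and per-construct item-discretization
#' parameters.
#'
#' The truth is fully deterministic; `seed` is stored so downstream
#' sampling helpers can default to it.
#'
#' @param seed Integer seed recorded in the object (the truth itself
#'   does not depend on it).
#' @return A `network_truth` object with fields `labels`, `K1`, `B`,
#'   `Sigma_e`, `item_model`, `seed`.
#' @export
make_default_truth <- function(seed = 1L) {
  labels <- construct_labels()
  p <- length(labels)
  P <- matrix(0, p, p, dimnames = list(labels, labels))
  edge <- function(a, b, v) { P[a, b] <<- v; P[b, a] <<- v }
  edge("SR", "BD", 0.40); edge("SR", "RP", 0.30); edge("BD", "RP", 0.30)
  edge("PHQ", "GAD", 0.35)
  edge("SR", "PHQ", 0.25); edge("SR", "GAD", 0.20)
  edge("NAT", "PHQ", 0.20); edge("NAT", "GAD", 0.20)
  edge("NAB", "NAT", 0.22)
  K1 <- diag(p) - P                       # unit diagonal => partials = P
  dimnames(K1) <- list(labels, labels)

  B <- diag(0.4, p)
  dimnames(B) <- list(labels, labels)
  B["SR", "PHQ"] <- 0.15
  B["NAT", "GAD"] <- 0.18
  B["PHQ", "GAD"] <- 0.12
  B["GAD", "SR"] <- 0.12

  Sigma_e <- diag(0.5, p)
  dimnames(Sigma_e) <- list(labels, labels)

  item_model <- data.frame(construct = labels, loading = 1,
                           noise_sd = 0.8)

  truth <- structure(
    list(labels = labels, K1 = K1, B = B, Sigma_e = Sigma_e,
         item_model = item_model, seed = as.integer(seed)),
    class = "network_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  K1 <- truth$K1
  if (max(abs(K1 - t(K1))) > 1e-10) stop("K1 must be symmetric")
  ev <- eigen(K1, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("K1 must be positive definite")
  S1 <- solve(K1)
  S2 <- t(truth$B) %*% S1 %*% truth$B + truth$Sigma_e
  ev2 <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) <= 0) stop("implied T2 covariance must be positive definite")
  invisible(truth)
}

#' True partial correlations of the wave-1 model
#' @param truth A [make_default_truth()] object.
#' @return Symmetric matrix of partial correlations, zero diagonal.
#' @export
truth_partial_cor <- function(truth) {
  precision_to_partial(truth$K1)
}

#' @export
print.network_truth <- function(x, ...) {
  pc <- truth_partial_cor(x)
  cat("Synthetic two-wave ground truth:", length(x$labels), "constructs,",
      sum(pc[upper.tri(pc)] != 0), "contemporaneous edges,",
      sum(x$B != 0) - nrow(x$B), "cross-lags\n")
  invisible(x)
}

#' Sample latent construct scores for both waves
#'
#' Wave-1 rows are i.i.d. multivariate normal with mean zero and
#' covariance `solve(K1)`; wave-2 rows follow the linear transition
#' `X2 = X1 B + E` with `E` i.i.d. normal with covariance `Sigma_e`.
#'
#' @param truth A [make_default_truth()] object.
#' @param n Number of respondents (`n >= 1`).
#' @param seed Integer seed.
#' @return List with matrices `x1`, `x2` (`n` by 7, labelled columns).
#' @export
sample_two_wave <- function(truth, n, seed = truth$seed) {
  stopifnot(n >= 1)
  validate_truth(truth)
  p <- length(truth$labels)
  set.seed(seed)
  R1 <- chol(solve(truth$K1))
  Re <- chol(truth$Sigma_e)
  x1 <- matrix(rnorm(n * p), n, p) %*% R1
  x2 <- x1 %*% truth$B + matrix(rnorm(n * p), n, p) %*% Re
  colnames(x1) <- colnames(x2) <- truth$labels
  list(x1 = x1, x2 = x2)
}

#' Discretize latent scores into item-level Likert responses
#'
#' Each item of a construct's scale is generated as
#' `round(clip(center + half * 0.5 * (loading * z + noise)))` where `z`
#' is the respondent's (standardized) latent score, `center`/`half`
#' describe the item's response range, and `noise` is independent
#' normal with the construct's `noise_sd`. Clean quality-control fields
#' (response time, lie check, age, grade, demographics) are attached;
#' use [inject_qc_violations()] to corrupt them.
#'
#' @param latent Matrix of latent scores (columns = construct labels).
#' @param wave Wave label, `"T1"` or `"T2"`.
#' @param codes Respondent codes; defaults to `S00001 ...`.
#' @param scales Scale definitions.
#' @param item_model Per-construct data frame with `construct`,
#'   `loading`, `noise_sd` (as in `truth$item_model`).
#' @param seed Integer seed.
#' @return Data frame of raw records (one row per respondent).
#' @export
discretize_to_items <- function(latent, wave = "T1", codes = NULL,
                                scales = default_scales(),
                                item_model = make_default_truth()$item_model,
                                seed = 1L) {
  n <- nrow(latent)
  if (is.null(codes)) codes <- sprintf("S%05d", seq_len(n))
  set.seed(seed)
  cmap <- construct_map(scales)
  rec <- data.frame(code = codes, wave = wave,
                    stringsAsFactors = FALSE)
  for (lab in names(cmap)) {
    sc <- cmap[[lab]]$scale
    im <- item_model[item_model$construct == lab, ]
    z <- latent[, lab]
    center <- (sc$response_min + sc$response_max) / 2
    half <- (sc$response_max - sc$response_min) / 2
    for (k in cmap[[lab]]$items) {
      pre <- center + half * 0.5 *
        (im$loading * z + rnorm(n, sd = im$noise_sd))
      rec[[paste0(sc$prefix, "_", k)]] <-
        pmin(sc$response_max, pmax(sc$response_min, round(pre)))
    }
  }
  rec$rt_s <- pmax(500, round(rnorm(n, mean = 900, sd = 150)))
  rec$lie_ok <- TRUE
  rec$age <- sample(18:24, n, replace = TRUE,
                    prob = c(0.2, 0.25, 0.25, 0.15, 0.08, 0.05, 0.02))
  rec$grade <- sample(1:4, n, replace = TRUE)
  rec$sex <- sample(c("female", "male"), n, replace = TRUE,
                    prob = c(0.78, 0.22))
  rec$residence <- sample(c("urban", "rural"), n, replace = TRUE,
                          prob = c(0.39, 0.61))
  rec
}

#' Inject quality-control violations into clean records
#'
#' Independently, with the stated per-reason probabilities, flips the
#' lie-check flag, blanks one to three random item responses, or sets
#' the response time below the validity threshold. The affected rows
#' are recorded in the `"qc_injections"` attribute (a data frame with
#' `code` and `reason`) so tests can verify that the validity filter
#' removes exactly the corrupted records.
#'
#' @param records Clean raw records, as from [discretize_to_items()].
#' @param rates Named numeric vector of probabilities; recognized names
#'   are `lie`, `missing`, `fast`.
#' @param seed Integer seed.
#' @param scales Scale definitions (for locating item columns).
#' @return The corrupted records, with the injection ledger attached.
#' @export
inject_qc_violations <- function(records,
                                 rates = c(lie = 0.03, missing = 0.04,
                                           fast = 0.03),
                                 seed = 1L, scales = default_scales()) {
  n <- nrow(records)
  set.seed(seed)
  ledger <- data.frame(code = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  mark <- function(rows, why) {
    if (length(rows))
      ledger <<- rbind(ledger,
                       data.frame(code = records$code[rows], reason = why,
                                  stringsAsFactors = FALSE))
  }
  rate <- function(why) if (why %in% names(rates)) rates[[why]] else 0

  hit <- which(stats::runif(n) < rate("lie"))
  records$lie_ok[hit] <- FALSE
  mark(hit, "lie")

  item_cols <- intersect(unlist(lapply(scales, item_columns)),
                         names(records))
  hit <- which(stats::runif(n) < rate("missing"))
  for (i in hit) {
    k <- sample(length(item_cols), sample(1:3, 1))
    records[i, item_cols[k]] <- NA
  }
  mark(hit, "missing")

  hit <- which(stats::runif(n) < rate("fast"))
  records$rt_s[hit] <- round(stats::runif(length(hit), 60, 470))
  mark(hit, "fast")

  attr(records, "qc_injections") <- ledger
  records
}

#' Simulate a complete two-wave questionnaire study
#'
#' Draws latent scores for `n_t1` respondents, observes wave 2 for a
#' random subset of `n_t2` of them (simple random attrition),
#' discretizes both waves to item-level records, and injects
#' quality-control violations at the given rates.
#'
#' @param truth Ground truth, as from [make_default_truth()].
#' @param n_t1 Wave-1 sample size.
#' @param n_t2 Number of wave-1 respondents also observed at wave 2.
#' @param seed Master seed; the latent draw, each wave's
#'   discretization, and each wave's violation injection use distinct
#'   child seeds derived from it.
#' @param rates Violation rates, as in [inject_qc_violations()].
#' @return List with `records_t1`, `records_t2`, `latent`
#'   (the underlying continuous scores), `t2_codes`, and `truth`.
#' @export
simulate_two_wave_study <- function(truth = make_default_truth(),
                                    n_t1 = 1000, n_t2 = round(n_t1 / 3),
                                    seed = truth$seed,
                                    rates = c(lie = 0.03, missing = 0.04,
                                              fast = 0.03)) {
  stopifnot(n_t2 <= n_t1)
  latent <- sample_two_wave(truth, n_t1, seed = child_seed(seed, 1))
  codes <- sprintf("S%05d", seq_len(n_t1))
  set.seed(child_seed(seed, 2))
  keep2 <- sort(sample(n_t1, n_t2))
  r1 <- discretize_to_items(latent$x1, "T1", codes, item_model = truth$item_model,
                            seed = child_seed(seed, 3))
  r2 <- discretize_to_items(latent$x2[keep2, , drop = FALSE], "T2",
                            codes[keep2], item_model = truth$item_model,
                            seed = child_seed(seed, 4))
  r1 <- inject_qc_violations(r1, rates, seed = child_seed(seed, 5))
  r2 <- inject_qc_violations(r2, rates, seed = child_seed(seed, 6))
  list(records_t1 = r1, records_t2 = r2, latent = latent,
       t2_codes = codes[keep2], truth = truth)
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule used by the pipeline so every stage has
#' its own reproducible stream: a fixed-multiplier congruential step,
#' `(master * 48271 + index) mod (2^31 - 1)`, computed in double
#' precision (exact for these magnitudes).
#'
#' @param master Integer master seed.
#' @param index Stage index (small non-negative integer).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + index) %% 2147483647)
}
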