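# Bootstrap accuracy and stability of the estimated network:
# nonparametric bootstrap CIs for edge weights, and case-drop bootstrap
# with the correlation-stability (CS) coefficient for centralities.

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Re-estimates the regularized network on `B` resamples (rows drawn
#' with replacement) and reports percentile 2.5/97.5 intervals for
#' every possible edge.
#'
#' @param scores Score table or numeric matrix.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed.
#' @param gamma,path_size Estimator settings, as in
#'   [estimate_network()].
#' @return A `bootstrap_edges` object: data frame `edges` with
#'   `node_a`, `node_b`, point estimate, `lower`, `upper`; plus `B`,
#'   `seed`, and `failed` (replicates on which estimation failed and
#'   was dropped).
#' @export
bootstrap_edges <- function(scores, B = 1000, seed = 1L, gamma = 0.5,
                            path_size = 100) {
  stopifnot(B >= 100)
  x <- score_matrix(scores)
  n <- nrow(x)
  full <- estimate_pcor(x, gamma = gamma, path_size = path_size)$W
  p <- nrow(full)
  ut <- upper.tri(full)
  set.seed(seed)
  draws <- matrix(NA_real_, B, sum(ut))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Wb <- tryCatch(estimate_pcor(x[idx, , drop = FALSE], gamma = gamma,
                                 path_size = path_size)$W,
                   error = function(e) NULL)
    if (is.null(Wb)) { failed <- failed + 1L; next }
    draws[b, ] <- Wb[ut]
  }
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  pairs <- which(ut, arr.ind = TRUE)
  edges <- data.frame(node_a = rownames(full)[pairs[, 1]],
                      node_b = colnames(full)[pairs[, 2]],
                      weight = full[ut],
                      lower = qs[1, ], upper = qs[2, ],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, B = B, seed = seed, failed = failed,
                 n = n),
            class = "bootstrap_edges")
}

#' @export
print.bootstrap_edges <- function(x, ...) {
  cat("Edge-weight bootstrap: B =", x$B, "replicates, n =", x$n, "\n")
  cat("  median CI width:",
      signif(stats::median(x$edges$upper - x$edges$lower), 3), "\n")
  invisible(x)
}

#' Case-drop bootstrap and correlation-stability coefficient
#'
#' For each drop proportion in `drop_grid`, draws `B` subsamples
#' without replacement of `(1 - drop) * n` rows, re-estimates the
#' network and its centralities, and correlates subsample centralities
#' with the full-sample values. The CS coefficient for a centrality
#' measure is the largest drop proportion at which the correlation is
#' at least `cor_threshold` in at least `prob_threshold` of subsamples
#' (0 when no level qualifies). Drop levels leaving fewer than `p + 1`
#' rows are skipped with a warning.
#'
#' @param scores Score table or numeric matrix.
#' @param measures Centrality measures to track.
#' @param drop_grid Drop proportions (default 0.05 to 0.75 by 0.05; the
#'   grid ceiling 0.75 is the largest reportable CS value).
#' @param B Subsamples per drop level (default 250).
#' @param seed Integer seed.
#' @param gamma,path_size Estimator settings.
#' @param cor_method Correlation for the stability curve (Spearman by
#'   default; Pearson available).
#' @param cor_threshold,prob_threshold CS rule constants (0.7 / 0.95).
#' @return A `case_drop_cs` object: `cs` (named CS coefficient per
#'   measure), `curve` (per level and measure: proportion of subsamples
#'   above threshold and mean correlation), and the settings.
#' @export
case_drop_cs <- function(scores,
                         measures = c("strength", "closeness",
                                      "betweenness"),
                         drop_grid = seq(0.05, 0.75, by = 0.05),
                         B = 250, seed = 1L, gamma = 0.5,
                         path_size = 100,
                         cor_method = c("spearman", "pearson"),
                         cor_threshold = 0.7, prob_threshold = 0.95) {
  cor_method <- match.arg(cor_method)
  x <- score_matrix(scores)
  n <- nrow(x)
  p <- ncol(x)
  full_net <- estimate_pcor(x, gamma = gamma, path_size = path_size)$W
  full_cent <- lapply(setNames(measures, measures), function(m)
    get(m, mode = "function")(full_net))
  set.seed(seed)
  rows <- list()
  for (drop in drop_grid) {
    m_sub <- round((1 - drop) * n)
    if (m_sub < p + 1) {
      warning("drop proportion ", drop, " leaves fewer than p + 1 cases; skipped")
      next
    }
    cors <- matrix(NA_real_, B, length(measures),
                   dimnames = list(NULL, measures))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m_sub)
      Wb <- tryCatch(estimate_pcor(x[idx, , drop = FALSE], gamma = gamma,
                                   path_size = path_size)$W,
                     error = function(e) NULL)
      if (is.null(Wb)) next
      for (m in measures) {
        cb <- get(m, mode = "function")(Wb)
        cors[b, m] <- suppressWarnings(
          cor(cb, full_cent[[m]], method = cor_method))
      }
    }
    for (m in measures) {
      cm <- cors[, m]
      # NA (failed replicate or degenerate centrality) counts as unstable
      rows[[length(rows) + 1]] <- data.frame(
        drop = drop, measure = m,
        prop_stable = mean(!is.na(cm) & cm >= cor_threshold),
        mean_cor = mean(cm, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  curve <- do.call(rbind, rows)
  cs <- vapply(setNames(measures, measures), function(m) {
    sub <- curve[curve$measure == m & curve$prop_stable >= prob_threshold, ]
    if (nrow(sub) == 0) 0 else max(sub$drop)
  }, numeric(1))
  structure(list(cs = cs, curve = curve, drop_grid = drop_grid, B = B,
                 seed = seed, cor_method = cor_method,
                 cor_threshold = cor_threshold,
                 prob_threshold = prob_threshold, n = n),
            class = "case_drop_cs")
}

#' @export
print.case_drop_cs <- function(x, ...) {
  cat("Case-drop bootstrap (B =", x$B, "per level, n =", x$n, ")\n")
  cat("  CS coefficients:",
      paste(names(x$cs), round(x$cs, 2), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
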