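# Permutation network comparison: invariance of global strength and of
# individual edge weights between two estimated networks, for
# independent groups or for the same respondents measured twice.

#' Global strength of a network
#'
#' Sum of absolute edge weights over unordered node pairs; the overall
#' interconnectedness of the network.
#'
#' @param net A `weighted_network` or symmetric weight matrix.
#' @return Scalar.
#' @export
global_strength <- function(net) {
  W <- net_weight_matrix(net)
  sum(abs(W[upper.tri(W)]))
}

#' Permutation network comparison test
#'
#' Estimates a regularized network per group and compares (a) global
#' strength and (b) every individual edge weight, against a permutation
#' null in which group labels are reassigned (`design =
#' "independent"`), or the two waves are swapped within respondent with
#' probability 1/2 (`design = "paired"`; both groups must hold the same
#' respondents in the same row order). Both networks are re-estimated
#' on every permutation. P-values use the add-one estimator
#' `(1 + #[null >= observed]) / (1 + n_perm)` and so are never zero;
#' per-edge p-values are corrected for multiplicity over all node pairs
#' (Holm by default).
#'
#' @param scores_a,scores_b Score tables or matrices with identical
#'   column labels.
#' @param design `"independent"` or `"paired"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param gamma,path_size Estimator settings.
#' @param p_adjust_method Multiplicity correction for per-edge tests:
#'   `"holm"` (default), `"bonferroni"`, `"BH"`, or `"none"`.
#' @return An `nct_result` object: global strengths `gs1`, `gs2`,
#'   observed absolute difference `gs_diff` with permutation p `gs_p`;
#'   omnibus statistic (maximum absolute edge difference) with
#'   `omnibus_p`; per-edge data frame with raw and adjusted p-values;
#'   and the settings.
#' @export
nct <- function(scores_a, scores_b, design = c("independent", "paired"),
                n_perm = 1000, seed = 1L, gamma = 0.5, path_size = 100,
                p_adjust_method = c("holm", "bonferroni", "BH", "none")) {
  design <- match.arg(design)
  p_adjust_method <- match.arg(p_adjust_method)
  xa <- score_matrix(scores_a)
  xb <- score_matrix(scores_b)
  if (!identical(colnames(xa), colnames(xb)))
    stop("the two groups must share the same node set (column labels)")
  if (design == "paired" && nrow(xa) != nrow(xb))
    stop("paired design requires the same respondents in both groups")
  p <- ncol(xa)
  ut <- upper.tri(matrix(0, p, p))

  stat <- function(x1, x2) {
    W1 <- estimate_pcor(x1, gamma = gamma, path_size = path_size)$W
    W2 <- estimate_pcor(x2, gamma = gamma, path_size = path_size)$W
    list(gs = abs(global_strength(W1) - global_strength(W2)),
         edge = abs(W1[ut] - W2[ut]),
         gs1 = global_strength(W1), gs2 = global_strength(W2),
         W1 = W1, W2 = W2)
  }
  obs <- stat(xa, xb)

  set.seed(seed)
  na <- nrow(xa)
  if (design == "independent") {
    # canonical row order makes the permutation null invariant to the
    # order of the two arguments (nct(A, B) reproduces nct(B, A))
    pool0 <- rbind(xa, xb)
    pool0 <- pool0[do.call(order, as.data.frame(pool0)), , drop = FALSE]
  }
  ge_gs <- 0L
  ge_omni <- 0L
  ge_edge <- integer(length(obs$edge))
  for (k in seq_len(n_perm)) {
    if (design == "independent") {
      idx <- sample.int(nrow(pool0))
      x1 <- pool0[idx[seq_len(na)], , drop = FALSE]
      x2 <- pool0[idx[-seq_len(na)], , drop = FALSE]
    } else {
      swap <- stats::runif(na) < 0.5
      x1 <- xa; x2 <- xb
      x1[swap, ] <- xb[swap, , drop = FALSE]
      x2[swap, ] <- xa[swap, , drop = FALSE]
    }
    nul <- stat(x1, x2)
    ge_gs <- ge_gs + (nul$gs >= obs$gs)
    ge_omni <- ge_omni + (max(nul$edge) >= max(obs$edge))
    ge_edge <- ge_edge + (nul$edge >= obs$edge)
  }
  add1 <- function(k) (1 + k) / (1 + n_perm)
  pairs <- which(ut, arr.ind = TRUE)
  labels <- colnames(xa)
  per_edge <- data.frame(node_a = labels[pairs[, 1]],
                         node_b = labels[pairs[, 2]],
                         weight_a = obs$W1[ut], weight_b = obs$W2[ut],
                         diff = obs$W2[ut] - obs$W1[ut],
                         p = add1(ge_edge),
                         stringsAsFactors = FALSE)
  per_edge$p_adj <- p.adjust(per_edge$p, method = p_adjust_method)
  structure(list(gs1 = obs$gs1, gs2 = obs$gs2, gs_diff = obs$gs,
                 gs_p = add1(ge_gs),
                 omnibus_stat = max(obs$edge), omnibus_p = add1(ge_omni),
                 per_edge = per_edge, n_perm = n_perm, seed = seed,
                 design = design, p_adjust_method = p_adjust_method,
                 labels = labels),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Permutation network comparison (", x$design, ", ", x$n_perm,
      " permutations)\n", sep = "")
  cat("  global strength: ", round(x$gs1, 3), " vs ", round(x$gs2, 3),
      "  |diff| = ", round(x$gs_diff, 3), ", p = ", round(x$gs_p, 4),
      "\n", sep = "")
  cat("  omnibus max |edge diff| = ", round(x$omnibus_stat, 3),
      ", p = ", round(x$omnibus_p, 4), "\n", sep = "")
  sig <- x$per_edge[x$per_edge$p_adj < 0.05, ]
  cat("  edges with adjusted p < 0.05:", nrow(sig), "\n")
  invisible(x)
}
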