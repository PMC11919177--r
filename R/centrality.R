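# Weighted-network centrality. Conventions: strength sums absolute edge
# weights; shortest-path measures (closeness, betweenness) use edge
# lengths 1/|w|; expected influence for directed networks sums signed
# weights. Shortest paths delegate to igraph (Dijkstra / Brandes with
# fractional tie handling).

net_weight_matrix <- function(net) {
  if (inherits(net, "weighted_network")) net$W else as.matrix(net)
}

net_igraph <- function(W) {
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Node strength
#'
#' Sum of the absolute weights of a node's edges.
#'
#' @param net A `weighted_network` or symmetric weight matrix.
#' @param node Optional node label or index; default all nodes.
#' @return Named numeric vector (or scalar for a single node).
#' @export
strength <- function(net, node = NULL) {
  W <- net_weight_matrix(net)
  s <- rowSums(abs(W))
  if (is.null(node)) s else unname(s[node])
}

#' Node closeness
#'
#' Reciprocal of the sum of shortest-path distances from the node to
#' all other nodes, with edge lengths `1/|w|`. A node that cannot reach
#' every other node has closeness 0.
#'
#' @inheritParams strength
#' @return Named numeric vector (or scalar for a single node).
#' @export
closeness <- function(net, node = NULL) {
  W <- net_weight_matrix(net)
  p <- nrow(W)
  g <- net_igraph(W)
  D <- igraph::distances(g, weights = igraph::E(g)$length)
  tot <- rowSums(D)   # includes d(i,i) = 0
  cl <- ifelse(is.finite(tot) & p > 1, 1 / tot, 0)
  names(cl) <- rownames(W)
  if (is.null(node)) cl else unname(cl[node])
}

#' Node betweenness
#'
#' Number of shortest paths between pairs of other nodes that pass
#' through the node (fractional credit for tied shortest paths; Brandes
#' convention; unordered pairs), with edge lengths `1/|w|`.
#'
#' @inheritParams strength
#' @return Named numeric vector (or scalar for a single node).
#' @export
betweenness <- function(net, node = NULL) {
  W <- net_weight_matrix(net)
  g <- net_igraph(W)
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = igraph::E(g)$length)
  b <- setNames(as.numeric(b), rownames(W))
  if (is.null(node)) b else unname(b[node])
}

#' Z-score columns of a centrality table
#'
#' Standardizes each numeric column over nodes using the population
#' (divide-by-n) standard deviation. A constant column maps to zeros
#' and is flagged in the `"degenerate"` attribute.
#'
#' @param x Numeric vector or data frame of centrality columns.
#' @return Standardized object of the same shape.
#' @export
zscore_columns <- function(x) {
  zs <- function(v) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s == 0) rep(0, length(v)) else (v - m) / s
  }
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    degen <- character(0)
    for (j in names(x)[num]) {
      if (sqrt(mean((x[[j]] - mean(x[[j]]))^2)) == 0)
        degen <- c(degen, j)
      x[[j]] <- zs(x[[j]])
    }
    attr(x, "degenerate") <- degen
    x
  } else {
    out <- zs(x)
    attr(out, "degenerate") <- sd(x) == 0
    out
  }
}

#' Centrality table for an undirected weighted network
#'
#' @param net A `weighted_network` or symmetric weight matrix.
#' @return Data frame with `node`, raw `strength`, `closeness`,
#'   `betweenness`, and population-z-scored `z_strength`,
#'   `z_closeness`, `z_betweenness`.
#' @export
centrality_table <- function(net) {
  W <- net_weight_matrix(net)
  raw <- data.frame(node = rownames(W),
                    strength = strength(W),
                    closeness = closeness(W),
                    betweenness = betweenness(W),
                    stringsAsFactors = FALSE, row.names = NULL)
  z <- zscore_columns(raw[, c("strength", "closeness", "betweenness")])
  names(z) <- paste0("z_", names(z))
  out <- cbind(raw, z)
  attr(out, "degenerate") <- attr(z, "degenerate")
  out
}

#' Expected influence of directed-network nodes
#'
#' Signed sums of a node's incoming (`mode = "in"`, IEI) or outgoing
#' (`mode = "out"`, OEI) edge weights in a cross-lagged coefficient
#' matrix whose entry (i, j) is the effect of wave-1 node i on wave-2
#' node j. With `exclude_self = TRUE` the autoregressive diagonal is
#' left out.
#'
#' @param B Directed weight matrix (or a `directed_network` object).
#' @param mode `"in"` or `"out"`.
#' @param exclude_self Drop the diagonal (default `TRUE`).
#' @return Named numeric vector over nodes.
#' @export
expected_influence <- function(B, mode = c("in", "out"),
                               exclude_self = TRUE) {
  mode <- match.arg(mode)
  if (inherits(B, "directed_network")) B <- B$B_hat
  M <- as.matrix(B)
  if (exclude_self) diag(M) <- 0
  if (mode == "in") colSums(M) else rowSums(M)
}
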