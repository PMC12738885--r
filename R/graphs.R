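#' Weighted graph container
#'
#' A minimal symmetric weighted graph: ordered node labels plus a symmetric
#' nonnegative weight matrix whose diagonal stores self-loop weights.
#'
#' @param W Symmetric nonnegative numeric matrix with dimnames.
#' @return Object of class \code{weighted_graph} with elements \code{nodes},
#'   \code{W} and \code{edges} (derived off-diagonal edge list).
#' @export
weighted_graph <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- sprintf("v%d", seq_len(nrow(W)))
  }
  if (any(W < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric",
                                       call. = FALSE)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(
    node_a = rownames(W)[idx[, 1]],
    node_b = colnames(W)[idx[, 2]],
    weight = W[idx],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = rownames(W), W = W, edges = edges),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", sum(diag(x$W) > 0), "self-loops\n")
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

#' Build the DEG brain-region interaction network (DEG-BRIN)
#'
#' Nodes are brain regions; the edge weight between two regions is the number
#' of universal-list DEGs their DEG sets share, and each region carries a
#' self-loop weighted by its own DEG-set size. Region DEG sets are first
#' restricted to the universal cross-region list G (genes differentially
#' expressed in at least \code{min_regions} regions).
#'
#' @param region_sets A \code{region_deg_sets} object from
#'   [degs_per_region()], or a named list of per-region gene sets together
#'   with \code{universal}.
#' @param universal Optional character vector overriding the universal list.
#' @return A [weighted_graph()] over the regions.
#' @export
build_degbrin <- function(region_sets, universal = NULL) {
  if (inherits(region_sets, "region_deg_sets")) {
    universal <- universal %||% region_sets$universal
    sets <- region_sets$region_sets
  } else {
    sets <- region_sets
    if (is.null(universal)) universal <- sort(unique(unlist(sets)))
  }
  if (length(sets) < 2) stop("need at least 2 regions", call. = FALSE)
  sets <- lapply(sets, intersect, y = universal)
  n <- length(sets)
  regions <- names(sets)
  W <- matrix(0, n, n, dimnames = list(regions, regions))
  for (i in seq_len(n)) {
    W[i, i] <- length(sets[[i]])
    if (i < n) for (j in seq((i + 1), n)) {
      w <- length(intersect(sets[[i]], sets[[j]]))
      W[i, j] <- W[j, i] <- w
    }
  }
  g <- weighted_graph(W)
  g$region_sets <- sets
  g
}

#' Threshold a PPI edge list into a binary interaction graph
#'
#' Keeps interactions whose combined confidence score is at least \code{tau}
#' (inclusive) and returns the binary undirected graph over all input genes.
#' The canonical confidence tiers are 0.4 (medium), 0.7 (high) and 0.9
#' (highest), but any value in [0, 1] is accepted.
#'
#' @param edges data.frame with columns gene_a, gene_b, score.
#' @param tau Confidence threshold in [0, 1].
#' @param nodes Optional node universe (defaults to genes present in
#'   \code{edges}).
#' @return A [weighted_graph()] with unit edge weights and no self-loops.
#' @export
threshold_ppi <- function(edges, tau, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "score") %in% names(edges)))
  check_fraction(tau, "tau")
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("PPI scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(edges$gene_a == edges$gene_b)) {
    stop("PPI edge list must not contain self-pairs", call. = FALSE)
  }
  nodes <- nodes %||% sort(unique(c(edges$gene_a, edges$gene_b)))
  keep <- edges[edges$score >= tau, , drop = FALSE]
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(keep) > 0) {
    ia <- match(keep$gene_a, nodes)
    ib <- match(keep$gene_b, nodes)
    W[cbind(ia, ib)] <- 1
    W[cbind(ib, ia)] <- 1
  }
  weighted_graph(W)
}

as_igraph <- function(g) {
  A <- g$W
  diag(A) <- 0          # centralities ignore self-loops
  A <- (A > 0) * 1      # and treat the graph as unweighted
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Degree centrality
#'
#' Number of distinct neighbours of each node; self-loops ignored and
#' weights binarised.
#'
#' @param g A [weighted_graph()].
#' @return Named integer vector.
#' @export
degree_centrality <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  A <- g$W
  diag(A) <- 0
  stats::setNames(as.integer(rowSums(A > 0)), g$nodes)
}

#' Betweenness centrality
#'
#' Freeman betweenness over unordered endpoint pairs: for each node v, the
#' sum over pairs (s, t), s != t, both != v, of the fraction of shortest
#' s-t paths passing through v. Unweighted, unnormalised; disconnected pairs
#' contribute zero.
#'
#' @param g A [weighted_graph()].
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  ig <- as_igraph(g)
  stats::setNames(igraph::betweenness(ig, directed = FALSE, weights = NULL),
                  g$nodes)
}

#' Centrality table for a graph
#'
#' @param g A [weighted_graph()].
#' @return data.frame with columns node, degree, betweenness.
#' @export
centrality_table <- function(g) {
  data.frame(
    node = g$nodes,
    degree = unname(degree_centrality(g)),
    betweenness = unname(betweenness_centrality(g)),
    stringsAsFactors = FALSE
  )
}

#' Select hub nodes from a centrality table
#'
#' Hubs are nodes ranking in the top \code{top_fraction} of both degree and
#' betweenness centrality. The cutoffs are the empirical values at rank
#' \code{ceiling(top_fraction * n)} from the top; boundary ties are included,
#' so a degenerate all-equal column returns every node.
#'
#' @param cent data.frame from [centrality_table()].
#' @param top_fraction Fraction of nodes defining "top" (default 0.2).
#' @return Character vector of hub node labels.
#' @export
select_hubs <- function(cent, top_fraction = 0.2) {
  stopifnot(is.data.frame(cent), nrow(cent) > 0,
            all(c("node", "degree", "betweenness") %in% names(cent)))
  check_fraction(top_fraction, "top_fraction", open_lower = TRUE)
  k <- max(1L, ceiling(top_fraction * nrow(cent)))
  thr <- function(x) sort(x, decreasing = TRUE)[k]
  hubs <- cent$node[cent$degree >= thr(cent$degree) &
                    cent$betweenness >= thr(cent$betweenness)]
  sort(hubs)
}

#' Random graph matched on node and edge counts
#'
#' Uniform simple graph with exactly \code{n_edges} unit-weight edges over
#' \code{n_nodes} nodes, preserving supplied self-loop weights. Used as the
#' topology-free baseline against the DEG-BRIN prior.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of off-diagonal edges.
#' @param self_loop_weights Numeric vector of diagonal weights (recycled;
#'   default 1).
#' @param seed Integer seed.
#' @param nodes Optional node labels.
#' @return A [weighted_graph()].
#' @export
random_graph_matched <- function(n_nodes, n_edges, self_loop_weights = 1,
                                 seed = 1L, nodes = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes")
  n_edges <- check_count(n_edges, "n_edges", min = 0)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    stop(sprintf("n_edges = %d infeasible for %d nodes (max %d)",
                 n_edges, n_nodes, max_edges), call. = FALSE)
  }
  nodes <- nodes %||% sprintf("v%02d", seq_len(n_nodes))
  set.seed(as.integer(seed))
  W <- matrix(0, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  if (n_edges > 0) {
    pairs <- which(upper.tri(W))
    chosen <- sample(pairs, n_edges)
    W[chosen] <- 1
    W <- pmax(W, t(W))
  }
  diag(W) <- rep_len(self_loop_weights, n_nodes)
  weighted_graph(W)
}

#' Symmetric degree normalisation of an adjacency matrix
#'
#' Computes the convolution operator A_hat = D^{-1/2} W D^{-1/2} with
#' D = diag(row sums of W). Requires self-loops (strictly positive diagonal)
#' so every row sum is positive; the result is symmetric with spectral
#' radius at most 1.
#'
#' @param g A [weighted_graph()] or a symmetric nonnegative matrix.
#' @return Normalised numeric matrix.
#' @export
normalize_adjacency <- function(g) {
  W <- if (inherits(g, "weighted_graph")) g$W else g
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  d <- rowSums(W)
  if (any(d <= 0)) {
    stop("zero row sum: every node needs a positive self-loop or edge weight",
         call. = FALSE)
  }
  dinv <- 1 / sqrt(d)
  A_hat <- W * outer(dinv, dinv)
  dimnames(A_hat) <- dimnames(W)
  A_hat
}

#' Add unit self-loops to a graph
#'
#' Convenience for turning a binary interaction graph into a convolution
#' substrate (PPI-GCN requires positive diagonals before normalisation).
#'
#' @param g A [weighted_graph()].
#' @param weight Self-loop weight (default 1).
#' @return A [weighted_graph()].
#' @export
add_self_loops <- function(g, weight = 1) {
  W <- g$W
  diag(W) <- pmax(diag(W), weight)
  weighted_graph(W)
}

#' Write a graph as a weighted edge-list TSV
#'
#' Self-loops are written as rows with node_a = node_b.
#'
#' @param g A [weighted_graph()].
#' @param path Output path.
#' @export
write_graph_tsv <- function(g, path) {
  loops <- data.frame(node_a = g$nodes, node_b = g$nodes,
                      weight = diag(g$W), stringsAsFactors = FALSE)
  loops <- loops[loops$weight > 0, , drop = FALSE]
  utils::write.table(rbind(g$edges, loops), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read a weighted edge-list TSV written by [write_graph_tsv()]
#'
#' @param path File path.
#' @param nodes Optional node universe.
#' @return A [weighted_graph()].
#' @export
read_graph_tsv <- function(path, nodes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  nodes <- nodes %||% sort(unique(c(df$node_a, df$node_b)))
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ia <- match(df$node_a, nodes); ib <- match(df$node_b, nodes)
  W[cbind(ia, ib)] <- df$weight
  W[cbind(ib, ia)] <- df$weight
  weighted_graph(W)
}
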