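# Eigenvector centrality on supplied gene-gene edge lists, per cluster;
# selection of most-central genes.

# Power iteration for the leading eigenvector of a symmetric non-negative
# adjacency matrix. A diagonal shift proportional to the maximum row sum
# keeps the Perron eigenvalue strictly dominant (bipartite components would
# otherwise make the iteration oscillate) without changing the eigenvector,
# and keeps the result invariant to uniform edge-weight scaling.
.power_eigen <- function(a, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(a)
  shift <- 0.5 * max(rowSums(a))
  if (shift > 0) a <- a + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(a %*% v)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("adjacency matrix annihilates the iterate")
    w <- w / nrm
    if (max(abs(w - v)) < tol) {
      w <- abs(w)
      return(w / max(w))
    }
    v <- w
  }
  stop("power iteration did not converge in ", max_iter, " iterations")
}

#' Eigenvector centrality of a gene subnetwork
#'
#' Induces the subgraph of the supplied undirected weighted edge list on
#' `nodes` (all edge-list genes if `NULL`) and computes eigenvector
#' centrality by power iteration on each connected component with at least
#' 2 nodes, normalized to max = 1 per component. Isolated nodes get
#' centrality 0. Ranks are unique, ordered by descending centrality with
#' ties broken by gene symbol.
#'
#' @param edges data.frame with columns gene_a, gene_b, weight (see
#'   [read_edge_list()]).
#' @param nodes Optional character vector restricting the subgraph.
#' @param tol,max_iter Power-iteration convergence controls.
#' @return data.frame: gene, component, centrality, rank.
#' @export
eigencentrality <- function(edges, nodes = NULL, tol = 1e-10, max_iter = 10000L) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  } else {
    nodes <- sort(unique(toupper(nodes)))
  }
  sub <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub[, c("gene_a", "gene_b", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  cent <- stats::setNames(rep(0, length(nodes)), nodes)
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    if (length(members) < 2L) next
    sg <- igraph::induced_subgraph(g, members)
    a <- igraph::as_adjacency_matrix(sg, attr = "weight", sparse = FALSE)
    v <- tryCatch(.power_eigen(a, tol = tol, max_iter = max_iter),
                  error = function(e)
                    stop("component ", ci, ": ", conditionMessage(e)))
    cent[igraph::V(sg)$name] <- v
  }
  out <- data.frame(gene = nodes,
                    component = unname(comp$membership[nodes]),
                    centrality = unname(cent[nodes]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$centrality, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Per-cluster eigenvector centrality
#'
#' Runs [eigencentrality()] on the subgraph induced by each cluster's
#' member genes.
#'
#' @param edges Edge list.
#' @param clusters A `cluster_set`, or a named character vector
#'   gene -> cluster label.
#' @return data.frame: gene, cluster, component, centrality, rank (within
#'   cluster).
#' @export
cluster_centrality <- function(edges, clusters) {
  assignment <- if (inherits(clusters, "cluster_set")) clusters$assignment else clusters
  labs <- sort(unique(assignment))
  out <- do.call(rbind, lapply(labs, function(lab) {
    members <- names(assignment)[assignment == lab]
    res <- eigencentrality(edges, nodes = members)
    res$cluster <- lab
    res
  }))
  out[, c("gene", "cluster", "component", "centrality", "rank")]
}

#' Most central genes per cluster
#'
#' @param result Output of [cluster_centrality()] (or [eigencentrality()],
#'   treated as a single cluster).
#' @param per_cluster Number of top genes per cluster (default 1); whole
#'   cluster if larger than the cluster.
#' @return Named list of gene vectors, one per cluster.
#' @export
top_central <- function(result, per_cluster = 1L) {
  stopifnot(nrow(result) > 0L)
  if (!"cluster" %in% names(result)) result$cluster <- "all"
  split_res <- split(result, result$cluster)
  lapply(split_res, function(df) {
    df <- df[order(-df$centrality, df$gene), , drop = FALSE]
    utils::head(df$gene, per_cluster)
  })
}

#' Edges bridging two clusters
#'
#' Emits the raw edges whose endpoints lie in two different clusters, for
#' inspection of genes that bridge, e.g., the decreasing and increasing
#' gradient modules.
#'
#' @param edges Edge list.
#' @param clusters A `cluster_set` or named assignment vector.
#' @return data.frame: gene_a, cluster_a, gene_b, cluster_b, weight.
#' @export
bridge_edges <- function(edges, clusters) {
  assignment <- if (inherits(clusters, "cluster_set")) clusters$assignment else clusters
  a <- assignment[edges$gene_a]
  b <- assignment[edges$gene_b]
  keep <- !is.na(a) & !is.na(b) & a != b
  out <- data.frame(gene_a = edges$gene_a[keep], cluster_a = unname(a[keep]),
                    gene_b = edges$gene_b[keep], cluster_b = unname(b[keep]),
                    weight = edges$weight[keep], stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
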