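# Centrality analysis of the annotated directed network and the
# top-ten intersection rule for selecting central regulators and
# targets. Out-degree, hub score and betweenness depend on outgoing
# edges and are ranked for TF-role nodes only; in-degree and authority
# are ranked for target-role (glycolysis-related) nodes.

#' In/out degree of every node
#'
#' @param net an [annotate_network()] graph.
#' @return data frame `node`, `role`, `in_degree`, `out_degree`.
#' @export
degree_centrality <- function(net) {
  data.frame(node = igraph::V(net)$name,
             role = igraph::V(net)$role,
             in_degree = igraph::degree(net, mode = "in"),
             out_degree = igraph::degree(net, mode = "out"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Directed betweenness centrality
#'
#' Unweighted shortest-path betweenness (Brandes algorithm), endpoints
#' excluded, unnormalized — ranking, which is all the selection uses, is
#' normalization-invariant. Target-role nodes are pure sinks, so their
#' betweenness is identically zero.
#'
#' @param net an [annotate_network()] graph.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  b <- igraph::betweenness(net, directed = TRUE, normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' HITS hub and authority scores
#'
#' Power iteration from the uniform vector: the authority score of a
#' node is the sum of hub scores of nodes linking into it, the hub score
#' the sum of authority scores of nodes it links to; each update is
#' renormalized to unit Euclidean norm. Convergence is declared when the
#' successive-vector max-difference of both score vectors falls below
#' `tol`.
#'
#' @param net an [annotate_network()] graph (nonempty).
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   last residual.
#' @return list with named numeric vectors `hub` and `authority` (unit
#'   Euclidean norm, all-zero only for edgeless graphs) and `iterations`.
#' @export
hits_scores <- function(net, tol = 1e-10, max_iter = 1000) {
  n <- igraph::vcount(net)
  if (n == 0) stop("hits_scores needs a nonempty network")
  nodes <- igraph::V(net)$name
  a_mat <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  if (igraph::ecount(net) == 0) {
    zero <- stats::setNames(numeric(n), nodes)
    return(list(hub = zero, authority = zero, iterations = 0L))
  }
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }
  hub <- unit(rep(1, n))
  auth <- unit(rep(1, n))
  for (it in seq_len(max_iter)) {
    auth_new <- unit(drop(crossprod(a_mat, hub)))
    hub_new <- unit(drop(a_mat %*% auth_new))
    resid <- max(max(abs(auth_new - auth)), max(abs(hub_new - hub)))
    auth <- auth_new
    hub <- hub_new
    if (resid < tol) {
      return(list(hub = stats::setNames(hub, nodes),
                  authority = stats::setNames(auth, nodes),
                  iterations = it))
    }
  }
  stop(sprintf("HITS did not converge in %d iterations (residual %.3g)",
               max_iter, resid))
}

#' Centrality table for an annotated network
#'
#' All five measures for every node: in/out degree, betweenness, hub and
#' authority score.
#'
#' @param net an [annotate_network()] graph.
#' @param tol,max_iter passed to [hits_scores()].
#' @return data frame `node`, `role`, `in_degree`, `out_degree`,
#'   `betweenness`, `hub`, `authority`.
#' @export
centrality_table <- function(net, tol = 1e-10, max_iter = 1000) {
  deg <- degree_centrality(net)
  if (nrow(deg) == 0) {
    deg$betweenness <- numeric(0)
    deg$hub <- numeric(0)
    deg$authority <- numeric(0)
    return(deg)
  }
  btw <- betweenness_centrality(net)
  hits <- hits_scores(net, tol = tol, max_iter = max_iter)
  deg$betweenness <- unname(btw[deg$node])
  deg$hub <- unname(hits$hub[deg$node])
  deg$authority <- unname(hits$authority[deg$node])
  deg
}

#' Top-k nodes of a centrality measure
#'
#' Nodes of the measure's eligible role, sorted by value descending with
#' a deterministic secondary sort by gene identifier. All nodes tied
#' with the k-th distinct retained value are included, so the list may
#' exceed `k`. Measures depending on outgoing edges (`out_degree`,
#' `hub`, `betweenness`) are restricted to TF-role nodes; `in_degree`
#' and `authority` to target-role nodes.
#'
#' @param table a [centrality_table()].
#' @param measure one of `"out_degree"`, `"hub"`, `"betweenness"`,
#'   `"in_degree"`, `"authority"`.
#' @param k list length before tie expansion (default 10).
#' @return character vector of node names, ordered.
#' @export
top_k <- function(table, measure = c("out_degree", "hub", "betweenness",
                                     "in_degree", "authority"), k = 10) {
  measure <- match.arg(measure)
  role_filter <- if (measure %in% c("out_degree", "hub", "betweenness")) {
    "TF"
  } else {
    "target"
  }
  sub <- table[table$role == role_filter, , drop = FALSE]
  sub <- sub[order(-sub[[measure]], sub$node), , drop = FALSE]
  if (nrow(sub) <= k) {
    if (nrow(sub) < k) {
      message(sprintf("top_k: only %d eligible %s-role node(s) for %s",
                      nrow(sub), role_filter, measure))
    }
    return(sub$node)
  }
  cutoff <- sub[[measure]][k]
  sub$node[sub[[measure]] >= cutoff]
}

#' Select central TFs and central target genes
#'
#' The top-list intersection rule: central TFs are the nodes common to
#' the top-k lists for out-degree, hub score and betweenness; central
#' targets are common to the top-k lists for in-degree and authority.
#'
#' @param table a [centrality_table()].
#' @param k top-list length (default 10).
#' @return list with `central_tfs`, `central_targets`, and `top_lists`
#'   (the per-measure lists retained for reporting).
#' @export
select_central_genes <- function(table, k = 10) {
  lists <- list(
    out_degree = top_k(table, "out_degree", k),
    hub = top_k(table, "hub", k),
    betweenness = top_k(table, "betweenness", k),
    in_degree = top_k(table, "in_degree", k),
    authority = top_k(table, "authority", k)
  )
  central_tfs <- Reduce(intersect,
                        lists[c("out_degree", "hub", "betweenness")])
  central_targets <- Reduce(intersect, lists[c("in_degree", "authority")])
  list(central_tfs = sort(central_tfs),
       central_targets = sort(central_targets),
       top_lists = lists)
}
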