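# Comparison of promoter-class and enhancer-class annotated networks for
# the same group contrast: per-target in-degrees with shared-edge counts,
# and per-TF binding-site comparisons for a chosen target gene.

#' Compare target in-degrees between two annotated networks
#'
#' For the union of target-role genes across a promoter-class and an
#' enhancer-class network of the same comparison: the in-degree in each
#' network (0 when absent) and the number of common edges — directed
#' (tf, target) edges present in both networks.
#'
#' @param net_promoter,net_enhancer [annotate_network()] graphs built
#'   from the same comparison and gene list.
#' @param de_table optional [differential_expression()] table used to
#'   attach each target's DE status.
#' @return data frame `gene`, `de_status`, `in_degree_promoter`,
#'   `in_degree_enhancer`, `common_edges`, sorted by promoter in-degree
#'   descending.
#' @export
compare_in_degrees <- function(net_promoter, net_enhancer, de_table = NULL) {
  cmp_p <- igraph::graph_attr(net_promoter, "comparison")
  cmp_e <- igraph::graph_attr(net_enhancer, "comparison")
  if (!is.null(cmp_p) && !is.null(cmp_e) && !identical(cmp_p, cmp_e)) {
    stop("consistency error: networks come from different comparisons (",
         cmp_p, " vs ", cmp_e, ")")
  }
  role_p <- stats::setNames(igraph::V(net_promoter)$role,
                            igraph::V(net_promoter)$name)
  role_e <- stats::setNames(igraph::V(net_enhancer)$role,
                            igraph::V(net_enhancer)$name)
  shared <- intersect(names(role_p), names(role_e))
  if (any(role_p[shared] != role_e[shared])) {
    stop("consistency error: conflicting gene roles between the networks")
  }

  targets <- sort(union(names(role_p)[role_p == "target"],
                        names(role_e)[role_e == "target"]))
  el_p <- igraph::as_data_frame(net_promoter, what = "edges")
  el_e <- igraph::as_data_frame(net_enhancer, what = "edges")
  key_p <- paste(el_p$from, el_p$to)
  key_e <- paste(el_e$from, el_e$to)

  indeg <- function(el, gene) sum(el$to == gene)
  out <- data.frame(
    gene = targets,
    de_status = rep(NA_character_, length(targets)),
    in_degree_promoter = vapply(targets, function(g) indeg(el_p, g), 0L),
    in_degree_enhancer = vapply(targets, function(g) indeg(el_e, g), 0L),
    common_edges = vapply(targets, function(g) {
      length(intersect(key_p[el_p$to == g], key_e[el_e$to == g]))
    }, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(de_table)) {
    out$de_status <- de_table$status[match(out$gene, de_table$gene)]
  }
  stopifnot(all(out$common_edges <=
                  pmin(out$in_degree_promoter, out$in_degree_enhancer)))
  out[order(-out$in_degree_promoter, out$gene), , drop = FALSE]
}

#' Compare binding-site counts between two regulatory databases
#'
#' For one target gene, lists the TFs recorded in both databases with
#' their binding-site counts, and tallies how many TFs have more sites
#' in the enhancer-class database, more in the promoter-class database,
#' or the same number. The three tallies always sum to the number of
#' common TFs.
#'
#' @param db_promoter,db_enhancer [regulatory_db()] objects.
#' @param target target gene identifier.
#' @return list with `rows` (data frame `tf`, `sites_promoter`,
#'   `sites_enhancer`) and `summary` (data frame `gene`, `n_common_tfs`,
#'   `n_more_enhancer`, `n_more_promoter`, `n_equal`).
#' @export
compare_binding_sites <- function(db_promoter, db_enhancer, target) {
  recs_p <- db_promoter[db_promoter$target == target, , drop = FALSE]
  recs_e <- db_enhancer[db_enhancer$target == target, , drop = FALSE]
  if (nrow(recs_p) == 0 || nrow(recs_e) == 0) {
    message("compare_binding_sites: target ", target,
            " absent from at least one database")
    empty <- data.frame(tf = character(), sites_promoter = integer(),
                        sites_enhancer = integer(), stringsAsFactors = FALSE)
    summary <- data.frame(gene = target, n_common_tfs = 0L,
                          n_more_enhancer = 0L, n_more_promoter = 0L,
                          n_equal = 0L, stringsAsFactors = FALSE)
    return(list(rows = empty, summary = summary))
  }
  common <- sort(intersect(recs_p$tf, recs_e$tf))
  rows <- data.frame(
    tf = common,
    sites_promoter = recs_p$binding_sites[match(common, recs_p$tf)],
    sites_enhancer = recs_e$binding_sites[match(common, recs_e$tf)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  summary <- data.frame(
    gene = target,
    n_common_tfs = nrow(rows),
    n_more_enhancer = sum(rows$sites_enhancer > rows$sites_promoter),
    n_more_promoter = sum(rows$sites_promoter > rows$sites_enhancer),
    n_equal = sum(rows$sites_promoter == rows$sites_enhancer),
    stringsAsFactors = FALSE
  )
  stopifnot(summary$n_more_enhancer + summary$n_more_promoter +
              summary$n_equal == summary$n_common_tfs)
  list(rows = rows, summary = summary)
}
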