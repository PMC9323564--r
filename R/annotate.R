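# Annotation of significant undirected pairs against a directed
# regulatory database. An edge enters the network only if (i) the pair's
# edge weight differs significantly between the groups and (ii) the
# directed TF -> target record exists in the database. Glycolysis-related
# (target-role) genes never gain outgoing edges.

#' Construct / validate a regulatory database table
#'
#' @param db data frame with columns `tf`, `target`, `binding_sites`,
#'   `region_class`; duplicates of (tf, target) within one region class
#'   are collapsed by summing `binding_sites` with a warning.
#' @param db_name descriptive tag stored as an attribute.
#' @return validated data frame of class `regulatory_db`.
#' @export
regulatory_db <- function(db, db_name = "regulatory_db") {
  required <- c("tf", "target", "binding_sites", "region_class")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0) {
    stop("format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  bad_class <- !db$region_class %in% c("promoter", "enhancer")
  if (any(bad_class)) {
    stop("format error: invalid region_class in row(s) ",
         paste(which(bad_class), collapse = ", "))
  }
  self_rec <- db$tf == db$target
  if (any(self_rec)) {
    stop("format error: self-records (tf == target) in row(s) ",
         paste(which(self_rec), collapse = ", "))
  }
  bad_sites <- !is.finite(db$binding_sites) | db$binding_sites < 1 |
    db$binding_sites != floor(db$binding_sites)
  if (any(bad_sites)) {
    stop("format error: non-positive or non-integer binding_sites in row(s) ",
         paste(which(bad_sites), collapse = ", "))
  }
  key <- paste(db$tf, db$target, db$region_class)
  if (anyDuplicated(key)) {
    warning("duplicate (tf, target) records collapsed by summing binding sites",
            call. = FALSE)
    db <- stats::aggregate(binding_sites ~ tf + target + region_class,
                           data = db, FUN = sum)
  }
  db <- db[order(db$tf, db$target), c("tf", "target", "binding_sites",
                                      "region_class")]
  rownames(db) <- NULL
  db$binding_sites <- as.integer(db$binding_sites)
  structure(db, class = c("regulatory_db", "data.frame"), db_name = db_name)
}

#' Load a regulatory database from TSV
#'
#' @param path TSV with columns `tf`, `target`, `binding_sites` and
#'   optionally `region_class` (filled from the argument when absent).
#' @param region_class `"promoter"` or `"enhancer"`; rows of other
#'   classes are dropped.
#' @param db_name tag (defaults to the file name).
#' @return a [regulatory_db()] object.
#' @export
load_regulatory_db <- function(path, region_class = c("promoter", "enhancer"),
                               db_name = basename(path)) {
  region_class <- match.arg(region_class)
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"region_class" %in% names(db)) db$region_class <- region_class
  db <- db[db$region_class == region_class, , drop = FALSE]
  regulatory_db(db, db_name = db_name)
}

#' Annotate significant pairs against a directed regulatory database
#'
#' For each significant pair {a, b}, emits the directed edge a -> b if
#' the database holds record (a, b) and b -> a if it holds (b, a); both
#' may fire for TF-TF pairs. Edge signs are copied from the pair's logFC
#' sign. Records whose source gene has target role are dropped (target
#' genes have no outgoing edges). Nodes are restricted to those incident
#' to at least one kept edge.
#'
#' @param sig_pairs data frame from [significant_edges()] (needs
#'   `gene_a`, `gene_b`, `sign`).
#' @param db a [regulatory_db()].
#' @param roles gene-role data frame covering all genes in `sig_pairs`.
#' @param comparison free-text tag stored on the graph.
#' @return directed [igraph::igraph] with vertex attribute `role`, edge
#'   attributes `sign` and `binding_sites`, and graph attributes
#'   `comparison`, `db_name`, `n_sig_pairs`, `n_unmatched_pairs`.
#' @export
annotate_network <- function(sig_pairs, db, roles, comparison = "case_vs_reference") {
  stopifnot(inherits(db, "regulatory_db"))
  role_of <- stats::setNames(roles$role, roles$gene_id)
  in_pairs <- unique(c(sig_pairs$gene_a, sig_pairs$gene_b))
  uncovered <- setdiff(in_pairs, names(role_of))
  if (length(uncovered) > 0) {
    stop("roles do not cover gene(s): ", paste(uncovered, collapse = ", "))
  }

  db_key <- paste(db$tf, db$target)
  match_dir <- function(from, to) {
    hit <- match(paste(from, to), db_key)
    ok <- !is.na(hit) & role_of[from] == "TF"
    list(ok = ok, sites = db$binding_sites[hit])
  }
  fwd <- match_dir(sig_pairs$gene_a, sig_pairs$gene_b)
  rev <- match_dir(sig_pairs$gene_b, sig_pairs$gene_a)

  edges <- rbind(
    data.frame(from = sig_pairs$gene_a[fwd$ok], to = sig_pairs$gene_b[fwd$ok],
               sign = sig_pairs$sign[fwd$ok],
               binding_sites = fwd$sites[fwd$ok],
               stringsAsFactors = FALSE),
    data.frame(from = sig_pairs$gene_b[rev$ok], to = sig_pairs$gene_a[rev$ok],
               sign = sig_pairs$sign[rev$ok],
               binding_sites = rev$sites[rev$ok],
               stringsAsFactors = FALSE)
  )
  n_unmatched <- sum(!(fwd$ok | rev$ok))

  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = data.frame(name = nodes, role = unname(role_of[nodes]),
                          stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "comparison", comparison)
  g <- igraph::set_graph_attr(g, "db_name", attr(db, "db_name"))
  g <- igraph::set_graph_attr(g, "n_sig_pairs", nrow(sig_pairs))
  g <- igraph::set_graph_attr(g, "n_unmatched_pairs", n_unmatched)
  g
}

#' Minimum-target network filter
#'
#' A network is carried into centrality analysis only if it contains at
#' least `min_targets` target-role (glycolysis-related) genes.
#'
#' @param net an [annotate_network()] graph.
#' @param min_targets inclusive threshold (default 20).
#' @return logical.
#' @export
passes_target_filter <- function(net, min_targets = 20) {
  sum(igraph::V(net)$role == "target") >= min_targets
}

#' Export an annotated network
#'
#' Writes the network as SIF (`tf<TAB>sign<TAB>target`, sign rendered as
#' `+`/`-`), GraphML (with node role and edge sign attributes), or an
#' edge-list TSV — all loadable by Cytoscape.
#'
#' @param net an [annotate_network()] graph.
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  el <- igraph::as_data_frame(net, what = "edges")
  if (format == "sif") {
    lines <- paste(el$from, ifelse(el$sign > 0, "+", "-"), el$to, sep = "\t")
    writeLines(lines, path)
  } else if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    names(el)[1:2] <- c("tf", "target")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
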