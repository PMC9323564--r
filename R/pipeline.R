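# End-to-end orchestration for one two-group comparison: differential
# expression -> expression transform -> LIONESS edge weights (pooled
# over the two compared groups only) -> moderated-t differential edges
# -> promoter-class annotation -> minimum-target filter -> centralities
# and selection -> enhancer-class annotation -> database comparisons.

#' Pipeline configuration
#'
#' Builds (and validates) the configuration for one comparison. All
#' thresholds default to the study settings: DE at BH FDR 0.1 with
#' linear fold change 1.5, differential edges at BH FDR 0.1, networks
#' kept only with at least 20 target genes, top-ten centrality lists.
#'
#' @param counts,samples,roles,promoter_db,enhancer_db input file paths
#'   (`enhancer_db` may be `NULL` to skip the database comparison).
#' @param out_dir output directory.
#' @param case_label,reference_label sample-sheet group labels defining
#'   the contrast (case first; positive logFC means higher in case).
#' @param de_fdr,de_fc,edge_fdr,min_targets,top_k thresholds.
#' @param transform `"log2norm"` or `"shrunken"`.
#' @param seed integer recorded in the manifest (the comparison itself
#'   is deterministic).
#' @param write_edge_matrix,write_graphml optional large outputs.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, roles, promoter_db,
                            enhancer_db = NULL, out_dir,
                            case_label = "case",
                            reference_label = "reference",
                            de_fdr = 0.1, de_fc = 1.5, edge_fdr = 0.1,
                            min_targets = 20, top_k = 10,
                            transform = "log2norm", seed = 1,
                            write_edge_matrix = FALSE,
                            write_graphml = FALSE) {
  if (identical(case_label, reference_label)) {
    stop("validation error: case and reference labels must differ")
  }
  for (v in c(de_fdr, edge_fdr)) {
    if (v <= 0 || v > 1) stop("validation error: FDR thresholds must be in (0, 1]")
  }
  if (de_fc < 1) stop("validation error: de_fc must be >= 1")
  if (top_k < 1) stop("validation error: top_k must be >= 1")
  structure(list(counts = counts, samples = samples, roles = roles,
                 promoter_db = promoter_db, enhancer_db = enhancer_db,
                 out_dir = out_dir, case_label = case_label,
                 reference_label = reference_label, de_fdr = de_fdr,
                 de_fc = de_fc, edge_fdr = edge_fdr,
                 min_targets = min_targets, top_k = top_k,
                 transform = transform, seed = seed,
                 write_edge_matrix = write_edge_matrix,
                 write_graphml = write_graphml),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input
#' paths are resolved against the file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^/", p)) file.path(base, p) else p
  }
  args <- y
  for (key in c("counts", "samples", "roles", "promoter_db", "enhancer_db",
                "out_dir")) {
    if (!is.null(args[[key]])) args[[key]] <- resolve(args[[key]])
  }
  do.call(pipeline_config, args)
}

# rethrow any stage error with a stage tag so callers can tell where a
# run aborted; the FAILED marker and partial outputs are left in place
with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run one comparison end-to-end
#'
#' Executes all stages for a single case-vs-reference comparison and
#' writes the result tables, networks, a run manifest and a log under
#' `config$out_dir`. When the promoter-class network holds fewer than
#' `min_targets` target genes, the centrality stage is skipped with an
#' explicit `SKIPPED` status (the network itself and all upstream tables
#' are still written).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a result bundle: list with `de`, `edges`
#'   (differential-edge table), `sig_edges`, `net_promoter`,
#'   `centrality`, `selection`, `centrality_status`, `net_enhancer`,
#'   `in_degree_comparison`, `binding_site_summary`, `manifest`.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(config$out_dir, "run.log")
  cat("comparison:", config$case_label, "vs", config$reference_label, "\n",
      file = log_file)
  logline <- function(...) {
    line <- paste(...)
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  fail_marker <- file.path(config$out_dir, "FAILED")
  on.exit({
    if (!file.exists(file.path(config$out_dir, "manifest.json"))) {
      writeLines("pipeline aborted; partial outputs retained", fail_marker)
    }
  })

  logline("[load] reading inputs")
  cm <- with_stage("load", read_counts(config$counts, config$samples,
                    case_label = config$case_label,
                    reference_label = config$reference_label))
  roles <- read_roles(config$roles)
  db_p <- load_regulatory_db(config$promoter_db, "promoter")
  db_e <- if (!is.null(config$enhancer_db)) {
    load_regulatory_db(config$enhancer_db, "enhancer")
  }
  logline("[load]", nrow(cm$counts), "genes,", ncol(cm$counts), "samples (",
          sum(cm$groups == "case"), "case /",
          sum(cm$groups == "reference"), "reference )")

  logline("[de] differential expression at FDR", config$de_fdr,
          "fold change", config$de_fc)
  de <- with_stage("de", differential_expression(cm, fdr = config$de_fdr,
                                                 fc_min = config$de_fc))
  logline("[de]", sum(de$status == "up"), "up,", sum(de$status == "down"),
          "down of", sum(de$status != "untested"), "tested genes")
  write_differential_edges(de, file.path(config$out_dir, "de_table.tsv"))

  logline("[transform] mode", config$transform)
  expr <- with_stage("transform", transform_counts(cm, mode = config$transform))

  gene_list <- intersect(roles$gene_id, rownames(expr))
  logline("[lioness] edge weights over", length(gene_list), "genes,",
          ncol(expr), "pooled samples")
  ewm <- with_stage("lioness", lioness_edge_weights(expr, gene_list))
  if (isTRUE(config$write_edge_matrix)) {
    write_edge_weights(ewm, file.path(config$out_dir, "edge_weights.tsv"))
  }

  logline("[diff-edges] moderated t over", length(ewm$pair_id), "pairs")
  edges <- with_stage("diff-edges", differential_edge_table(ewm, cm$groups))
  sig <- significant_edges(edges, fdr = config$edge_fdr)
  logline("[diff-edges]", nrow(sig), "significant of", nrow(edges),
          "pairs at FDR", config$edge_fdr)
  write_differential_edges(
    edges, file.path(config$out_dir, "differential_edges.tsv"))

  comparison_tag <- paste(config$case_label, "vs", config$reference_label)
  net_p <- with_stage("annotate-promoter",
                      annotate_network(sig, db_p, roles,
                                       comparison = comparison_tag))
  logline("[annotate:promoter]", igraph::ecount(net_p), "edges,",
          sum(igraph::V(net_p)$role == "target"), "target genes (",
          igraph::graph_attr(net_p, "n_unmatched_pairs"),
          "significant pairs without database support )")
  write_network(net_p, file.path(config$out_dir, "network_promoter.sif"),
                "sif")
  write_network(net_p, file.path(config$out_dir, "network_promoter.tsv"),
                "tsv")
  if (isTRUE(config$write_graphml)) {
    write_network(net_p,
                  file.path(config$out_dir, "network_promoter.graphml"),
                  "graphml")
  }

  centrality <- NULL
  selection <- NULL
  if (passes_target_filter(net_p, config$min_targets)) {
    centrality_status <- "OK"
    centrality <- centrality_table(net_p)
    selection <- select_central_genes(centrality, k = config$top_k)
    logline("[centrality] central TFs:",
            paste(selection$central_tfs, collapse = ", "))
    logline("[centrality] central targets:",
            paste(selection$central_targets, collapse = ", "))
    utils::write.table(centrality,
                       file.path(config$out_dir, "centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(selection[c("central_tfs", "central_targets",
                                     "top_lists")],
                         file.path(config$out_dir, "selection.json"),
                         auto_unbox = FALSE)
  } else {
    centrality_status <- "SKIPPED"
    logline("[centrality] SKIPPED:",
            sum(igraph::V(net_p)$role == "target"),
            "target genes in network, fewer than", config$min_targets)
  }

  net_e <- NULL
  indeg_cmp <- NULL
  site_summary <- NULL
  if (!is.null(db_e)) {
    net_e <- with_stage("annotate-enhancer",
                        annotate_network(sig, db_e, roles,
                                         comparison = comparison_tag))
    logline("[annotate:enhancer]", igraph::ecount(net_e), "edges,",
            sum(igraph::V(net_e)$role == "target"), "target genes")
    write_network(net_e, file.path(config$out_dir, "network_enhancer.sif"),
                  "sif")
    indeg_cmp <- compare_in_degrees(net_p, net_e, de_table = de)
    utils::write.table(indeg_cmp,
                       file.path(config$out_dir, "in_degree_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    shared_targets <- indeg_cmp$gene[indeg_cmp$in_degree_promoter > 0 &
                                       indeg_cmp$in_degree_enhancer > 0]
    site_summary <- do.call(rbind, lapply(shared_targets, function(tg) {
      suppressMessages(compare_binding_sites(db_p, db_e, tg))$summary
    }))
    if (!is.null(site_summary)) {
      utils::write.table(site_summary,
                         file.path(config$out_dir,
                                   "binding_site_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glyconet")),
    comparison = comparison_tag,
    seed = config$seed,
    thresholds = config[c("de_fdr", "de_fc", "edge_fdr", "min_targets",
                          "top_k")],
    transform = config$transform,
    n_case = sum(cm$groups == "case"),
    n_ref = sum(cm$groups == "reference"),
    n_genes = nrow(cm$counts),
    n_pairs_tested = attr(edges, "n_tests"),
    bh_denominator = attr(edges, "n_tests"),
    eb_prior = list(d0 = attr(edges, "d0"), s0_sq = attr(edges, "s0_sq")),
    n_significant_edges = nrow(sig),
    n_network_edges_promoter = igraph::ecount(net_p),
    n_network_targets_promoter = sum(igraph::V(net_p)$role == "target"),
    centrality_status = centrality_status
  )
  # self-consistency before writing
  stopifnot(manifest$n_pairs_tested == nrow(edges),
            manifest$n_significant_edges == nrow(sig))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logline("[done] outputs in", config$out_dir)

  invisible(list(de = de, expr = expr, ewm = ewm, edges = edges,
                 sig_edges = sig, net_promoter = net_p,
                 centrality = centrality, selection = selection,
                 centrality_status = centrality_status,
                 net_enhancer = net_e, in_degree_comparison = indeg_cmp,
                 binding_site_summary = site_summary, manifest = manifest))
}
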