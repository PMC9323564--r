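# Single-sample co-expression edge weights by linear interpolation
# (LIONESS). For an aggregate Pearson correlation e_alpha over N samples
# and the leave-one-out correlation e_alpha_minus_q without sample q, the
# weight attributed to sample q is
#
#   e_q = N * (e_alpha - e_alpha_minus_q) + e_alpha_minus_q
#
# Correlations are bounded in [-1, 1] but e_q is not: no clipping is
# applied, by design.

# Pearson correlation matrix over samples with constant genes mapped to
# zero correlation instead of NA.
cor_safe <- function(x, warn = TRUE) {
  sds <- apply(x, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(x)))
  if (any(sds == 0)) {
    if (warn) {
      warning("constant gene(s) ", paste(rownames(x)[sds == 0], collapse = ", "),
              ": correlations set to 0", call. = FALSE)
    }
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  cc
}

pair_index <- function(genes) {
  idx <- utils::combn(seq_along(genes), 2)
  list(i = idx[1, ], j = idx[2, ],
       gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
       pair_id = paste(genes[idx[1, ]], genes[idx[2, ]], sep = "|"))
}

#' Aggregate co-expression network
#'
#' Pearson correlation over all samples for every canonical (unordered,
#' lexicographically stored) gene pair in the subset. Constant genes get
#' correlation 0 with a warning; such pairs can never reach significance
#' downstream.
#'
#' @param expr transformed expression matrix, genes x samples.
#' @param gene_subset genes to use (default: all rows); order is
#'   canonicalized by sorting.
#' @return data frame with `gene_a`, `gene_b`, `pair_id`, `e_alpha`.
#' @export
aggregate_network <- function(expr, gene_subset = rownames(expr)) {
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing) > 0) {
    stop("genes not in expression matrix: ", paste(missing, collapse = ", "))
  }
  if (ncol(expr) < 3) stop("insufficient samples: need >= 3")
  genes <- sort(unique(gene_subset))
  if (length(genes) < 2) stop("need at least 2 genes")
  x <- expr[genes, , drop = FALSE]
  cc <- cor_safe(x)
  pr <- pair_index(genes)
  data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b, pair_id = pr$pair_id,
             e_alpha = cc[cbind(pr$i, pr$j)], stringsAsFactors = FALSE)
}

#' LIONESS single-sample edge weights
#'
#' Computes, for every canonical gene pair and every sample q, the
#' sample-specific edge weight `e_q = N (e_alpha - e_alpha_minus_q) +
#' e_alpha_minus_q`, via one aggregate and N leave-one-out full
#' correlation-matrix evaluations (clarity and exactness over rank-one
#' updates at this scale).
#'
#' @param expr transformed expression matrix, genes x samples.
#' @param gene_subset genes to use (default: all rows).
#' @return object of class `edge_weight_matrix`: list with `gene_a`,
#'   `gene_b`, `pair_id`, `aggregate` (e_alpha per pair), `loo`
#'   (pairs x samples leave-one-out correlations), `weights`
#'   (pairs x samples e_q), `sample_ids`, `n_samples`.
#' @export
lioness_edge_weights <- function(expr, gene_subset = rownames(expr)) {
  n <- ncol(expr)
  if (n < 4) stop("insufficient samples: leave-one-out needs N >= 4")
  agg <- aggregate_network(expr, gene_subset)
  genes <- sort(unique(gene_subset))
  x <- expr[genes, , drop = FALSE]
  pr <- pair_index(genes)
  ij <- cbind(pr$i, pr$j)

  loo <- matrix(NA_real_, nrow = length(pr$i), ncol = n)
  for (q in seq_len(n)) {
    cc <- cor_safe(x[, -q, drop = FALSE], warn = FALSE)
    loo[, q] <- cc[ij]
  }
  weights <- n * (agg$e_alpha - loo) + loo
  dimnames(loo) <- dimnames(weights) <- list(pr$pair_id, colnames(expr))

  structure(list(gene_a = pr$gene_a, gene_b = pr$gene_b,
                 pair_id = pr$pair_id, aggregate = agg$e_alpha,
                 loo = loo, weights = weights,
                 sample_ids = colnames(expr), n_samples = n),
            class = "edge_weight_matrix")
}

#' @export
print.edge_weight_matrix <- function(x, ...) {
  cat("edge_weight_matrix:", length(x$pair_id), "pairs x", x$n_samples,
      "samples\n")
  invisible(x)
}

#' Write an edge-weight matrix as TSV
#'
#' One row per pair (`pair_id = "geneA|geneB"`), one column per sample.
#' Large for realistic gene lists, hence a separate opt-in writer.
#'
#' @param ewm an [lioness_edge_weights()] result.
#' @param path output file.
#' @export
write_edge_weights <- function(ewm, path) {
  df <- data.frame(pair_id = ewm$pair_id, ewm$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
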