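# Synthetic-data generator: negative-binomial counts with planted
# group-specific co-expression, planted DE genes, and regulatory tables
# with controlled coverage of the planted differential pairs. Everything
# downstream of read counting can be exercised against this ground truth.

#' Simulation design for a two-group count study
#'
#' Describes a synthetic bulk RNA-seq experiment over a TF/target gene
#' list: baseline negative-binomial count marginals, differential
#' expression planted in the case group, and group-specific pairwise
#' correlation planted on the latent (Gaussian copula) scale.
#'
#' @param n_tf number of TF-role genes (>= 1).
#' @param n_target number of target-role (glycolysis-related) genes (>= 1).
#' @param n_case,n_ref samples per group (each >= 3).
#' @param mu_range interval for baseline mean counts; gene means are drawn
#'   log-uniformly from it.
#' @param dispersion negative-binomial dispersion phi, so that
#'   `var = mu + phi * mu^2`; `0` gives Poisson counts.
#' @param de_plan `NULL` or a data frame with columns `gene`, `log2fc`:
#'   genes whose case-group mean is shifted by `2^log2fc`.
#' @param coexpr_plan `NULL` or a data frame with columns `gene_a`,
#'   `gene_b`, `r_case`, `r_ref`: latent-scale correlations planted per
#'   group (all `|r| < 1`).
#' @param db_coverage default fraction of planted differential pairs to be
#'   covered by a simulated regulatory table (in `[0, 1]`).
#' @param hub_min_pairs minimum number of planted differential pairs a TF
#'   must participate in to be recorded as a planted hub.
#' @param seed master seed; independent RNG streams for gene roles,
#'   baseline means, latent draws and regulatory tables are derived from
#'   it.
#' @return an object of class `sim_design`.
#' @seealso [simulate_counts()], [simulate_regulatory_db()]
#' @export
sim_design <- function(n_tf, n_target, n_case, n_ref,
                       mu_range = c(20, 2000), dispersion = 0.05,
                       de_plan = NULL, coexpr_plan = NULL,
                       db_coverage = 1, hub_min_pairs = 10, seed = 1) {
  if (!is.numeric(n_tf) || !is.numeric(n_target) || n_tf < 1 || n_target < 1) {
    stop("invalid design: n_tf and n_target must be positive counts")
  }
  if (n_case < 3 || n_ref < 3) {
    stop("invalid design: need at least 3 samples per group")
  }
  if (dispersion < 0) stop("invalid design: dispersion must be >= 0")
  if (length(mu_range) != 2 || any(mu_range <= 0) || mu_range[1] > mu_range[2]) {
    stop("invalid design: mu_range must be a positive interval")
  }
  if (db_coverage < 0 || db_coverage > 1) {
    stop("invalid design: db_coverage must be in [0, 1]")
  }
  if (!is.null(de_plan)) {
    stopifnot(is.data.frame(de_plan),
              all(c("gene", "log2fc") %in% names(de_plan)))
    if (anyDuplicated(de_plan$gene)) stop("invalid design: duplicate DE genes")
  }
  if (!is.null(coexpr_plan)) {
    stopifnot(is.data.frame(coexpr_plan),
              all(c("gene_a", "gene_b", "r_case", "r_ref") %in%
                    names(coexpr_plan)))
    if (any(coexpr_plan$gene_a == coexpr_plan$gene_b)) {
      stop("invalid design: self-pairs in coexpr_plan")
    }
    if (any(abs(c(coexpr_plan$r_case, coexpr_plan$r_ref)) >= 1)) {
      stop("invalid design: planted correlations must satisfy |r| < 1")
    }
  }
  structure(list(n_tf = as.integer(n_tf), n_target = as.integer(n_target),
                 n_case = as.integer(n_case), n_ref = as.integer(n_ref),
                 mu_range = as.numeric(mu_range),
                 dispersion = as.numeric(dispersion),
                 de_plan = de_plan, coexpr_plan = coexpr_plan,
                 db_coverage = db_coverage,
                 hub_min_pairs = as.integer(hub_min_pairs),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a gene-role table
#'
#' Creates unique gene identifiers labelled with their network role:
#' `TF` (regulator, may have outgoing edges) or `target`
#' (glycolysis-related, incoming edges only).
#'
#' @param n_tf,n_target positive counts of genes per role.
#' @param seed integer; the returned row order is a seeded permutation so
#'   that downstream code never relies on role blocks being contiguous.
#' @return data frame with columns `gene_id`, `role`.
#' @export
generate_gene_roles <- function(n_tf, n_target, seed = 1) {
  if (n_tf < 1 || n_target < 1) {
    stop("invalid design: gene counts must be positive")
  }
  roles <- data.frame(
    gene_id = c(sprintf("TF%04d", seq_len(n_tf)),
                sprintf("GLY%03d", seq_len(n_target))),
    role = rep(c("TF", "target"), c(n_tf, n_target)),
    stringsAsFactors = FALSE
  )
  s <- derive_seeds(seed, 1L)
  set.seed(s)
  roles <- roles[sample.int(nrow(roles)), , drop = FALSE]
  rownames(roles) <- NULL
  roles
}

# Build one latent correlation matrix from the plan's per-group column,
# validate positive semi-definiteness, and return its Cholesky-like
# factor (via eigen so that exact-PSD boundary cases are accepted).
latent_factor <- function(genes, plan, r_col) {
  p <- length(genes)
  sigma <- diag(p)
  dimnames(sigma) <- list(genes, genes)
  if (!is.null(plan) && nrow(plan) > 0) {
    ia <- match(plan$gene_a, genes)
    ib <- match(plan$gene_b, genes)
    if (anyNA(ia) || anyNA(ib)) {
      missing <- unique(c(plan$gene_a[is.na(ia)], plan$gene_b[is.na(ib)]))
      stop("invalid design: planted genes not in gene list: ",
           paste(missing, collapse = ", "))
    }
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    if (anyDuplicated(key)) stop("invalid design: duplicate planted pairs")
    sigma[cbind(ia, ib)] <- plan[[r_col]]
    sigma[cbind(ib, ia)] <- plan[[r_col]]
  }
  ev <- eigen(sigma, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ev$values))
  if (min(ev$values) < -tol) {
    bad <- which(ev$values < -tol)
    load <- abs(ev$vectors[, bad, drop = FALSE])
    involved <- genes[rowSums(load) > sqrt(.Machine$double.eps)]
    off <- plan[plan$gene_a %in% involved | plan$gene_b %in% involved, ]
    stop("infeasible correlation structure (latent covariance not ",
         "positive semi-definite); offending pairs: ",
         paste(paste(off$gene_a, off$gene_b, sep = "-"), collapse = ", "))
  }
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Simulate a count matrix with planted structure
#'
#' Draws a genes-by-samples integer count matrix for a two-group design.
#' Pairwise correlation is planted on the latent Gaussian scale: a
#' standard multivariate normal draw with the group's planted correlation
#' matrix is pushed through exact negative-binomial marginal quantiles
#' (`qnbinom(pnorm(z))`, Gaussian copula), so count marginals are exactly
#' NB(mu, phi) while log-scale sample correlations attain the plants.
#' Planted DE genes have their case-group mean shifted by `2^log2fc`.
#'
#' @param design a [sim_design()] object.
#' @return list with components `counts` (a `count_matrix`), `roles`
#'   (gene-role data frame) and `truth` (a `sim_truth` list recording
#'   `de_genes`, `diff_pairs`, `hub_tfs` and `baseline_mu`).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  seeds <- derive_seeds(design$seed, 4L)
  roles <- generate_gene_roles(design$n_tf, design$n_target, seeds[1])
  genes <- sort(roles$gene_id)
  p <- length(genes)

  if (!is.null(design$de_plan)) {
    missing <- setdiff(design$de_plan$gene, genes)
    if (length(missing) > 0) {
      stop("invalid design: DE genes not in gene list: ",
           paste(missing, collapse = ", "))
    }
  }

  set.seed(seeds[2])
  mu <- exp(runif(p, log(design$mu_range[1]), log(design$mu_range[2])))
  names(mu) <- genes

  fac_case <- latent_factor(genes, design$coexpr_plan, "r_case")
  fac_ref <- latent_factor(genes, design$coexpr_plan, "r_ref")

  n_case <- design$n_case
  n_ref <- design$n_ref
  set.seed(seeds[3])
  z_case <- fac_case %*% matrix(rnorm(p * n_case), p, n_case)
  z_ref <- fac_ref %*% matrix(rnorm(p * n_ref), p, n_ref)

  mu_case <- mu
  if (!is.null(design$de_plan)) {
    idx <- match(design$de_plan$gene, genes)
    mu_case[idx] <- mu[idx] * 2^design$de_plan$log2fc
  }

  nb_quantile <- function(u, m) {
    if (design$dispersion == 0) {
      qpois(u, lambda = m)
    } else {
      qnbinom(u, mu = m, size = 1 / design$dispersion)
    }
  }
  counts_case <- nb_quantile(pnorm(z_case), mu_case)
  counts_ref <- nb_quantile(pnorm(z_ref), mu)
  counts <- cbind(matrix(counts_case, p, n_case),
                  matrix(counts_ref, p, n_ref))
  storage.mode(counts) <- "integer"
  rownames(counts) <- genes
  colnames(counts) <- c(sprintf("case_%02d", seq_len(n_case)),
                        sprintf("ref_%02d", seq_len(n_ref)))
  groups <- setNames(rep(c("case", "reference"), c(n_case, n_ref)),
                     colnames(counts))

  diff_pairs <- data.frame(gene_a = character(), gene_b = character(),
                           r_case = numeric(), r_ref = numeric(),
                           stringsAsFactors = FALSE)
  if (!is.null(design$coexpr_plan)) {
    cp <- design$coexpr_plan
    diff <- cp[cp$r_case != cp$r_ref, , drop = FALSE]
    if (nrow(diff) > 0) {
      cano <- canonical_pair(diff$gene_a, diff$gene_b)
      diff_pairs <- data.frame(gene_a = cano$gene_a, gene_b = cano$gene_b,
                               r_case = diff$r_case, r_ref = diff$r_ref,
                               stringsAsFactors = FALSE)
      diff_pairs <- diff_pairs[order(cano$pair_id), , drop = FALSE]
      rownames(diff_pairs) <- NULL
    }
  }
  tf_ids <- roles$gene_id[roles$role == "TF"]
  pair_members <- c(diff_pairs$gene_a, diff_pairs$gene_b)
  tf_counts <- table(pair_members[pair_members %in% tf_ids])
  hub_tfs <- names(tf_counts)[tf_counts >= design$hub_min_pairs]

  de_genes <- numeric(0)
  if (!is.null(design$de_plan)) {
    de_genes <- setNames(design$de_plan$log2fc, design$de_plan$gene)
  }
  truth <- structure(list(de_genes = de_genes, diff_pairs = diff_pairs,
                          hub_tfs = sort(hub_tfs), baseline_mu = mu,
                          db_edges = NULL),
                     class = "sim_truth")
  list(counts = count_matrix(counts, groups), roles = roles, truth = truth)
}

#' Simulate a directed regulatory-interaction table
#'
#' Emits TF-to-target records mimicking a promoter-class (GTRD-like) or
#' enhancer-class (GeneHancer-like) database: a `db_coverage` fraction of
#' the planted differential pairs that contain a TF member (direction
#' TF -> partner), plus `extra_edges` decoy records not related to any
#' plant. Binding-site counts are drawn from a shifted geometric
#' distribution (support >= 1), mimicking the long right tail of real
#' binding-site counts.
#'
#' @param roles gene-role data frame (`gene_id`, `role`).
#' @param truth a `sim_truth` object from [simulate_counts()].
#' @param db_coverage fraction of eligible planted pairs to include.
#' @param extra_edges number of decoy records.
#' @param region_class `"promoter"` or `"enhancer"`.
#' @param seed RNG seed for pair selection, decoys and site counts.
#' @return a `regulatory_db` data frame (columns `tf`, `target`,
#'   `binding_sites`, `region_class`) with attribute `db_name`.
#' @export
simulate_regulatory_db <- function(roles, truth, db_coverage = 1,
                                   extra_edges = 0,
                                   region_class = c("promoter", "enhancer"),
                                   seed = 1) {
  region_class <- match.arg(region_class)
  stopifnot(inherits(truth, "sim_truth"))
  if (db_coverage < 0 || db_coverage > 1) stop("db_coverage must be in [0, 1]")
  tf_ids <- roles$gene_id[roles$role == "TF"]

  dp <- truth$diff_pairs
  cand <- dp[dp$gene_a %in% tf_ids | dp$gene_b %in% tf_ids, , drop = FALSE]
  # direction: TF -> partner; for TF-TF pairs the canonical first member
  # is taken as the source
  src <- ifelse(cand$gene_a %in% tf_ids, cand$gene_a, cand$gene_b)
  dst <- ifelse(cand$gene_a %in% tf_ids, cand$gene_b, cand$gene_a)

  set.seed(derive_seeds(seed, 1L))
  n_keep <- round(db_coverage * length(src))
  keep <- if (n_keep >= length(src)) seq_along(src) else
    sort(sample.int(length(src), n_keep))
  tf <- src[keep]
  target <- dst[keep]

  if (extra_edges > 0) {
    have <- paste(tf, target)
    decoy_tf <- character(0)
    decoy_tg <- character(0)
    all_genes <- roles$gene_id
    while (length(decoy_tf) < extra_edges) {
      need <- extra_edges - length(decoy_tf)
      t1 <- sample(tf_ids, need, replace = TRUE)
      t2 <- sample(all_genes, need, replace = TRUE)
      ok <- t1 != t2 & !(paste(t1, t2) %in% c(have, paste(decoy_tf, decoy_tg)))
      ok <- ok & !duplicated(paste(t1, t2))
      decoy_tf <- c(decoy_tf, t1[ok])
      decoy_tg <- c(decoy_tg, t2[ok])
    }
    tf <- c(tf, decoy_tf)
    target <- c(target, decoy_tg)
  }

  db <- data.frame(tf = tf, target = target,
                   binding_sites = 1L + rgeom(length(tf), prob = 0.3),
                   region_class = rep(region_class, length(tf)),
                   stringsAsFactors = FALSE)
  regulatory_db(db, db_name = paste0("synthetic_", region_class))
}

#' Write a simulated fixture bundle to disk
#'
#' Writes the plain-text files a pipeline run consumes: counts TSV,
#' sample sheet TSV, gene-roles TSV, one regulatory TSV per region class,
#' and the ground truth as JSON.
#'
#' @param sim output of [simulate_counts()].
#' @param dbs named list of `regulatory_db` objects (names used in file
#'   names).
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_sim_bundle <- function(sim, dbs = list(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             roles = file.path(dir, "roles.tsv"),
             truth = file.path(dir, "truth.json"))
  cm <- sim$counts
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths[["counts"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(cm$groups),
                                group = unname(cm$groups)),
                     paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$roles, paths[["roles"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(de_genes = as.list(truth$de_genes),
         diff_pairs = truth$diff_pairs,
         hub_tfs = truth$hub_tfs),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  for (nm in names(dbs)) {
    p <- file.path(dir, paste0("regdb_", nm, ".tsv"))
    utils::write.table(dbs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Hub-and-spoke simulation design
#'
#' Convenience constructor for the fixture geometry the pipeline tests
#' use: a set of TF-led equicorrelated blocks (one TF plus
#' `block_sizes[i]` target genes, all pairwise at `r_case` in the case
#' group and `r_ref` in the reference group) plus disjoint single
#' TF-target pairs. The first block's TF is the planted dominant hub.
#' Blocks must be equicorrelated because a correlation star is not
#' positive semi-definite once a TF has more than `1/r^2` independent
#' partners; the within-block target-target pairs this implies are
#' recorded in the ground truth like every other planted pair.
#'
#' @param n_tf,n_target,n_case,n_ref as in [sim_design()].
#' @param block_sizes target count per TF-led block (descending makes
#'   the first TF the dominant hub).
#' @param n_single_pairs additional disjoint TF-target pairs.
#' @param r_case,r_ref planted correlations for every planted pair.
#' @param de_plan,mu_range,dispersion,db_coverage,hub_min_pairs,seed as
#'   in [sim_design()]; `de_plan = NULL` plants two up- and two
#'   down-regulated target genes at |log2fc| = 1.5.
#' @return a `sim_design` whose attribute `hub_tf` names the planted
#'   dominant hub.
#' @export
hub_and_spoke_design <- function(n_tf = 50, n_target = 50,
                                 n_case = 10, n_ref = 10,
                                 block_sizes = c(12, 6, 5, 4, 3, 3, 2, 2, 2, 2),
                                 n_single_pairs = 9,
                                 r_case = 0.9, r_ref = 0,
                                 de_plan = NULL,
                                 mu_range = c(50, 2000), dispersion = 0.05,
                                 db_coverage = 1, hub_min_pairs = 10,
                                 seed = 1) {
  n_block_tfs <- length(block_sizes)
  need_tf <- n_block_tfs + n_single_pairs
  need_target <- sum(block_sizes) + n_single_pairs
  if (n_tf < need_tf || n_target < need_target) {
    stop("invalid design: need at least ", need_tf, " TFs and ",
         need_target, " targets for this layout")
  }
  tfs <- sprintf("TF%04d", seq_len(n_tf))
  targets <- sprintf("GLY%03d", seq_len(n_target))

  plan <- list()
  used <- 0L
  for (b in seq_len(n_block_tfs)) {
    members <- c(tfs[b], targets[used + seq_len(block_sizes[b])])
    used <- used + block_sizes[b]
    idx <- utils::combn(members, 2)
    plan[[b]] <- data.frame(gene_a = idx[1, ], gene_b = idx[2, ],
                            r_case = r_case, r_ref = r_ref,
                            stringsAsFactors = FALSE)
  }
  if (n_single_pairs > 0) {
    plan[[n_block_tfs + 1]] <- data.frame(
      gene_a = tfs[n_block_tfs + seq_len(n_single_pairs)],
      gene_b = targets[used + seq_len(n_single_pairs)],
      r_case = r_case, r_ref = r_ref, stringsAsFactors = FALSE)
  }
  coexpr_plan <- do.call(rbind, plan)

  if (is.null(de_plan)) {
    de_plan <- data.frame(
      gene = targets[seq_len(4)],
      log2fc = c(1.5, 1.5, -1.5, -1.5),
      stringsAsFactors = FALSE)
  }

  design <- sim_design(n_tf = n_tf, n_target = n_target, n_case = n_case,
                       n_ref = n_ref, mu_range = mu_range,
                       dispersion = dispersion, de_plan = de_plan,
                       coexpr_plan = coexpr_plan, db_coverage = db_coverage,
                       hub_min_pairs = hub_min_pairs, seed = seed)
  attr(design, "hub_tf") <- tfs[1]
  design
}
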