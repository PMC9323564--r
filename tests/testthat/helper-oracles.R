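# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (loops, enumeration) and never call the package
# code paths they check.

# Brute-force LIONESS: recompute aggregate and leave-one-out Pearson
# correlation per left-out sample with plain loops.
oracle_lioness <- function(x, gi, gj) {
  n <- ncol(x)
  ea <- stats::cor(x[gi, ], x[gj, ])
  vapply(seq_len(n), function(q) {
    el <- stats::cor(x[gi, -q], x[gj, -q])
    n * (ea - el) + el
  }, numeric(1))
}

# Textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive directed betweenness: enumerate all shortest paths between
# every ordered node pair via BFS, count pass-through fractions.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_shortest <- function(s, t) {
    # BFS returning every shortest s->t path as a list of node vectors
    if (s == t) return(list())
    paths <- list(s)
    found <- list()
    visited_depth <- rep(Inf, n)
    visited_depth[s] <- 0
    depth <- 0
    while (length(paths) > 0 && length(found) == 0) {
      depth <- depth + 1
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        for (v in which(adj[last, ] > 0)) {
          if (visited_depth[v] < depth) next
          visited_depth[v] <- depth
          np <- c(p, v)
          if (v == t) found[[length(found) + 1]] <- np else {
            nxt[[length(nxt) + 1]] <- np
          }
        }
      }
      paths <- nxt
    }
    found
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- all_shortest(s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

# Random directed graph as an annotated-network igraph, with roles.
random_net <- function(n_tf, n_target, p_edge = 0.3, seed = 1) {
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tf))
  tgs <- sprintf("GL%02d", seq_len(n_target))
  from <- character(0); to <- character(0)
  for (a in tfs) {
    for (b in c(tfs, tgs)) {
      if (a != b && stats::runif(1) < p_edge) {
        from <- c(from, a); to <- c(to, b)
      }
    }
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to,
               sign = sample(c(-1, 1), length(from), replace = TRUE),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = c(tfs, tgs),
                          role = rep(c("TF", "target"), c(n_tf, n_target)),
                          stringsAsFactors = FALSE))
}

# Tiny hand-built network: sig pairs + DB + roles -> annotated graph.
toy_network <- function(edges_df) {
  roles <- data.frame(
    gene_id = unique(c(edges_df$tf, edges_df$target)),
    stringsAsFactors = FALSE)
  roles$role <- ifelse(roles$gene_id %in% edges_df$tf, "TF", "target")
  db <- regulatory_db(data.frame(tf = edges_df$tf, target = edges_df$target,
                                 binding_sites = 1L,
                                 region_class = "promoter",
                                 stringsAsFactors = FALSE))
  cano <- canonical_sig(edges_df$tf, edges_df$target)
  annotate_network(cano, db, roles)
}

canonical_sig <- function(a, b, sign = 1) {
  ga <- pmin(a, b); gb <- pmax(a, b)
  data.frame(gene_a = ga, gene_b = gb, sign = rep_len(sign, length(ga)),
             stringsAsFactors = FALSE)
}

# Small expression matrix of independent Gaussian genes.
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
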