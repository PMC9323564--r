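# Degree, betweenness, HITS scores, top-k selection.

test_that("degrees satisfy star and handshake properties", {
  star <- toy_network(data.frame(tf = "TF1",
                                 target = sprintf("G%02d", 1:5)))
  deg <- degree_centrality(star)
  expect_equal(deg$out_degree[deg$node == "TF1"], 5)
  expect_true(all(deg$in_degree[deg$node != "TF1"] == 1))
  for (seed in 1:4) {
    rn <- random_net(5, 4, seed = seed)
    d <- degree_centrality(rn)
    expect_equal(sum(d$in_degree), igraph::ecount(rn))
    expect_equal(sum(d$out_degree), igraph::ecount(rn))
  }
})

test_that("a planted high in-degree is reported exactly", {
  net <- toy_network(data.frame(tf = sprintf("TF%03d", 1:103),
                                target = "GLY001"))
  deg <- degree_centrality(net)
  expect_equal(deg$in_degree[deg$node == "GLY001"], 103)
})

test_that("betweenness: path case, sink property, brute-force oracle", {
  # chain of TFs: A -> B -> C
  roles <- data.frame(gene_id = c("A", "B", "C"), role = "TF")
  db <- regulatory_db(data.frame(tf = c("A", "B"), target = c("B", "C"),
                                 binding_sites = 1L,
                                 region_class = "promoter"))
  chain <- annotate_network(canonical_sig(c("A", "B"), c("B", "C")), db, roles)
  btw <- betweenness_centrality(chain)
  expect_equal(unname(btw[c("A", "B", "C")]), c(0, 1, 0))

  for (seed in 1:6) {
    rn <- random_net(7, 5, p_edge = 0.25, seed = seed)
    btw <- betweenness_centrality(rn)
    expect_true(all(btw[igraph::V(rn)$role == "target"] == 0))
    adj <- igraph::as_adjacency_matrix(rn, sparse = FALSE)
    expect_equal(unname(btw), oracle_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("HITS scores solve the mutual-reinforcement fixed point", {
  single <- toy_network(data.frame(tf = "A", target = "B"))
  h <- hits_scores(single)
  expect_equal(unname(h$hub[c("A", "B")]), c(1, 0))
  expect_equal(unname(h$authority[c("A", "B")]), c(0, 1))

  bip <- toy_network(expand.grid(tf = c("T1", "T2"),
                                 target = c("G1", "G2", "G3"),
                                 stringsAsFactors = FALSE))
  hb <- hits_scores(bip)
  expect_equal(unname(hb$hub[c("T1", "T2")]), rep(1 / sqrt(2), 2),
               tolerance = 1e-8)
  expect_equal(unname(hb$authority[c("G1", "G2", "G3")]),
               rep(1 / sqrt(3), 3), tolerance = 1e-8)

  for (seed in 1:20) {
    rn <- random_net(sample(3:8, 1), sample(2:7, 1), p_edge = 0.4,
                     seed = 400 + seed)
    if (igraph::ecount(rn) == 0) next
    h <- hits_scores(rn)
    a_mat <- igraph::as_adjacency_matrix(rn, sparse = FALSE)
    # authority = principal eigenvector of A'A (up to sign); skip the
    # rare near-degenerate spectra where that vector is not unique
    es <- eigen(crossprod(a_mat), symmetric = TRUE)
    if (es$values[1] - es$values[2] < 1e-6) next
    ev <- es$vectors[, 1]
    ev <- ev * sign(sum(ev * h$authority))
    expect_equal(unname(h$authority), ev / sqrt(sum(ev^2)), tolerance = 1e-8)
    # fixed point: A %*% authority proportional to hub
    pred_hub <- unname(drop(a_mat %*% h$authority))
    if (sqrt(sum(pred_hub^2)) > 0) {
      expect_equal(pred_hub / sqrt(sum(pred_hub^2)), unname(h$hub),
                   tolerance = 1e-8)
    }
    expect_equal(sqrt(sum(h$hub^2)), 1, tolerance = 1e-10)
    expect_true(all(h$hub >= -1e-12) && all(h$authority >= -1e-12))
  }
})

test_that("top_k applies the tie policy and role restriction", {
  tab <- data.frame(
    node = c(sprintf("TF%02d", 1:12), sprintf("G%02d", 1:4)),
    role = rep(c("TF", "target"), c(12, 4)),
    in_degree = c(rep(0, 12), 4:1),
    out_degree = c(12:1, rep(0, 4)),
    betweenness = c(12:1, rep(0, 4)),
    hub = c(12:1, rep(0, 4)) / 100,
    authority = c(rep(0, 12), 4:1) / 10)
  expect_length(top_k(tab, "out_degree", k = 10), 10)
  expect_identical(top_k(tab, "out_degree", k = 10),
                   sprintf("TF%02d", 1:10))
  suppressMessages(expect_length(top_k(tab, "in_degree", k = 10), 4))

  tied <- tab
  tied$out_degree <- c(5, 5, rep(4, 10), rep(0, 4))
  expect_length(top_k(tied, "out_degree", k = 2), 2)
  tied$out_degree <- c(5, 4, rep(4, 10), rep(0, 4))
  expect_length(top_k(tied, "out_degree", k = 2), 12)  # rank-2 tie expands
})

test_that("central-gene selection intersects the top lists", {
  star <- toy_network(data.frame(tf = "TF1",
                                 target = sprintf("G%02d", 1:6)))
  tab <- centrality_table(star)
  sel <- suppressMessages(select_central_genes(tab))
  expect_identical(sel$central_tfs, "TF1")
  expect_setequal(sel$central_targets, sprintf("G%02d", 1:6))

  # hub TF with dominant out-degree and hub score tops the selection
  edges <- rbind(
    expand.grid(tf = "HUB", target = sprintf("G%02d", 1:12),
                stringsAsFactors = FALSE),
    data.frame(tf = sprintf("TF%02d", 1:15),
               target = sprintf("G%02d", c(1:12, 1:3))))
  big <- toy_network(edges)
  sel2 <- suppressMessages(select_central_genes(centrality_table(big)))
  expect_true("HUB" %in% sel2$central_tfs)
})

test_that("selection is equivariant under node relabeling", {
  edges <- data.frame(tf = c("TF1", "TF1", "TF1", "TF2", "TF3"),
                      target = c("G1", "G2", "G3", "G1", "G2"))
  sel <- suppressMessages(select_central_genes(centrality_table(toy_network(edges))))
  relabel <- c(TF1 = "TFX", TF2 = "TFY", TF3 = "TFZ",
               G1 = "GA", G2 = "GB", G3 = "GC")
  edges2 <- data.frame(tf = unname(relabel[edges$tf]),
                       target = unname(relabel[edges$target]))
  sel2 <- suppressMessages(select_central_genes(centrality_table(toy_network(edges2))))
  expect_setequal(unname(relabel[sel$central_tfs]), sel2$central_tfs)
  expect_setequal(unname(relabel[sel$central_targets]), sel2$central_targets)
})

test_that("empty and edgeless networks degrade gracefully", {
  empty <- annotate_network(
    data.frame(gene_a = character(), gene_b = character(), sign = numeric()),
    regulatory_db(data.frame(tf = "TF1", target = "G1", binding_sites = 1L,
                             region_class = "promoter")),
    data.frame(gene_id = c("TF1", "G1"), role = c("TF", "target")))
  tab <- centrality_table(empty)
  expect_equal(nrow(tab), 0)
  expect_error(hits_scores(empty), "nonempty")
})
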