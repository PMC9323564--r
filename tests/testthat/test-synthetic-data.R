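# Synthetic-data generator: role tables, planted correlation and DE
# structure, NB marginals, regulatory-table coverage.

test_that("gene roles have requested counts, unique ids, seed determinism", {
  roles <- generate_gene_roles(1233, 74, seed = 3)
  expect_equal(nrow(roles), 1307)
  expect_equal(sum(roles$role == "TF"), 1233)
  expect_equal(sum(roles$role == "target"), 74)
  expect_false(anyDuplicated(roles$gene_id) > 0)

  tiny <- generate_gene_roles(1, 1, seed = 0)
  expect_setequal(tiny$role, c("TF", "target"))

  expect_identical(generate_gene_roles(5, 3, seed = 7),
                   generate_gene_roles(5, 3, seed = 7))
  expect_error(generate_gene_roles(0, 3), "positive")
})

test_that("simulate_counts is deterministic and marginals are NB-consistent", {
  design <- sim_design(n_tf = 10, n_target = 10, n_case = 100, n_ref = 100,
                       mu_range = c(100, 1000), dispersion = 0.1, seed = 5)
  sim1 <- simulate_counts(design)
  sim2 <- simulate_counts(design)
  expect_identical(sim1$counts$counts, sim2$counts$counts)

  cm <- sim1$counts$counts
  expect_true(all(cm >= 0))
  expect_type(cm[1, 1], "integer")
  mu <- sim1$truth$baseline_mu[rownames(cm)]
  means <- rowMeans(cm)
  vars <- apply(cm, 1, var)
  # NB(mu, phi): var = mu + phi mu^2; generous band for n = 200 draws
  expect_true(all(abs(means - mu) / mu < 0.2))
  expect_true(all(vars > means))  # overdispersed when phi > 0
  expect_true(all(abs(vars / (mu + 0.1 * mu^2) - 1) < 0.5))
})

test_that("planted correlations are attained on log counts at large n", {
  plan <- data.frame(gene_a = c("TF0001", "TF0002", "GLY001"),
                     gene_b = c("GLY001", "GLY002", "GLY003"),
                     r_case = c(0.9, -0.5, 0.0),
                     r_ref = c(0.0, 0.0, 0.7),
                     stringsAsFactors = FALSE)
  # GLY001 in two pairs (0.9 with TF0001, 0 with GLY003): PSD fine
  design <- sim_design(n_tf = 3, n_target = 3, n_case = 250, n_ref = 250,
                       mu_range = c(200, 800), dispersion = 0.05,
                       coexpr_plan = plan, seed = 11)
  sim <- simulate_counts(design)
  lg <- log1p(sim$counts$counts)
  for (grp in c("case", "reference")) {
    idx <- sim$counts$groups == grp
    col <- if (grp == "case") "r_case" else "r_ref"
    for (k in seq_len(nrow(plan))) {
      r_hat <- cor(lg[plan$gene_a[k], idx], lg[plan$gene_b[k], idx])
      expect_lt(abs(r_hat - plan[[col]][k]), 0.1,
                label = sprintf("attained r (%s, pair %d); |diff|", grp, k))
    }
  }
})

test_that("infeasible correlation structure fails loudly naming pairs", {
  # correlation star: one gene at r = 0.9 with 3 mutually independent
  # partners is not positive semi-definite
  star <- data.frame(gene_a = "TF0001",
                     gene_b = c("GLY001", "GLY002", "GLY003"),
                     r_case = 0.9, r_ref = 0, stringsAsFactors = FALSE)
  design <- sim_design(n_tf = 2, n_target = 3, n_case = 5, n_ref = 5,
                       coexpr_plan = star, seed = 1)
  expect_error(simulate_counts(design), "positive semi-definite")
  expect_error(simulate_counts(design), "TF0001")
})

test_that("null design yields exchangeable groups and no DE discoveries", {
  design <- sim_design(n_tf = 40, n_target = 40, n_case = 10, n_ref = 10,
                       dispersion = 0.05, seed = 21)
  sim <- simulate_counts(design)
  de <- differential_expression(sim$counts, fdr = 0.1)
  expect_lte(sum(de$status %in% c("up", "down")), 2)
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.01)

  # permutation check on one gene: observed group mean difference is an
  # unremarkable draw from the permutation distribution
  x <- sim$counts$counts[1, ]
  grp <- sim$counts$groups == "case"
  obs <- mean(x[grp]) - mean(x[!grp])
  set.seed(1)
  perm <- replicate(499, {
    s <- sample(grp)
    mean(x[s]) - mean(x[!s])
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / 500
  expect_gt(p_perm, 0.01)
})

test_that("regulatory-db coverage semantics and record validity", {
  design <- hub_and_spoke_design(n_case = 4, n_ref = 4, seed = 9)
  sim <- simulate_counts(design)
  tf_ids <- sim$roles$gene_id[sim$roles$role == "TF"]
  dp <- sim$truth$diff_pairs
  eligible <- dp[dp$gene_a %in% tf_ids | dp$gene_b %in% tf_ids, ]

  full <- simulate_regulatory_db(sim$roles, sim$truth, db_coverage = 1,
                                 extra_edges = 0, "promoter", seed = 2)
  expect_equal(nrow(full), nrow(eligible))
  expect_true(all(full$tf %in% tf_ids))
  expect_true(all(full$binding_sites >= 1))
  expect_true(all(full$tf != full$target))
  # every record corresponds to an eligible planted pair
  rec_key <- paste(pmin(full$tf, full$target), pmax(full$tf, full$target))
  expect_setequal(rec_key, paste(eligible$gene_a, eligible$gene_b))

  none <- simulate_regulatory_db(sim$roles, sim$truth, db_coverage = 0,
                                 extra_edges = 0, "promoter", seed = 2)
  expect_equal(nrow(none), 0)

  withdecoys <- simulate_regulatory_db(sim$roles, sim$truth, db_coverage = 1,
                                       extra_edges = 25, "enhancer", seed = 2)
  expect_equal(nrow(withdecoys), nrow(eligible) + 25)
  expect_false(anyDuplicated(paste(withdecoys$tf, withdecoys$target)) > 0)
})

test_that("fractional coverage rounds to the nearest eligible-pair count", {
  # study-scale illustration: coverage 75,606 / 128,318 of 128,318
  # eligible pairs annotates 75,606 of them (plus-minus rounding)
  tfs <- sprintf("TF%04d", 1:600)
  tgs <- sprintf("GLY%03d", 1:250)
  roles <- data.frame(gene_id = c(tfs, tgs),
                      role = rep(c("TF", "target"), c(600, 250)),
                      stringsAsFactors = FALSE)
  pairs <- expand.grid(gene_a = tfs, gene_b = tgs,
                       stringsAsFactors = FALSE)[1:128318, ]
  truth <- structure(list(diff_pairs = data.frame(pairs, r_case = 0.5,
                                                  r_ref = 0)),
                     class = "sim_truth")
  db <- simulate_regulatory_db(roles, truth,
                               db_coverage = 75606 / 128318,
                               extra_edges = 0, "promoter", seed = 4)
  expect_lte(abs(nrow(db) - 75606), 1)
})

test_that("sim bundle round-trips through the plain-text readers", {
  design <- hub_and_spoke_design(n_case = 5, n_ref = 5, seed = 13)
  sim <- simulate_counts(design)
  db <- simulate_regulatory_db(sim$roles, sim$truth, 1, 5, "promoter",
                               seed = 14)
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(sim, list(promoter = db), dir)
  cm <- read_counts(paths[["counts"]], paths[["samples"]])
  expect_identical(cm$counts, sim$counts$counts)
  expect_identical(unname(cm$groups[colnames(cm$counts)]),
                   unname(sim$counts$groups[colnames(cm$counts)]))
  roles <- read_roles(paths[["roles"]])
  expect_identical(roles, sim$roles)
  db2 <- load_regulatory_db(paths[["promoter"]], "promoter")
  expect_equal(db2$tf, db$tf)
  expect_equal(db2$binding_sites, db$binding_sites)
})
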