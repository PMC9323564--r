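# glyconet

Differential co-expression networks of glycolysis regulation from bulk
RNA-seq.

## What it does

In autoimmune disease, T lymphocytes rewire their energy metabolism;
whether that rewiring is driven by changed *transcriptional regulation*
of glycolysis genes is not visible from differential expression alone.
`glyconet` implements a pipeline that asks, for every transcription
factor (TF) / glycolysis-gene pair, whether the *co-expression* between
the two differs between two groups of samples (e.g. patients vs
healthy donors), and then maps the significant pairs onto known
regulatory interactions to find the central regulators and targets.

The stages:

1. **Differential expression** — median-of-ratios size factors and a
   simplified negative-binomial Wald test; genes are called up/down at
   BH FDR ≤ 0.1 and linear fold change ≥ 1.5.
2. **Single-sample edge weights (LIONESS)** — for each gene pair, the
   Pearson correlation over all N pooled samples, e^α, and without
   sample q, e^(α−q), give a per-sample edge weight by linear
   interpolation:

   e_q = N · (e^α − e^(α−q)) + e^(α−q)

3. **Differential edge weights** — a per-pair two-group linear model
   with an empirical-Bayes moderated t-statistic: the posterior
   variance s²_post = (d₀·s₀² + d·s²)/(d₀ + d) with the prior (d₀, s₀²)
   estimated across all pairs by moment-matching of log variances;
   BH correction across all C(p, 2) pairs; significance at FDR ≤ 0.1.
4. **Regulatory annotation** — significant undirected pairs become
   directed TF → target edges when a promoter-class (GTRD-like) or
   enhancer-class (GeneHancer-like) database records the interaction;
   edge signs keep the direction of the group difference. Networks
   with fewer than 20 glycolysis (target-role) genes are not analysed
   further.
5. **Centrality selection** — in/out-degree, unnormalized directed
   betweenness, and HITS hub/authority scores; central TFs are the
   intersection of the top-ten lists for out-degree, hub score and
   betweenness, central targets the intersection for in-degree and
   authority.
6. **Database comparison** — per-target in-degrees, shared edges, and
   per-TF binding-site counts between the promoter-class and
   enhancer-class networks.

A synthetic-data module generates count matrices with *planted* ground
truth (negative-binomial marginals, group-specific correlation planted
through a Gaussian copula, planted DE genes, regulatory tables with
controlled coverage), so the whole pipeline is testable without any
external download.

## Worked example

Simulate a two-group study (100 genes, 50 samples per group) with a
planted hub TF whose 12 target genes change correlation between groups,
then run one comparison end to end:

```r
library(glyconet)

design <- hub_and_spoke_design(n_case = 50, n_ref = 50, seed = 42)
sim <- simulate_counts(design)
dbs <- list(
  promoter = simulate_regulatory_db(sim$roles, sim$truth, 1, 20, "promoter", 43),
  enhancer = simulate_regulatory_db(sim$roles, sim$truth, 1, 20, "enhancer", 44))
paths <- write_sim_bundle(sim, dbs, "demo")

cfg <- pipeline_config(counts = paths[["counts"]], samples = paths[["samples"]],
                       roles = paths[["roles"]],
                       promoter_db = paths[["promoter"]],
                       enhancer_db = paths[["enhancer"]], out_dir = "demo/out")
res <- run_comparison(cfg)
```

which logs:

```
[load] 100 genes, 100 samples ( 50 case / 50 reference )
[de] 2 up, 2 down of 100 tested genes
[diff-edges] moderated t over 4950 pairs
[diff-edges] 125 significant of 4950 pairs at FDR 0.1
[annotate:promoter] 46 edges, 46 target genes ( 79 significant pairs without database support )
[centrality] central TFs: TF0001, TF0002, TF0003, TF0004, TF0005, TF0006, TF0007, TF0008, TF0009, TF0010
```

Reading the numbers: all four planted DE genes are recovered (2 up,
2 down); 125 of 4,950 tested pairs have significantly different edge
weights, of which 46 are supported by the promoter-class database and
become directed network edges; and the planted dominant hub `TF0001`
tops the central-TF list (`res$selection$central_tfs`), alongside the
other planted block TFs. `demo/out/` holds the DE table, the
differential-edge table, SIF/TSV networks loadable by Cytoscape, the
centrality table, the database comparison tables, a run log, and a
JSON manifest (thresholds, BH denominator, group sizes).

A thin command-line wrapper with `simulate`, `run` and `compare-dbs`
subcommands is installed at
`system.file("cli", "glyconet.R", package = "glyconet")`.

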