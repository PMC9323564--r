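---
title: "Methods: differential co-expression networks of glycolysis regulation"
author: "glyconet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression networks of glycolysis regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

Differential expression compares the *level* of a transcript between
two groups; it says nothing about whether a transcription factor's
*relationship* to a target gene has changed. `glyconet` targets the
latter: for each pair over a curated list of transcription factors
(TFs) and glycolysis-related genes, it tests whether the pair's
co-expression differs between a case and a reference group, and
assembles the significant, database-supported pairs into a directed
regulatory network whose central nodes summarize altered glycolysis
regulation.

The pipeline assumes bulk RNA-seq counts, two groups with at least a
handful of samples each, a role for each gene (`TF` or `target`), and
two directed interaction tables: a promoter-class table (interactions
supported by at least one TF binding site in a window around the
target's transcription start site, GTRD-style) and an enhancer-class
table (binding sites outside that window, GeneHancer-style).

### Single-sample edge weights

Correlation is a population quantity; to test it with per-sample
resolution we use linear interpolation of network estimates (LIONESS).
With e^α the Pearson correlation of a gene pair across all N pooled
samples and e^(α−q) the correlation without sample q, the weight
attributed to sample q is

$$ e_q = N\,(e^\alpha - e^{\alpha-q}) + e^{\alpha-q}. $$

Correlations are bounded in [−1, 1]; e_q is *not*, and no clipping is
applied — the interpolation deliberately amplifies a sample's
leave-one-out influence by the factor N. The implementation performs
one aggregate and N leave-one-out full correlation evaluations; at the
intended scale (about 1.3k genes and tens of samples per comparison)
this is fast, exact, and trivially auditable against a brute-force
loop, which the test suite does to 1e−12.

Edge weights are computed on the pooled samples of the *two compared
groups only*. Pooling additional cohorts would let unrelated samples
move e^α and hence every e_q; restricting the pool keeps the aggregate
an estimate for the contrast at hand. This choice is recorded in the
run manifest.

### Differential edge weights

Each pair's weights are modelled with a two-group linear model in
closed form (logFC = mean case − mean reference, pooled residual
variance s², d = N − 2 residual degrees of freedom). With one test per
pair and few samples, per-pair variances are noisy; an empirical-Bayes
prior is fitted by moment-matching of log s² to a scaled log-F
distribution (digamma/trigamma inversion), giving prior degrees of
freedom d₀ and prior variance s₀². The moderated statistic uses the
posterior variance

$$ s^2_{post} = \frac{d_0 s_0^2 + d s^2}{d_0 + d},
   \qquad t = \frac{\mathrm{logFC}}{\sqrt{s^2_{post}(1/n_1 + 1/n_0)}} $$

referred to a t distribution with d + d₀ degrees of freedom. When the
observed spread of log s² does not exceed what sampling alone implies,
d₀ is infinite: the prior variance is then the geometric mean of the
s², and the statistic reduces exactly to a z-test — the suite checks
this branch explicitly, and checks the finite-d₀ path against an
independent reference implementation to machine precision.

Benjamini–Hochberg correction runs across *all* canonical pairs of the
gene list (the database filter comes after significance, so the test
universe is the full pair set; the BH denominator is written to the
manifest). Pairs with adjusted p ≤ `edge_fdr` are significant; the sign
of logFC records which group had the higher edge weight (positive =
case, with the case group listed first — the sign convention all
exports share).

### Annotation, filtering, centrality

A significant pair {a, b} becomes the directed edge a → b if the
database holds the record (a, b), and b → a if it holds (b, a); both
can fire for TF–TF pairs. Records whose source gene has target role are
dropped, so glycolysis genes are pure sinks by construction. Networks
with fewer than `min_targets = 20` target-role genes are reported but
not carried into centrality analysis (status `SKIPPED`).

Five centralities are computed: in/out-degree, unnormalized directed
betweenness (Brandes; ranking is normalization-invariant, and pure
sinks provably score zero — asserted as a test), and HITS hub/authority
scores by power iteration from the uniform vector with Euclidean
renormalization, tolerance 1e−10 on the successive max-difference, and
an explicit error carrying the residual if 1000 iterations do not
converge. Measures that depend on outgoing edges (out-degree, hub,
betweenness) are ranked over TF-role nodes; in-degree and authority
over target-role nodes. Central TFs are the intersection of the three
TF top-ten lists, central targets the intersection of the two target
lists. At rank ten, *all* nodes tied with the tenth value are kept —
the deterministic choice; dropped ties would depend on storage order —
with a secondary sort by gene identifier.

### Promoter vs enhancer comparison

For the same contrast annotated against both database classes, the
pipeline reports per-target in-degrees in each network, the number of
directed edges common to both ("common edges", bounded by the smaller
in-degree — asserted on every output), and, per target, how many of
the TFs recorded in both databases have more binding sites in the
enhancer-class table, more in the promoter-class table, or the same
number (the three tallies always sum to the common-TF count). The
enhancer-class table is defined to contain only sites *outside* the
promoter window; where a source mixes both, the promoter-window sites
should be excluded before loading (a deliberate reading of the
ambiguous convention; the loader makes no attempt to re-classify).

## The synthetic-data generator

The generator emulates the statistical regime the pipeline assumes,
with known plants for every downstream stage:

- **Count marginals.** Negative binomial with var = μ + φμ²; baseline
  means drawn log-uniformly from `mu_range` (default 20–2000,
  counts per gene per sample), dispersion `phi` (default 0.05, a
  typical bulk RNA-seq value; φ = 0 gives Poisson). The study data's
  within-group biological variance is not published, so dispersion is
  a free parameter rather than a matched value.
- **Planted correlation.** A per-group latent correlation matrix (unit
  diagonal, planted r for listed pairs) is validated by eigenvalue
  check — infeasible plans fail loudly, naming the offending pairs;
  there is no silent nearest-PSD repair — and a multivariate normal
  draw is pushed through exact NB quantiles (`qnbinom(pnorm(z))`,
  Gaussian copula). Planting on the latent scale is the only place a
  target correlation is well defined, and the copula keeps the count
  marginals exactly NB while log-count sample correlations attain the
  plants (the suite requires |attained − planted| < 0.1 at n ≥ 200 per
  group).
- **Planted DE.** Case-group means shifted by 2^log2fc for listed
  genes.
- **Regulatory tables.** A `db_coverage` fraction of the planted
  differential pairs with a TF member, direction TF → partner, plus
  decoy records; binding-site counts from a shifted geometric
  distribution (support ≥ 1), mimicking the long right tail of real
  binding-site counts without asserting any specific value.
- **Seeding.** One RNG stream per logical component (roles, baseline
  means, latent draws, database) derived from the master seed, so
  adding decoy edges never perturbs the counts.

A geometric constraint worth knowing: a "star" of planted correlations
(one TF at r with k mutually independent partners) is only positive
semi-definite while k ≤ 1/r², so hubs are planted as *equicorrelated
blocks* (TF plus its targets, all pairwise at r). The within-block
target–target pairs are genuine plants too and are recorded in the
ground truth; they can never enter the network (no TF member), which
the annotation stage must — and does — handle. `hub_and_spoke_design()`
encodes the fixture geometry used throughout the tests: ten TF-led
blocks with descending sizes plus disjoint single pairs, 50 TF–target
planted pairs over 100 genes, r = 0.9 in the case group versus 0 in
the reference group, and four planted DE genes at |log2fc| = 1.5. A
TF participating in at least `hub_min_pairs = 10` planted pairs is
recorded as a planted hub.

What the generator does *not* emulate: library-size gradients beyond
what NB sampling induces, batch effects, covariates, count outliers,
and the dense correlated-module structure of real transcriptomes.
Passing recovery tests therefore show the pipeline detects planted
pairwise effects at the simulated noise level — not that real-data
discoveries at a given FDR are equally reliable.

## Statistical power, and why two recovery scales

The single-sample construction amplifies leave-one-out noise by N, so
per-pair differential tests at small N are weak. Monte-Carlo
experiments on perfect latent Gaussian data put the median two-sample
|t| near 2.1 for r = 0.9 versus 0 at 10 samples per group — and even an
oracle Fisher-z comparison of those correlations has a median p around
0.006, while BH at q = 0.1 with a few percent true pairs needs p below
about 0.001. No per-pair test of this contrast can reach high
sensitivity at that scale; this is a property of the statistics, not
of the implementation. The acceptance script therefore reports planted
recovery at two scales: 10 samples per group (the regime typical of
the motivating cohort sizes, where recall is expected to be near zero)
and 50 per group, where the same pipeline attains recall above 0.7
with a false-discovery proportion within the nominal level and
recovers the planted hub TF. Interpreting small-cohort runs should
lean on the FDR guarantee (what *is* reported is mostly real), not on
sensitivity (much is missed).

## Numerical choices and edge cases

- **Expression transform.** Default `log2norm`, log2(count/factor + 1);
  pseudocount 1 keeps zeros at zero. Mode `shrunken` additionally
  shrinks each gene toward its cross-sample mean with weight
  s²/(s² + s₀²), s₀² the median gene variance — a monotone
  variance-stabilizing surrogate for regularized-log transforms, whose
  GLM-based shrinkage is intentionally not reproduced (the transform
  feeds only correlations, which are invariant to per-gene monotone
  linear rescaling of spread to first order). Constant genes are left
  unchanged.
- **DE test.** Method-of-moments NB dispersion floored at 1e−8; Wald
  statistic on the log2 mean ratio with a delta-method standard error;
  all-zero genes are reported `untested` and excluded from the BH
  denominator; a zero group mean of an otherwise-tested gene is
  floored at 0.5 normalized counts for the ratio and its SE. The 1.5
  fold-change filter applies to the raw point estimate, as a second
  criterion alongside the FDR cut.
- **Constant genes in correlation.** Defined as correlation 0 with a
  warning (not NA), keeping the edge-weight matrix rectangular; such
  pairs cannot reach significance.
- **Trigamma inversion.** Newton iteration with asymptotic fallbacks at
  both ends; the Inf-d₀ branch activates when the log-variance spread
  is at or below its pure-sampling expectation.
- **Pair identity.** Pairs are stored unordered with the
  lexicographically smaller gene first (`"a|b"`), so (a, b) and (b, a)
  are one test everywhere.
- **Determinism.** A fixed configuration reproduces byte-identical
  tables; the manifest records thresholds, group sizes, the BH
  denominator, and the fitted prior.

## Problem sizes in the test suite

The suite exercises oracle equivalences on matrices up to 6 genes × 8
samples (hundreds of randomized trials), HITS against eigen
decompositions on over a hundred random digraphs of up to 15 nodes,
null calibration on 5,000 simulated pairs at 10 samples per group,
prior recovery on 10,000 simulated variances, and end-to-end runs on
the 100-gene fixture at 10 and 50 samples per group. These sizes give
stable Monte-Carlo margins for every asserted bound while keeping the
default test run fast.

## Known limitations

- Two-group contrasts only; no covariates, array weights, or robust
  variance options in the moderated test.
- Pearson correlation is the only aggregate network estimator.
- The DE stage is a simplified NB Wald test: adequate for up/down node
  labels and threshold filters, not a replacement for a full
  shrinkage-based DE analysis.
- Database tables are consumed as resolved TF → target pairs; peak
  calling, TSS resolution and enhancer–gene linking are upstream
  data-engineering concerns.
- Single-sample edge weights at small N are intrinsically noisy (see
  the power section); treat small-cohort sensitivities accordingly.
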