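# Count container, normalization, expression transform and the
# differential-expression caller. Differential expression here is a
# simplified negative-binomial Wald test: it feeds only the up/down node
# labels and threshold filters of the network stages, so full
# DESeq2-style shrinkage machinery is deliberately not reproduced.

#' Count matrix with group labels
#'
#' @param counts integer matrix, genes x samples, with unique row and
#'   column names.
#' @param groups named character vector mapping every sample to
#'   `"case"` or `"reference"` (names must match `colnames(counts)`).
#' @return object of class `count_matrix` (list with `counts`, `groups`).
#' @export
count_matrix <- function(counts, groups) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate gene or sample identifiers")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (!all(colnames(counts) %in% names(groups))) {
    stop("every sample needs a group label")
  }
  groups <- groups[colnames(counts)]
  as_group_factor(groups)  # validates labels
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$groups == "case"), "case /",
      sum(x$groups == "reference"), "reference )\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors by the median-of-ratios convention: a
#' reference pseudo-sample is formed from the geometric mean of each
#' gene's counts over the genes expressed in every sample, and each
#' sample's factor is the median ratio of its counts to that reference.
#'
#' @param counts a [count_matrix()] or a bare counts matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  all_pos <- rowSums(m <= 0) == 0
  if (!any(all_pos)) {
    stop("normalization error: no gene expressed in all samples")
  }
  sub <- m[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  factors <- apply(sub / ref, 2, stats::median)
  names(factors) <- colnames(m)
  factors
}

#' Transform counts for co-expression analysis
#'
#' `log2norm` (default) is `log2(count / factor + 1)`. `shrunken`
#' additionally shrinks each gene's log2norm values toward its
#' cross-sample mean with weight `w = s2_gene / (s2_gene + s2_0)`, where
#' `s2_0` is the median gene variance: a monotone, variance-stabilizing
#' surrogate for regularized-log transforms, damping the inflated
#' log-scale variance of low-count genes.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param factors size factors from [size_factors()].
#' @param mode `"log2norm"` or `"shrunken"`.
#' @return numeric matrix of transformed expression (same dimnames),
#'   with attribute `transform_tag`.
#' @export
transform_counts <- function(counts, factors = size_factors(counts),
                             mode = c("log2norm", "shrunken")) {
  mode <- match.arg(mode)
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(length(factors) == ncol(m), all(factors > 0))
  x <- log2(sweep(m, 2, factors, "/") + 1)
  if (mode == "shrunken") {
    means <- rowMeans(x)
    vars <- apply(x, 1, stats::var)
    s2_0 <- stats::median(vars)
    w <- if (s2_0 == 0) as.numeric(vars > 0) else vars / (vars + s2_0)
    x <- means + w * (x - means)
  }
  attr(x, "transform_tag") <- if (mode == "log2norm") "log2norm" else "shrunken"
  x
}

#' Differential expression by a negative-binomial Wald test
#'
#' Tests each gene for a case-vs-reference difference in normalized mean
#' counts. The gene-wise NB dispersion is estimated by the method of
#' moments on within-group variation (floored at 1e-8); the Wald
#' statistic is the log2 mean difference over its delta-method standard
#' error. P-values are Benjamini-Hochberg adjusted over tested genes
#' only; genes with zero counts in all samples are reported untested.
#' A gene is called `up` when `adj_p <= fdr` and `linear_fc >= fc_min`,
#' `down` when `adj_p <= fdr` and `linear_fc <= 1/fc_min`, `ns`
#' otherwise.
#'
#' @param counts a [count_matrix()].
#' @param fdr BH-adjusted p-value cutoff (default 0.1).
#' @param fc_min linear fold-change threshold (default 1.5).
#' @return data frame (one row per gene): `gene`, `log2fc`, `linear_fc`,
#'   `p`, `adj_p`, `mean_case`, `mean_ref`, `status`.
#' @export
differential_expression <- function(counts, fdr = 0.1, fc_min = 1.5) {
  stopifnot(inherits(counts, "count_matrix"))
  g <- as_group_factor(counts$groups)
  n1 <- sum(g == "case")
  n0 <- sum(g == "reference")
  if (n1 < 2 || n0 < 2) stop("design error: need >= 2 samples per group")

  sf <- size_factors(counts)
  norm <- sweep(counts$counts, 2, sf, "/")
  case_idx <- which(g == "case")
  ref_idx <- which(g == "reference")
  m1 <- rowMeans(norm[, case_idx, drop = FALSE])
  m0 <- rowMeans(norm[, ref_idx, drop = FALSE])

  tested <- rowSums(counts$counts) > 0

  # method-of-moments dispersion from within-group variance, pooled
  v1 <- apply(norm[, case_idx, drop = FALSE], 1, stats::var)
  v0 <- apply(norm[, ref_idx, drop = FALSE], 1, stats::var)
  v_pool <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  m_pool <- (n1 * m1 + n0 * m0) / (n1 + n0)
  phi <- ifelse(m_pool > 0, pmax((v_pool - m_pool) / m_pool^2, 1e-8), NA_real_)

  # zero group means of otherwise-tested genes are floored for the
  # log-ratio and its SE (no shrinkage machinery in this simplified test)
  m1f <- pmax(m1, 0.5)
  m0f <- pmax(m0, 0.5)
  log2fc <- ifelse(tested, log2(m1f / m0f), NA_real_)
  var_m1 <- (m1f + phi * m1f^2) / n1
  var_m0 <- (m0f + phi * m0f^2) / n0
  se <- sqrt(var_m1 / m1f^2 + var_m0 / m0f^2) / log(2)
  z <- ifelse(tested & se > 0, log2fc / se, 0)
  p <- ifelse(tested, 2 * stats::pnorm(-abs(z)), NA_real_)
  adj_p <- rep(NA_real_, length(p))
  adj_p[tested] <- stats::p.adjust(p[tested], method = "BH")

  linear_fc <- 2^log2fc
  status <- rep("ns", length(p))
  status[tested & adj_p <= fdr & linear_fc >= fc_min] <- "up"
  status[tested & adj_p <= fdr & linear_fc <= 1 / fc_min] <- "down"
  status[!tested] <- "untested"

  data.frame(gene = rownames(counts$counts), log2fc = log2fc,
             linear_fc = linear_fc, p = p, adj_p = adj_p,
             mean_case = m1, mean_ref = m0, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linear fold change from a log2 fold change
#'
#' @param log2fc finite numeric vector.
#' @param digits optional number of decimal places for printed-table
#'   formatting; `NULL` returns the exact value.
#' @return `2^log2fc`, rounded when `digits` is given.
#' @examples
#' linear_fold_change(0.631, digits = 2)  # 1.55
#' linear_fold_change(-1.462, digits = 3) # 0.363
#' @export
linear_fold_change <- function(log2fc, digits = NULL) {
  stopifnot(all(is.finite(log2fc)))
  fc <- 2^log2fc
  if (!is.null(digits)) fc <- round(fc, digits)
  fc
}
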