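# Group-wise differential testing of LIONESS edge weights with an
# empirical-Bayes moderated t-statistic. Each pair is a two-group linear
# model in closed form; the pair-wise residual variances are shrunk
# toward a common prior estimated by moment-matching of log variances to
# a scaled F distribution, and the moderated t uses the posterior
# variance
#
#   s2_post = (d0 * s0_sq + d * s2) / (d0 + d)
#
# with d + d0 degrees of freedom (normal reference when d0 is infinite).
# The sign convention: positive logFC means higher edge weight in the
# case group (listed first).

#' Per-pair two-group contrast of edge weights
#'
#' Ordinary least squares for the two-group design, in closed form:
#' `logFC = mean(case) - mean(reference)`, pooled residual variance
#' `s2`, residual degrees of freedom `d = N - 2`.
#'
#' @param ewm an [lioness_edge_weights()] result.
#' @param groups named character vector or factor mapping `ewm$sample_ids`
#'   to `"case"` / `"reference"`.
#' @return data frame (`gene_a`, `gene_b`, `pair_id`, `logFC`, `s2`) with
#'   attributes `d`, `n_case`, `n_ref`.
#' @export
fit_edge_contrasts <- function(ewm, groups) {
  stopifnot(inherits(ewm, "edge_weight_matrix"))
  g <- as_group_factor(groups[ewm$sample_ids])
  n1 <- sum(g == "case")
  n0 <- sum(g == "reference")
  if (n1 < 2 || n0 < 2) stop("design error: need >= 2 samples per group")

  w <- ewm$weights
  i1 <- which(g == "case")
  i0 <- which(g == "reference")
  m1 <- rowMeans(w[, i1, drop = FALSE])
  m0 <- rowMeans(w[, i0, drop = FALSE])
  rss <- rowSums((w[, i1, drop = FALSE] - m1)^2) +
    rowSums((w[, i0, drop = FALSE] - m0)^2)
  d <- as.integer(n1 + n0 - 2)

  out <- data.frame(gene_a = ewm$gene_a, gene_b = ewm$gene_b,
                    pair_id = ewm$pair_id, logFC = m1 - m0, s2 = rss / d,
                    stringsAsFactors = FALSE)
  attr(out, "d") <- d
  attr(out, "n_case") <- n1
  attr(out, "n_ref") <- n0
  out
}

# Inverse of the trigamma function by Newton iteration on 1/x scale
# (monotone, globally convergent for y > 0).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of pair-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' by moment-matching of `log(s2)` to a scaled log-F distribution
#' (digamma/trigamma inversion), then forms posterior variances and
#' moderated t-statistics. When the observed log-variance spread does not
#' exceed what sampling alone implies, `d0` is infinite and the statistic
#' reduces to a z-test against the common variance.
#'
#' @param s2 vector of residual variances (>= 0).
#' @param d residual degrees of freedom of each `s2` (scalar, >= 1).
#' @param logFC optional vector of contrasts; when supplied with
#'   `n_case`/`n_ref`, moderated t and p-values are returned.
#' @param n_case,n_ref group sizes for the contrast standard error.
#' @return list with `d0`, `s0_sq`, `s2_post`, and (when `logFC` given)
#'   `t_mod`, `p`, `df_total`.
#' @export
ebayes_moderation <- function(s2, d, logFC = NULL, n_case = NULL,
                              n_ref = NULL) {
  stopifnot(all(s2 >= 0), d >= 1)
  # zero variances carry no log information; floor only for the moments
  pos <- pmax(s2, 1e-300)
  z <- log(pos)
  e <- z - digamma(d / 2) + log(d / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e)

  excess <- e_var - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    # no excess spread: infinitely informative prior; the common
    # variance is the geometric mean (exact when all s2 are equal)
    d0 <- Inf
    s0_sq <- exp(mean(z))
    s2_post <- rep(s0_sq, length(s2))
  } else {
    half_d0 <- trigamma_inverse(excess)
    d0 <- 2 * half_d0
    s0_sq <- exp(e_mean + digamma(half_d0) - log(half_d0))
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
  }

  out <- list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
  if (!is.null(logFC)) {
    stopifnot(!is.null(n_case), !is.null(n_ref))
    se <- sqrt(s2_post * (1 / n_case + 1 / n_ref))
    t_mod <- ifelse(se > 0, logFC / se, 0)
    df_total <- d + d0
    p <- if (is.finite(df_total)) {
      2 * stats::pt(-abs(t_mod), df = df_total)
    } else {
      2 * stats::pnorm(-abs(t_mod))
    }
    out$t_mod <- t_mod
    out$p <- p
    out$df_total <- df_total
  }
  out
}

#' Differential edge-weight table
#'
#' Runs [fit_edge_contrasts()] and [ebayes_moderation()] and adjusts
#' p-values by Benjamini-Hochberg across all canonical pairs of the gene
#' list (the full pair set is the test universe; database filtering
#' happens after significance).
#'
#' @param ewm an [lioness_edge_weights()] result.
#' @param groups named group labels for `ewm$sample_ids`.
#' @return data frame per pair: `gene_a`, `gene_b`, `pair_id`, `logFC`,
#'   `s2`, `t_mod`, `p`, `adj_p`; attributes `d0`, `s0_sq`, `d`,
#'   `n_tests`, `n_case`, `n_ref`.
#' @export
differential_edge_table <- function(ewm, groups) {
  fit <- fit_edge_contrasts(ewm, groups)
  d <- attr(fit, "d")
  eb <- ebayes_moderation(fit$s2, d, logFC = fit$logFC,
                          n_case = attr(fit, "n_case"),
                          n_ref = attr(fit, "n_ref"))
  fit$t_mod <- eb$t_mod
  fit$p <- eb$p
  fit$adj_p <- stats::p.adjust(eb$p, method = "BH")
  attr(fit, "d0") <- eb$d0
  attr(fit, "s0_sq") <- eb$s0_sq
  attr(fit, "n_tests") <- nrow(fit)
  fit
}

#' Significant differential edges
#'
#' Pairs with `adj_p <= fdr`, each carrying the sign of its logFC:
#' `+1` means higher edge weight in the case group, `-1` higher in the
#' reference group.
#'
#' @param table a [differential_edge_table()] result.
#' @param fdr BH-adjusted p-value cutoff (default 0.1).
#' @return subset data frame with an added `sign` column.
#' @export
significant_edges <- function(table, fdr = 0.1) {
  keep <- !is.na(table$adj_p) & table$adj_p <= fdr
  out <- table[keep, , drop = FALSE]
  out$sign <- sign(out$logFC)
  rownames(out) <- NULL
  out
}

#' Write a differential-edge table as TSV
#'
#' @param table a [differential_edge_table()] result (optionally with
#'   `sign`).
#' @param path output file.
#' @export
write_differential_edges <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
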