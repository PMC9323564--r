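# Internal helpers shared across modules.

#' Canonical (unordered) pair identifier
#'
#' Gene pairs are stored unordered; the canonical form puts the
#' lexicographically smaller identifier first so that (a,b) and (b,a)
#' map to the same pair.
#'
#' @param a,b character vectors of gene identifiers (recycled).
#' @return list with components `gene_a`, `gene_b` (canonical order) and
#'   `pair_id` (`"a|b"`).
#' @keywords internal
canonical_pair <- function(a, b) {
  swap <- a > b
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  list(gene_a = ga, gene_b = gb, pair_id = paste(ga, gb, sep = "|"))
}

# Derive independent sub-seeds (one RNG stream per logical component)
# from a master seed, so e.g. adding decoy DB edges never perturbs the
# count draws.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Two-level group factor with "case" first; errors on unknown labels.
as_group_factor <- function(groups, case = "case", reference = "reference") {
  g <- as.character(groups)
  bad <- setdiff(unique(g), c(case, reference))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  factor(g, levels = c(case, reference))
}
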