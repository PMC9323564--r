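# Plain-text readers for pipeline inputs.

#' Read a count matrix and sample sheet
#'
#' The counts TSV has a `gene_id` column and one column per sample; the
#' sample sheet TSV has columns `sample_id` and `group`. Samples whose
#' group is neither `case_label` nor `reference_label` are dropped, and
#' the remaining labels are mapped to `"case"` / `"reference"`.
#'
#' @param counts_path counts TSV.
#' @param samples_path sample-sheet TSV.
#' @param case_label,reference_label group labels in the sheet defining
#'   the contrast (case listed first fixes the sign convention).
#' @return a [count_matrix()].
#' @export
read_counts <- function(counts_path, samples_path,
                        case_label = "case", reference_label = "reference") {
  if (identical(case_label, reference_label)) {
    stop("case and reference labels must differ")
  }
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(raw)) stop("counts TSV needs a gene_id column")
  m <- as.matrix(raw[, setdiff(names(raw), "gene_id"), drop = FALSE])
  rownames(m) <- raw$gene_id
  storage.mode(m) <- "integer"

  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs sample_id and group columns")
  }
  sheet <- sheet[sheet$group %in% c(case_label, reference_label), , drop = FALSE]
  if (nrow(sheet) == 0) stop("no samples match the requested groups")
  keep <- intersect(colnames(m), sheet$sample_id)
  m <- m[, keep, drop = FALSE]
  groups <- ifelse(sheet$group[match(keep, sheet$sample_id)] == case_label,
                   "case", "reference")
  count_matrix(m, stats::setNames(groups, keep))
}

#' Read a gene-role table
#'
#' @param path TSV with columns `gene_id`, `role` (values `TF` /
#'   `target`).
#' @return data frame.
#' @export
read_roles <- function(path) {
  roles <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "role") %in% names(roles))) {
    stop("roles TSV needs gene_id and role columns")
  }
  bad <- !roles$role %in% c("TF", "target")
  if (any(bad)) {
    stop("invalid role value(s) in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  if (anyDuplicated(roles$gene_id)) stop("duplicate gene_id in roles TSV")
  roles
}
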