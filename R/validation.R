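#' A posteriori concordance with genes of known chromosomal location
#'
#' Compares the blinded depth-based annotation against a table of candidate
#' genes whose autosomal or Z location is known independently. Genes on
#' ambiguous or un-annotated scaffolds are non-assessable and excluded from
#' the strict concordance denominator; because ambiguous scaffolds still
#' carry per-replicate labels, a lenient figure is also reported in which a
#' gene on an ambiguous scaffold counts as concordant when at least one
#' replicate pair's provisional label matches its known class.
#'
#' @param annotations annotation `data.table` from [annotate_genome()] (or
#'   re-read with [read_annotation_table()]).
#' @param genes gene table from [read_gene_table()]: `gene_id`,
#'   `scaffold_id`, `known_class` (`autosomal` or `Z`).
#' @return a `concordance_report` list: `per_gene` (a `data.table` with the
#'   assigned label and a status among `match`, `mismatch`,
#'   `non-assessable`, `unresolved`), `n_assessable`, `n_match`,
#'   `concordance` (strict fraction over assessable genes; `NA` when none),
#'   and `concordance_lenient`.
#' @export
concordance_report <- function(annotations, genes) {
  ann <- as.data.table(annotations)
  genes <- as.data.table(genes)
  bad <- setdiff(unique(genes$known_class), c("autosomal", "Z"))
  if (length(bad)) stop("known_class must be 'autosomal' or 'Z', got: ",
                        paste(bad, collapse = ", "))
  label_cols <- grep("^label_", names(ann), value = TRUE)

  per <- genes[, .(gene_id, scaffold_id, known_class)]
  idx <- match(per$scaffold_id, ann$scaffold_id)
  per[, assigned_label := ifelse(is.na(idx), NA_character_, ann$final_label[idx])]
  per[, status := fcase(
    is.na(assigned_label), "unresolved",
    assigned_label %in% c("ambiguous", "unannotated"), "non-assessable",
    assigned_label == known_class, "match",
    default = "mismatch")]
  # lenient: a non-assessable ambiguous scaffold counts if any replicate agrees
  any_rep <- vapply(seq_len(nrow(per)), function(i) {
    if (is.na(idx[i]) || !length(label_cols)) return(FALSE)
    any(unlist(ann[idx[i], ..label_cols]) == per$known_class[i])
  }, logical(1))
  per[, any_replicate_match := any_rep]

  n_assess <- sum(per$status %in% c("match", "mismatch"))
  n_match <- sum(per$status == "match")
  len_pool <- per$status %in% c("match", "mismatch") |
    (per$status == "non-assessable" & per$assigned_label == "ambiguous" & !is.na(per$assigned_label))
  len_match <- sum((per$status == "match") |
                     (len_pool & per$status == "non-assessable" & per$any_replicate_match))
  structure(list(per_gene = per[],
                 n_genes = nrow(per),
                 n_assessable = n_assess,
                 n_match = n_match,
                 concordance = if (n_assess > 0) n_match / n_assess else NA_real_,
                 n_lenient = sum(len_pool),
                 concordance_lenient = if (sum(len_pool) > 0) len_match / sum(len_pool) else NA_real_),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Candidate-gene concordance with depth-based annotation\n")
  print(as.data.frame(x$per_gene), row.names = FALSE)
  if (is.na(x$concordance)) {
    cat("strict concordance: undefined (no assessable genes)\n")
  } else {
    cat(sprintf("strict concordance: %d/%d = %.3f\n",
                x$n_match, x$n_assessable, x$concordance))
  }
  if (!is.na(x$concordance_lenient) && x$n_lenient > x$n_assessable)
    cat(sprintf("lenient concordance (any replicate matches on ambiguous scaffolds): %.3f over %d genes\n",
                x$concordance_lenient, x$n_lenient))
  invisible(x)
}
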