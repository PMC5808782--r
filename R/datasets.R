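# Standardization of probe/transcript-level matrices: collapse probes to
# unique gene identifiers, replicates to one column per tissue, and free-
# text tissue labels to ontology term ids.

#' Construct an alias dictionary
#'
#' Maps probe/transcript/name aliases to canonical gene identifiers for one
#' organism.  An alias may resolve to more than one gene; such ambiguous
#' aliases are filtered out by [map_identifiers()].
#'
#' @param entries data.frame with character columns `alias` and `gene`.
#' @param organism taxon label.
#' @return an `AliasDictionary`.
#' @export
alias_dictionary <- function(entries, organism = "human") {
  stopifnot(is.data.frame(entries),
            all(c("alias", "gene") %in% names(entries)))
  entries <- unique(data.frame(alias = as.character(entries$alias),
                               gene = as.character(entries$gene),
                               stringsAsFactors = FALSE))
  if (any(!nzchar(entries$alias)))
    stop("empty alias in dictionary", call. = FALSE)
  structure(list(entries = entries, organism = organism),
            class = "AliasDictionary")
}

#' Map probe-level rows to canonical gene identifiers
#'
#' Applies the standard identifier-mapping rules: a probe whose alias
#' resolves to more than one canonical gene is removed entirely (before any
#' averaging, so an ambiguous probe never contributes to any gene); probes
#' without a dictionary entry are removed; when several probes map to the
#' same gene, the gene's value in each tissue is the arithmetic mean of the
#' probe values on the raw scale (no log transform).
#'
#' @param raw probe-level `ExpressionDataset` (row names are aliases).
#' @param dict an `AliasDictionary`.
#' @return gene-level `ExpressionDataset`; `attr(, "dropped")` is a named
#'   integer vector with counts `ambiguous` and `unmapped`.
#' @export
map_identifiers <- function(raw, dict) {
  if (nrow(dict$entries) == 0L)
    stop("alias dictionary is empty", call. = FALSE)
  probes <- dataset_genes(raw)
  targets_per_alias <- split(dict$entries$gene, dict$entries$alias)
  n_targets <- lengths(targets_per_alias)
  hit <- probes %in% names(targets_per_alias)
  ambiguous <- hit & n_targets[probes] > 1L
  ambiguous[is.na(ambiguous)] <- FALSE
  keep <- hit & !ambiguous
  dropped <- c(ambiguous = sum(ambiguous), unmapped = sum(!hit))
  if (!any(keep))
    stop("identifier mapping produced zero genes", call. = FALSE)
  gene_of <- vapply(targets_per_alias[probes[keep]], `[`, character(1), 1L)
  m <- raw$values[keep, , drop = FALSE]
  collapsed <- rowsum(m, group = gene_of, reorder = TRUE)
  counts <- as.vector(table(gene_of)[rownames(collapsed)])
  collapsed <- collapsed / counts
  out <- expression_dataset(collapsed, dataset_id = raw$dataset_id,
                            organism = raw$organism, unit = raw$unit)
  attr(out, "dropped") <- dropped
  out
}

#' Average replicate sample columns into one column per tissue
#'
#' Columns are sample labels; `sample_to_tissue` assigns each sample a
#' tissue term or label.  Samples without an assignment are dropped and
#' counted.  Each output column is the arithmetic mean of its samples'
#' values on the raw scale.
#'
#' @param ds an `ExpressionDataset` whose columns are samples.
#' @param sample_to_tissue named character vector: sample label -> tissue.
#' @return an `ExpressionDataset` with one column per tissue;
#'   `attr(, "dropped")` holds the unassigned-sample count.
#' @export
average_replicates <- function(ds, sample_to_tissue) {
  samples <- dataset_tissues(ds)
  tissue <- sample_to_tissue[samples]
  keep <- !is.na(tissue)
  if (!any(keep))
    stop("sample-to-tissue mapping covers zero samples", call. = FALSE)
  m <- ds$values[, keep, drop = FALSE]
  tissue <- tissue[keep]
  collapsed <- t(rowsum(t(m), group = tissue, reorder = TRUE))
  counts <- as.vector(table(tissue)[colnames(collapsed)])
  collapsed <- sweep(collapsed, 2, counts, "/")
  out <- expression_dataset(collapsed, dataset_id = ds$dataset_id,
                            organism = ds$organism, unit = ds$unit)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Rename tissue columns to ontology term ids
#'
#' Free-text column labels are translated through `label_to_term`; labels
#' without a mapping are dropped and counted.  Two labels mapping to the
#' same term are an error -- merge replicates with [average_replicates()]
#' first.
#'
#' @param ds an `ExpressionDataset` with free-text tissue labels.
#' @param label_to_term named character vector: label -> term id.
#' @param onto a `TissueOntology`; mapped terms must exist in it.
#' @return an `ExpressionDataset` keyed by term ids; `attr(, "dropped")`
#'   holds the unmapped-label count.
#' @export
map_tissue_labels <- function(ds, label_to_term, onto) {
  labels <- dataset_tissues(ds)
  term <- label_to_term[labels]
  keep <- !is.na(term)
  term <- term[keep]
  if (anyDuplicated(term))
    stop("two labels map to the same term: ",
         paste(unique(term[duplicated(term)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(term, names(onto$terms))
  if (length(bad))
    stop("mapped term(s) not in ontology: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!any(keep))
    stop("no tissue label could be mapped", call. = FALSE)
  m <- ds$values[, keep, drop = FALSE]
  colnames(m) <- unname(term)
  out <- expression_dataset(m, dataset_id = ds$dataset_id,
                            organism = ds$organism, unit = ds$unit)
  attr(out, "dropped") <- sum(!keep)
  out
}
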