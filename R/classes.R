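#' @keywords internal
"_PACKAGE"

# Core S3 containers shared by every module.  All of them are plain lists
# with a class attribute and a validator that is run on construction, so a
# malformed object fails loudly at the boundary rather than deep inside the
# scoring code.

#' Construct an expression dataset
#'
#' An `ExpressionDataset` is an organism-tagged gene-by-tissue matrix of raw
#' expression values (microarray intensity, FPKM, TPM or arbitrary units).
#' Rows are unique gene (or probe) identifiers, columns unique tissue term
#' identifiers (or sample labels prior to tissue mapping).
#'
#' @param values numeric matrix, genes in rows, tissues in columns, with
#'   unique non-empty dimnames; all values finite and non-negative.
#' @param dataset_id short label for the dataset.
#' @param organism taxon label, e.g. `"human"`.
#' @param unit one of `"intensity"`, `"FPKM"`, `"TPM"`, `"arbitrary"`.
#' @return an object of class `ExpressionDataset` with fields `dataset_id`,
#'   `organism`, `unit` and `values`; `genes()`/`tissues()` are the
#'   row/column names of `values`.
#' @export
expression_dataset <- function(values, dataset_id = "dataset",
                               organism = "human", unit = "arbitrary") {
  unit <- match.arg(unit, c("intensity", "FPKM", "TPM", "arbitrary"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene row names and tissue column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate tissue identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  structure(
    list(dataset_id = dataset_id, organism = organism, unit = unit,
         values = values),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s' (%s, %s): %d genes x %d tissues\n",
              x$dataset_id, x$organism, x$unit,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Genes and tissues of an expression dataset
#' @param ds an `ExpressionDataset`.
#' @return character vector of gene / tissue identifiers.
#' @export
dataset_genes <- function(ds) rownames(ds$values)

#' @rdname dataset_genes
#' @export
dataset_tissues <- function(ds) colnames(ds$values)

#' Construct a gold standard of trusted gene-tissue pairs
#'
#' A `GoldStandard` is a set of unique (gene, tissue term) pairs used for
#' benchmarking an expression dataset: the trusted, but typically very
#' incomplete, annotation of which genes are expressed in which tissues.
#'
#' @param pairs data.frame with character columns `gene` and `tissue`.
#' @param organism taxon label.
#' @param source one of `"curated"`, `"orthology-transferred"`,
#'   `"synthetic"`.
#' @return an object of class `GoldStandard`.
#' @export
gold_standard <- function(pairs, organism = "human", source = "curated") {
  source <- match.arg(source,
                      c("curated", "orthology-transferred", "synthetic"))
  if (!is.data.frame(pairs) || !all(c("gene", "tissue") %in% names(pairs)))
    stop("'pairs' must be a data.frame with columns gene, tissue",
         call. = FALSE)
  pairs <- data.frame(gene = as.character(pairs$gene),
                      tissue = as.character(pairs$tissue),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$gene, pairs$tissue), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(organism = organism, pairs = pairs, source = source),
            class = "GoldStandard")
}

#' @export
print.GoldStandard <- function(x, ...) {
  cat(sprintf("GoldStandard (%s, %s): %d gene-tissue pairs\n",
              x$organism, x$source, nrow(x$pairs)))
  invisible(x)
}

#' Construct a scored evidence channel
#'
#' A `ScoredChannel` holds gene-tissue associations for one evidence channel
#' (curated knowledge, expression experiments, text mining, or the
#' integrated channel), each carrying an optional raw value, a confidence
#' score in fold-enrichment units, and a calibrated star score on the
#' common 0-5 scale.
#'
#' @param associations data.frame with columns `gene`, `tissue`, and
#'   optionally `raw`, `confidence`, `stars` (missing ones are filled with
#'   `NA`).
#' @param channel one of `"knowledge"`, `"experiments"`, `"textmining"`,
#'   `"integrated"`.
#' @param organism taxon label.
#' @param dataset_id optional dataset label carried through for reporting.
#' @return an object of class `ScoredChannel`.
#' @export
scored_channel <- function(associations, channel = "experiments",
                           organism = "human", dataset_id = channel) {
  channel <- match.arg(channel, c("knowledge", "experiments",
                                  "textmining", "integrated"))
  if (!is.data.frame(associations) ||
      !all(c("gene", "tissue") %in% names(associations)))
    stop("'associations' must be a data.frame with columns gene, tissue",
         call. = FALSE)
  a <- associations
  for (col in c("raw", "confidence", "stars"))
    if (is.null(a[[col]])) a[[col]] <- rep(NA_real_, nrow(a))
  a <- data.frame(gene = as.character(a$gene),
                  tissue = as.character(a$tissue),
                  raw = as.numeric(a$raw),
                  confidence = as.numeric(a$confidence),
                  stars = as.numeric(a$stars),
                  stringsAsFactors = FALSE)
  key <- paste(a$gene, a$tissue, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, tissue) association within one channel: ",
         paste(utils::head(unique(sub("\r", " / ", key[duplicated(key)])), 3),
               collapse = "; "), call. = FALSE)
  a <- a[order(a$gene, a$tissue), , drop = FALSE]
  rownames(a) <- NULL
  structure(list(channel = channel, organism = organism,
                 dataset_id = dataset_id, associations = a),
            class = "ScoredChannel")
}

#' @export
print.ScoredChannel <- function(x, ...) {
  cat(sprintf("ScoredChannel '%s' (%s, %s): %d associations\n",
              x$dataset_id, x$channel, x$organism, nrow(x$associations)))
  invisible(x)
}

# internal: gene\r tissue key used wherever pairs index a table
pair_key <- function(gene, tissue) paste(gene, tissue, sep = "\r")
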