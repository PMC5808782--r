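# Dictionary-based gene/tissue co-mention counting over a sentence-split
# corpus, and conversion to a normalized co-occurrence score.  This is a
# deliberately simple stand-in for a production named-entity recognition
# engine: exact, case-insensitive, longest-alias matching only.

#' Read a sentence-split corpus from TSV
#'
#' Dialect: `doc_id<TAB>sentence_index<TAB>sentence_text`, no header.
#'
#' @param path TSV file path.
#' @return list of documents; each is a list with `doc_id` and `sentences`
#'   (character vector ordered by sentence index).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  doc <- vapply(rows, `[`, character(1), 1L)
  idx <- as.integer(vapply(rows, `[`, character(1), 2L))
  txt <- vapply(rows, function(r)
    paste(r[-(1:2)], collapse = "\t"), character(1))
  docs <- lapply(split(seq_along(doc), doc), function(i) {
    o <- order(idx[i])
    list(doc_id = doc[i][1], sentences = txt[i][o])
  })
  docs[order(names(docs))]
}

#' Write a corpus as TSV
#'
#' @param corpus list of documents as produced by [read_corpus()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  out <- unlist(lapply(corpus, function(d)
    paste(d$doc_id, seq_along(d$sentences), d$sentences, sep = "\t")))
  writeLines(out, path)
  invisible(path)
}

# which dictionary entries match a piece of text (case-insensitive,
# word-boundary exact match); single-token aliases are matched by hashed
# token lookup, multi-token ones by regex
match_aliases <- function(text, aliases) {
  text <- tolower(text)
  tokens <- strsplit(text, "[^a-z0-9_]+")[[1]]
  la <- tolower(aliases)
  multi <- grepl("[^a-z0-9_]", la)
  hits <- logical(length(aliases))
  hits[!multi] <- la[!multi] %in% tokens
  if (any(multi))
    hits[multi] <- vapply(la[multi], function(a)
      grepl(paste0("\\b", escape_regex(a), "\\b"), text), logical(1))
  which(hits)
}

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Count weighted gene-tissue co-mentions in a corpus
#'
#' For each document, every (gene, tissue) pair mentioned together in at
#' least one sentence contributes `w_sentence`; pairs mentioned in the
#' same document but never in a common sentence contribute `w_abstract`.
#' When `organisms` is supplied, a gene is only counted in a document if
#' one of its organism's names (Linnaean or common) appears somewhere in
#' that document -- the explicit-species-mention rule.
#'
#' @param corpus list of documents (see [read_corpus()]).
#' @param gene_names data.frame with columns `alias`, `gene`, and
#'   optionally `organism`.
#' @param tissue_names data.frame with columns `alias`, `tissue`.
#' @param organisms optional data.frame with columns `organism`, `name`
#'   (one row per accepted species name).
#' @param w_sentence,w_abstract co-mention weights (defaults 1.0 / 0.2).
#' @return a `CoMentionCounts`: list with `C` (data.frame `gene`,
#'   `tissue`, `count`), margins `C_gene`, `C_tissue`, total `C_total`,
#'   and the weights used.
#' @export
count_comentions <- function(corpus, gene_names, tissue_names,
                             organisms = NULL,
                             w_sentence = 1.0, w_abstract = 0.2) {
  if (nrow(gene_names) == 0L || nrow(tissue_names) == 0L)
    stop("empty alias dictionaries", call. = FALSE)
  counts <- new.env(parent = emptyenv())
  for (d in corpus) {
    full_text <- paste(d$sentences, collapse = " ")
    allowed_orgs <- NULL
    if (!is.null(organisms)) {
      present <- vapply(seq_len(nrow(organisms)), function(i)
        grepl(paste0("\\b", escape_regex(tolower(organisms$name[i])), "\\b"),
              tolower(full_text)), logical(1))
      allowed_orgs <- unique(organisms$organism[present])
    }
    gdict <- gene_names
    if (!is.null(allowed_orgs) && "organism" %in% names(gene_names))
      gdict <- gene_names[gene_names$organism %in% allowed_orgs, ,
                          drop = FALSE]
    if (nrow(gdict) == 0L) next
    sent_genes <- lapply(d$sentences, function(s)
      unique(gdict$gene[match_aliases(s, gdict$alias)]))
    sent_tissues <- lapply(d$sentences, function(s)
      unique(tissue_names$tissue[match_aliases(s, tissue_names$alias)]))
    sentence_pairs <- character(0)
    for (i in seq_along(d$sentences)) {
      gs <- sent_genes[[i]]; ts <- sent_tissues[[i]]
      if (length(gs) && length(ts))
        sentence_pairs <- c(sentence_pairs,
                            as.vector(outer(gs, ts, pair_key)))
    }
    sentence_pairs <- unique(sentence_pairs)
    doc_genes <- unique(unlist(sent_genes))
    doc_tissues <- unique(unlist(sent_tissues))
    doc_pairs <- if (length(doc_genes) && length(doc_tissues))
      as.vector(outer(doc_genes, doc_tissues, pair_key)) else character(0)
    abstract_pairs <- setdiff(doc_pairs, sentence_pairs)
    for (k in sentence_pairs)
      assign(k, w_sentence + mget(k, counts, ifnotfound = 0)[[1]], counts)
    for (k in abstract_pairs)
      assign(k, w_abstract + mget(k, counts, ifnotfound = 0)[[1]], counts)
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    C <- data.frame(gene = character(), tissue = character(),
                    count = numeric(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    C <- data.frame(gene = vapply(parts, `[`, character(1), 1L),
                    tissue = vapply(parts, `[`, character(1), 2L),
                    count = vapply(keys, get, numeric(1), envir = counts),
                    stringsAsFactors = FALSE)
    C <- C[order(C$gene, C$tissue), , drop = FALSE]
    rownames(C) <- NULL
  }
  co_mention_counts(C, w_sentence = w_sentence, w_abstract = w_abstract)
}

#' Construct a co-mention count object
#'
#' @param C data.frame with columns `gene`, `tissue`, `count` (weighted
#'   co-mention counts, all non-negative).
#' @param w_sentence,w_abstract the weights the counts were built with.
#' @return a `CoMentionCounts` with margins and grand total derived from
#'   `C`.
#' @export
co_mention_counts <- function(C, w_sentence = 1.0, w_abstract = 0.2) {
  stopifnot(is.data.frame(C),
            all(c("gene", "tissue", "count") %in% names(C)))
  if (any(C$count < 0)) stop("negative co-mention count", call. = FALSE)
  C_gene <- tapply(C$count, C$gene, sum)
  C_tissue <- tapply(C$count, C$tissue, sum)
  structure(list(C = C,
                 C_gene = C_gene, C_tissue = C_tissue,
                 C_total = sum(C$count),
                 w_sentence = w_sentence, w_abstract = w_abstract),
            class = "CoMentionCounts")
}

#' @export
print.CoMentionCounts <- function(x, ...) {
  cat(sprintf(
    "CoMentionCounts: %d pairs, %d genes, %d tissues, total weight %.3g\n",
    nrow(x$C), length(x$C_gene), length(x$C_tissue), x$C_total))
  invisible(x)
}

#' Normalized co-occurrence score
#'
#' Combines the raw weighted co-mention count with a normalization for how
#' much the gene and the tissue are each mentioned overall:
#' `s(g, t) = C(g,t)^alpha * (C(g,t) * C_total / (C_gene(g) * C_tissue(t)))^(1 - alpha)`.
#' With `alpha = 1` the score reduces to the raw count; with `alpha = 0`
#' it is a pure pointwise dependency ratio.  Pairs with zero count are
#' omitted.
#'
#' @param counts a `CoMentionCounts`.
#' @param alpha mixing weight in `[0, 1]`, default 0.6.
#' @param organism,dataset_id labels for the returned channel.
#' @return a `ScoredChannel` (`channel = "textmining"`) whose `raw` and
#'   `confidence` columns both carry the co-occurrence score.
#' @export
cooccurrence_score <- function(counts, alpha = 0.6, organism = "human",
                               dataset_id = "textmining") {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  C <- counts$C[counts$C$count > 0, , drop = FALSE]
  if (nrow(C) == 0L)
    return(scored_channel(
      data.frame(gene = character(), tissue = character()),
      channel = "textmining", organism = organism,
      dataset_id = dataset_id))
  cg <- as.numeric(counts$C_gene[C$gene])
  ct <- as.numeric(counts$C_tissue[C$tissue])
  s <- C$count^alpha *
    (C$count * counts$C_total / (cg * ct))^(1 - alpha)
  scored_channel(
    data.frame(gene = C$gene, tissue = C$tissue, raw = s, confidence = s,
               stringsAsFactors = FALSE),
    channel = "textmining", organism = organism, dataset_id = dataset_id)
}
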