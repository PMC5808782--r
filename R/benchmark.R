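# Agreement between scored datasets (Pearson correlations, within and
# across organisms) and against the gold standard (ROC / AUC).

# build the paired star-score vectors for two channels over their common
# genes and tissues; genes matched through an ortholog map when given
paired_star_vectors <- function(a, b, map = NULL,
                                mode = c("zero_fill", "co_detected"),
                                tissues = NULL) {
  mode <- match.arg(mode)
  aa <- a$associations
  bb <- b$associations
  genes_a <- unique(aa$gene)
  genes_b <- unique(bb$gene)
  if (is.null(map)) {
    genes <- intersect(genes_a, genes_b)
    ga <- genes; gb <- genes
  } else {
    p <- map$pairs
    keep <- p$gene_a %in% genes_a & p$gene_b %in% genes_b
    ga <- p$gene_a[keep]; gb <- p$gene_b[keep]
  }
  if (is.null(tissues))
    tissues <- intersect(unique(aa$tissue), unique(bb$tissue))
  n_g <- length(ga)
  if (n_g == 0L || length(tissues) == 0L)
    stop("no common genes or tissues between the channels", call. = FALSE)
  ka <- pair_key(rep(ga, times = length(tissues)),
                 rep(tissues, each = n_g))
  kb <- pair_key(rep(gb, times = length(tissues)),
                 rep(tissues, each = n_g))
  sa <- stats::setNames(aa$stars, pair_key(aa$gene, aa$tissue))[ka]
  sb <- stats::setNames(bb$stars, pair_key(bb$gene, bb$tissue))[kb]
  if (mode == "zero_fill") {
    sa[is.na(sa)] <- 0
    sb[is.na(sb)] <- 0
  } else {
    keep <- !is.na(sa) & !is.na(sb)
    sa <- sa[keep]; sb <- sb[keep]
  }
  list(a = unname(sa), b = unname(sb))
}

pearson_or_stop <- function(x, y) {
  if (length(x) < 3L)
    stop("fewer than 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in a score vector",
         call. = FALSE)
  stats::cor(x, y)
}

#' Pearson correlation between two scored channels
#'
#' Builds vectors of final star scores over the (common gene x common
#' tissue) grid of the two channels and returns their Pearson correlation.
#' The gene universe is the genes observed (expressed in at least one
#' tissue) in both channels, matched through 1:1 orthologs when the
#' channels belong to different organisms.  Pairs absent from one channel
#' contribute a score of 0 by default (`mode = "zero_fill"`); set
#' `mode = "co_detected"` to restrict to pairs present in both.
#' Negative-score associations are expected to have been removed already
#' (by [apply_stars()]).
#'
#' @param a,b `ScoredChannel` objects.
#' @param map optional `OrthologMap` from `a`'s organism to `b`'s.
#' @param mode `"zero_fill"` (default) or `"co_detected"`.
#' @param tissues optional tissue subset; default is the common tissues.
#' @return Pearson r.
#' @export
dataset_correlation <- function(a, b, map = NULL,
                                mode = c("zero_fill", "co_detected"),
                                tissues = NULL) {
  v <- paired_star_vectors(a, b, map = map, mode = mode, tissues = tissues)
  pearson_or_stop(v$a, v$b)
}

#' Pearson correlation restricted to one tissue
#'
#' @inheritParams dataset_correlation
#' @param tissue a single tissue term present in both channels.
#' @return Pearson r over the gene vectors of that tissue.
#' @export
per_tissue_correlation <- function(a, b, tissue, map = NULL,
                                   mode = c("zero_fill", "co_detected")) {
  if (!tissue %in% unique(a$associations$tissue))
    stop("tissue absent from first channel: ", tissue, call. = FALSE)
  if (!tissue %in% unique(b$associations$tissue))
    stop("tissue absent from second channel: ", tissue, call. = FALSE)
  dataset_correlation(a, b, map = map, mode = mode, tissues = tissue)
}

#' Pairwise correlation matrix across scored channels
#'
#' @param channels named list of `ScoredChannel` objects (names become
#'   row/column labels; unnamed lists use dataset ids).
#' @param maps optional named list of `OrthologMap` objects keyed
#'   `"orgA|orgB"` for cross-organism pairs.
#' @param mode passed to [dataset_correlation()].
#' @return symmetric numeric matrix of Pearson r with unit diagonal;
#'   cells whose correlation is undefined are `NA` and listed in
#'   `attr(, "failed")`.
#' @export
correlation_matrix <- function(channels, maps = list(),
                               mode = c("zero_fill", "co_detected")) {
  if (length(channels) < 2L) stop("need at least 2 channels", call. = FALSE)
  ids <- names(channels)
  if (is.null(ids))
    ids <- vapply(channels, function(ch) ch$dataset_id, character(1))
  n <- length(channels)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  failed <- character()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- channels[[i]]; b <- channels[[j]]
    map <- NULL
    if (!identical(a$organism, b$organism)) {
      map <- maps[[paste(a$organism, b$organism, sep = "|")]]
      if (is.null(map)) {
        rev <- maps[[paste(b$organism, a$organism, sep = "|")]]
        if (!is.null(rev))
          map <- structure(list(org_a = rev$org_b, org_b = rev$org_a,
                                pairs = data.frame(gene_a = rev$pairs$gene_b,
                                                   gene_b = rev$pairs$gene_a,
                                                   stringsAsFactors = FALSE),
                                voided = rev$voided),
                           class = "OrthologMap")
      }
    }
    r <- tryCatch(dataset_correlation(a, b, map = map, mode = mode),
                  error = function(e) {
                    failed <<- c(failed,
                                 sprintf("%s/%s: %s", ids[i], ids[j],
                                         conditionMessage(e)))
                    NA_real_
                  })
    m[i, j] <- r
    m[j, i] <- r
  }
  attr(m, "failed") <- failed
  m
}

#' ROC curve of a scored channel against the gold standard
#'
#' Positives are the gold-standard pairs restricted to genes shared
#' between the channel and the gold standard and to the given benchmark
#' tissues; negatives are every remaining (shared gene x benchmark tissue)
#' combination.  Because the gold standard is reliable but incomplete,
#' unannotated pairs may contain true expression, so the false-positive
#' rate is an upper bound.  Pairs absent from the channel score 0; ties
#' share one threshold point; the area under the curve is computed by the
#' trapezoidal rule.
#'
#' @param ch a `ScoredChannel` with star scores.
#' @param gs a `GoldStandard`.
#' @param tissues benchmark tissue set (the convention is a small set of
#'   tissues covered by every dataset, e.g. nervous system, liver, heart,
#'   kidney).
#' @param score_col which score to threshold: `"stars"`, `"confidence"`,
#'   or `"auto"` (stars when any are present, confidence otherwise).
#' @return a `ROCResult`: list with `points` (data.frame `threshold`,
#'   `tpr`, `fpr`, ordered from the strictest threshold) and `auc`.
#' @export
roc_against_gold <- function(ch, gs, tissues,
                             score_col = c("auto", "stars", "confidence")) {
  score_col <- match.arg(score_col)
  a <- ch$associations
  if (score_col == "auto")
    score_col <- if (any(!is.na(a$stars))) "stars" else "confidence"
  a$stars <- a[[score_col]]
  genes <- intersect(unique(a$gene), unique(gs$pairs$gene))
  if (length(genes) == 0L || length(tissues) == 0L)
    stop("no shared genes or empty benchmark tissue set", call. = FALSE)
  univ_gene <- rep(genes, times = length(tissues))
  univ_tissue <- rep(tissues, each = length(genes))
  key <- pair_key(univ_gene, univ_tissue)
  is_pos <- key %in% pair_key(gs$pairs$gene, gs$pairs$tissue)
  if (!any(is_pos)) stop("zero positives in benchmark universe",
                         call. = FALSE)
  if (all(is_pos)) stop("zero negatives in benchmark universe",
                        call. = FALSE)
  score <- stats::setNames(a$stars, pair_key(a$gene, a$tissue))[key]
  score[is.na(score)] <- 0
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & is_pos) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !is_pos) / n_neg,
                numeric(1))
  points <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                       fpr = c(0, fpr))
  if (points$tpr[nrow(points)] != 1 || points$fpr[nrow(points)] != 1)
    points <- rbind(points,
                    data.frame(threshold = -Inf, tpr = 1, fpr = 1))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: %d threshold points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Tissue-profile correlation between a gene and a homolog
#'
#' Pearson correlation of two integrated star-score profiles over the same
#' major-tissue list (the per-gene row of the homolog table in the web
#' resource).  Missing tissues score 0.
#'
#' @param query,other named numeric vectors of star scores; names are
#'   tissue term ids.
#' @param tissues the shared major-tissue list to correlate over.
#' @return Pearson r.
#' @export
homolog_profile_correlation <- function(query, other,
                                        tissues = union(names(query),
                                                        names(other))) {
  if (length(tissues) < 3L)
    stop("fewer than 3 usable tissues", call. = FALSE)
  q <- query[tissues]; o <- other[tissues]
  q[is.na(q)] <- 0; o[is.na(o)] <- 0
  pearson_or_stop(unname(q), unname(o))
}

#' Write a correlation matrix as square TSV
#'
#' @param m matrix from [correlation_matrix()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_correlation_matrix <- function(m, path) {
  header <- paste(c("dataset", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            formatC(m[i, ], digits = 15, format = "g")),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write ROC points as TSV
#'
#' @param roc a `ROCResult`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_roc <- function(roc, path) {
  header <- "threshold\ttpr\tfpr"
  body <- paste(formatC(roc$points$threshold, digits = 15, format = "g"),
                formatC(roc$points$tpr, digits = 15, format = "g"),
                formatC(roc$points$fpr, digits = 15, format = "g"),
                sep = "\t")
  writeLines(c(header, body, sprintf("# auc\t%.15g", roc$auc)), path)
  invisible(path)
}
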