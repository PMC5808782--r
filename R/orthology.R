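# 1:1 ortholog extraction from orthologous groups and orthology-based
# transfer of gold-standard annotations across organisms.

#' Extract 1:1 ortholog pairs between two organisms
#'
#' A group contributes a pair exactly when it contains one gene of
#' `org_a` and one gene of `org_b`; groups with zero or two-plus members of
#' either organism contribute nothing (in-paralogs make the relationship
#' ambiguous).  A gene appearing in more than one group could end up in two
#' different pairs; conservatively, all pairs involving such a gene are
#' discarded and counted.
#'
#' @param groups an `OrthologGroups` object.
#' @param org_a,org_b distinct organism labels.
#' @return an `OrthologMap`: list with `org_a`, `org_b`, `pairs`
#'   (data.frame `gene_a`, `gene_b`, a bijection) and `voided` (number of
#'   pairs discarded for multi-group gene membership).
#' @export
one_to_one_pairs <- function(groups, org_a, org_b) {
  if (identical(org_a, org_b))
    stop("org_a and org_b must differ", call. = FALSE)
  g <- groups$groups
  g <- g[g$organism %in% c(org_a, org_b), , drop = FALSE]
  pairs <- do.call(rbind, lapply(split(g, g$group), function(gr) {
    a <- gr$gene[gr$organism == org_a]
    b <- gr$gene[gr$organism == org_b]
    if (length(a) == 1L && length(b) == 1L)
      data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  dup_a <- pairs$gene_a %in% pairs$gene_a[duplicated(pairs$gene_a)]
  dup_b <- pairs$gene_b %in% pairs$gene_b[duplicated(pairs$gene_b)]
  voided <- sum(dup_a | dup_b)
  pairs <- pairs[!(dup_a | dup_b), , drop = FALSE]
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(org_a = org_a, org_b = org_b, pairs = pairs,
                 voided = voided),
            class = "OrthologMap")
}

#' @export
print.OrthologMap <- function(x, ...) {
  cat(sprintf("OrthologMap %s <-> %s: %d 1:1 pairs (%d voided)\n",
              x$org_a, x$org_b, nrow(x$pairs), x$voided))
  invisible(x)
}

#' Extract 1:1:...:1 ortholog tuples across several organisms
#'
#' Emits one tuple per group containing exactly one gene of every listed
#' organism; tuples reusing a gene already emitted (multi-group
#' membership) are discarded like in [one_to_one_pairs()].
#'
#' @param groups an `OrthologGroups` object.
#' @param orgs character vector of two or more distinct organism labels.
#' @return data.frame with one column per organism, one row per tuple.
#' @export
one_to_one_across <- function(groups, orgs) {
  if (length(orgs) < 2L) stop("need at least two organisms", call. = FALSE)
  if (anyDuplicated(orgs))
    stop("duplicate organism in list", call. = FALSE)
  g <- groups$groups
  g <- g[g$organism %in% orgs, , drop = FALSE]
  tuples <- do.call(rbind, lapply(split(g, g$group), function(gr) {
    per <- lapply(orgs, function(o) gr$gene[gr$organism == o])
    if (all(lengths(per) == 1L)) {
      row <- as.data.frame(per, stringsAsFactors = FALSE)
      names(row) <- orgs
      row
    }
  }))
  if (is.null(tuples)) {
    tuples <- as.data.frame(stats::setNames(
      rep(list(character()), length(orgs)), orgs),
      stringsAsFactors = FALSE)
  }
  keep <- rep(TRUE, nrow(tuples))
  for (o in orgs) {
    dup <- tuples[[o]] %in% tuples[[o]][duplicated(tuples[[o]])]
    keep <- keep & !dup
  }
  tuples <- tuples[keep, , drop = FALSE]
  tuples <- tuples[do.call(order, tuples), , drop = FALSE]
  rownames(tuples) <- NULL
  tuples
}

#' Transfer a gold standard to another organism via 1:1 orthologs
#'
#' Each (gene, tissue) pair whose gene has a 1:1 ortholog becomes
#' (ortholog, tissue); tissue terms are preserved verbatim.  Pairs whose
#' gene lacks an ortholog are dropped and counted.  This rests on the
#' assumption that orthologous genes are similarly expressed in homologous
#' tissues.
#'
#' @param gs a `GoldStandard` whose organism matches `map$org_a`.
#' @param map an `OrthologMap` from the gold standard's organism (`org_a`)
#'   to the target organism (`org_b`).
#' @return a `GoldStandard` for `map$org_b` with
#'   `source = "orthology-transferred"`; `attr(, "dropped")` counts the
#'   unmapped pairs.
#' @export
transfer_gold_standard <- function(gs, map) {
  if (nrow(map$pairs) == 0L)
    stop("ortholog map is empty", call. = FALSE)
  if (!identical(gs$organism, map$org_a))
    stop(sprintf("gold standard organism '%s' does not match map source '%s'",
                 gs$organism, map$org_a), call. = FALSE)
  lookup <- stats::setNames(map$pairs$gene_b, map$pairs$gene_a)
  mapped <- lookup[gs$pairs$gene]
  keep <- !is.na(mapped)
  out <- gold_standard(
    data.frame(gene = unname(mapped[keep]), tissue = gs$pairs$tissue[keep],
               stringsAsFactors = FALSE),
    organism = map$org_b, source = "orthology-transferred")
  attr(out, "dropped") <- sum(!keep)
  out
}

#' List homologs of a gene with ortholog/paralog relation
#'
#' Scans the query gene's orthologous group(s): co-members from the same
#' organism are paralogs, co-members from other organisms orthologs.
#'
#' @param groups an `OrthologGroups` object.
#' @param organism,gene the query.
#' @return data.frame with columns `gene`, `organism`, `relation`
#'   (`"ortholog"` or `"paralog"`); zero rows if the gene is in no group.
#' @export
classify_homologs <- function(groups, organism, gene) {
  g <- groups$groups
  gids <- unique(g$group[g$organism == organism & g$gene == gene])
  co <- g[g$group %in% gids & !(g$organism == organism & g$gene == gene), ,
          drop = FALSE]
  co <- unique(co[, c("organism", "gene")])
  out <- data.frame(gene = co$gene, organism = co$organism,
                    relation = ifelse(co$organism == organism,
                                      "paralog", "ortholog"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$relation, out$organism, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
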